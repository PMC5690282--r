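test_that("SASA matches the isolated-sphere closed form and occlusion logic", {
  carbon <- new_structure(data.frame(
    chain = "A", resno = 1, resname = "ALA", atom = "CA", element = "C",
    x = 0, y = 0, z = 0))
  s1 <- sasa(carbon)
  expect_equal(s1$total, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)

  # two (near-)coincident atoms: each sphere's inward half is occluded by
  # the other, so the joint envelope equals one atom's area
  two <- new_structure(data.frame(
    chain = "A", resno = 1:2, resname = "ALA", atom = "CA", element = "C",
    x = c(0, 1e-3), y = 0, z = 0))
  expect_equal(sasa(two)$total, s1$total, tolerance = 0.02)

  # area decreases monotonically as a second atom approaches
  areas <- sapply(seq(10, 2, by = -1), function(d) {
    st <- new_structure(data.frame(
      chain = "A", resno = 1:2, resname = "ALA", atom = "CA", element = "C",
      x = c(0, d), y = 0, z = 0))
    sasa(st)$total
  })
  expect_true(all(diff(areas) <= 1e-9))

  bad <- new_structure(data.frame(
    chain = "A", resno = 1, resname = "UNK", atom = "X1", element = "XX",
    x = 0, y = 0, z = 0))
  expect_error(sasa(bad), "XX")
  # element radius overrides are honoured
  s3 <- sasa(carbon, radii = c(C = 3.0))
  expect_equal(s3$total, 4 * pi * (3.0 + 1.4)^2, tolerance = 0.01)
})

test_that("interface areas are symmetric, zero at distance, and cap-exact", {
  far_a <- ca_struct(matrix(rnorm(30, sd = 4), ncol = 3), chain = "A")
  far_b <- ca_struct(matrix(rnorm(30, sd = 4) + 100, ncol = 3), chain = "B")
  asm <- new_assembly(list(a = far_a, b = far_b))
  expect_equal(interface_area(asm, "a", "b"), 0, tolerance = 1)
  expect_identical(interface_area(asm, "a", "b"),
                   interface_area(asm, "b", "a"))
  expect_error(interface_area(asm, "a", "a"), "disjoint")
  expect_error(interface_area(asm, "a", "z"), "unknown")

  # two-sphere oracle: spheres of radius r (augmented R = r + probe) at
  # separation d bury a cap of area 2*pi*R*h per sphere, h = R - d/2
  r <- 1.7; probe <- 1.4; R <- r + probe; d <- 4.0
  s_a <- new_structure(data.frame(chain = "A", resno = 1, resname = "ALA",
                                  atom = "CA", element = "C",
                                  x = 0, y = 0, z = 0))
  s_b <- new_structure(data.frame(chain = "B", resno = 1, resname = "ALA",
                                  atom = "CA", element = "C",
                                  x = d, y = 0, z = 0))
  asm2 <- new_assembly(list(a = s_a, b = s_b))
  got <- interface_area(asm2, "a", "b", n_points = 4000)
  h <- R - d / 2
  expect_equal(got, 2 * pi * R * h, tolerance = 0.03)

  # three mutually distant bodies: all pairwise interfaces vanish
  far_c <- ca_struct(matrix(rnorm(30, sd = 4) - 100, ncol = 3), chain = "C")
  asm3 <- new_assembly(list(a = far_a, b = far_b, c = far_c))
  expect_equal(interface_area(asm3, "a", "c"), 0, tolerance = 1)
  expect_equal(interface_area(asm3, "b", "c"), 0, tolerance = 1)
})

test_that("stoichiometry inference is exhaustive and matches brute force", {
  sol <- infer_stoichiometry(c(TBP = 20659, TAF = 40691), 61351,
                             tolerance = 2)
  expect_equal(nrow(sol), 1L)
  expect_equal(sol$TBP, 1L)
  expect_equal(sol$TAF, 1L)
  expect_equal(abs(sol$residual), 1)

  # complex mass equal to one component at zero tolerance
  sol2 <- infer_stoichiometry(c(A = 1000, B = 3333), 3333, tolerance = 0)
  expect_equal(nrow(sol2), 1L)
  expect_equal(sol2$B, 1L)
  expect_equal(sol2$A, 0L)

  # oracle equivalence on random instances (independent nested-loop search)
  set.seed(31)
  for (k in 1:10) {
    masses <- round(runif(3, 5000, 60000))
    names(masses) <- c("x", "y", "z")
    cm <- round(runif(1, 10000, 150000))
    tol <- 500
    got <- infer_stoichiometry(masses, cm, tol, max_copies = 3)
    want <- list()
    for (i in 0:3) for (j in 0:3) for (l in 0:3) {
      if (i + j + l == 0) next
      m <- i * masses[1] + j * masses[2] + l * masses[3]
      if (abs(m - cm) <= tol) want[[length(want) + 1]] <- c(i, j, l)
    }
    expect_equal(nrow(got), length(want))
    if (nrow(got) > 0) {
      got_keys <- sort(apply(got[, 1:3], 1, paste, collapse = "-"))
      want_keys <- sort(vapply(want, paste, "", collapse = "-"))
      expect_equal(got_keys, want_keys)
    }
  }

  # superset property: solutions at a smaller tolerance are contained in
  # those at a larger one
  lo <- infer_stoichiometry(c(a = 11111, b = 23456), 100000, tolerance = 300,
                            max_copies = 4)
  hi <- infer_stoichiometry(c(a = 11111, b = 23456), 100000, tolerance = 3000,
                            max_copies = 4)
  key <- function(df) paste(df$a, df$b)
  expect_true(all(key(lo) %in% key(hi)))
  expect_error(infer_stoichiometry(c(a = -5), 10, 1), "positive")
})

test_that("NSAF values implement length normalization and sum to one", {
  single <- nsaf(data.frame(protein = "A", spectral_count = 50, length = 300))
  expect_equal(single$nsaf, 1)

  two <- nsaf(data.frame(protein = c("A", "B"), spectral_count = c(10, 10),
                         length = c(100, 200)))
  expect_equal(two$nsaf, c(2 / 3, 1 / 3))

  base <- data.frame(protein = letters[1:4],
                     spectral_count = c(12, 55, 7, 120),
                     length = c(150, 420, 90, 800))
  expect_equal(sum(nsaf(base)$nsaf), 1, tolerance = 1e-9)
  scaled <- base; scaled$spectral_count <- scaled$spectral_count * 10
  expect_equal(nsaf(scaled)$nsaf, nsaf(base)$nsaf, tolerance = 1e-12)
  zero <- base; zero$spectral_count <- 0
  expect_error(nsaf(zero), "zero")
})

test_that("quality reports are complete, consistent and byte-stable", {
  scn <- scenario(seed = 5, n_receptor = 60, n_mobile = 50)
  toy <- make_toy_complex(scn)
  cs <- simulate_crosslinks(toy$assembly, n_links = 10, decoy_fraction = 0,
                            seed = 2)
  built <- build_restraints(deduplicate_links(cs), toy$assembly,
                            chain_map = c(receptor = "A", mobile = "B"))
  start <- structure(list(transform = toy$true_transform), class = "pose")
  res <- iterative_refine(start, toy$receptor, toy$mobile, built$restraints)

  # minimal input: valid document with explicit nulls for absent sections
  rep_min <- quality_report(res)
  expect_null(rep_min$satisfaction)
  expect_null(rep_min$saxs)
  txt <- jsonlite::toJSON(rep_min, auto_unbox = TRUE, null = "null")
  expect_true(jsonlite::validate(txt))

  # consistency: the report echoes the clms module's fraction exactly
  sat <- evaluate_satisfaction(res$assembly, built$restraints)
  rep_full <- quality_report(res, satisfaction = sat,
                             interface_areas = c(ab = 123.4),
                             config = list(seed = 5))
  expect_identical(rep_full$satisfaction$fraction, sat$fraction)
  expect_identical(rep_full$refinement$satisfaction, res$satisfaction)

  # regeneration is byte-identical
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  quality_report(res, satisfaction = sat, path = f1)
  quality_report(res, satisfaction = sat, path = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(quality_report(list()), "refinement_result")
})

test_that("the CLI front end answers io, dedup and stoichiometry queries", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ca_struct(matrix(rnorm(30), ncol = 3)), f)
  out <- capture.output(info <- intmod_cli(c("io", "info", f)))
  expect_equal(info$n_atoms, 10L)
  expect_equal(info$chains$A$n_residues, 10L)

  out2 <- capture.output(dd <- intmod_cli(c("clms", "dedup", bs3_fixture())))
  expect_equal(dd$n_unique, 36L)    # 9 + 5 + 22 pairs across the blocks

  out3 <- capture.output(st <- intmod_cli(
    c("ms", "stoich", "--components", "TBP=20659,TAF=40691",
      "--complex", "61351", "--tol", "2")))
  expect_equal(st$n_solutions, 1L)
  expect_error(intmod_cli("nope"), "usage")
})
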