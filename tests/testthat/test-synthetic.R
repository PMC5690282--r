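test_that("toy complexes have the stated geometry and are seed-pure", {
  scn <- scenario(seed = 7, n_receptor = 80, n_mobile = 40)
  toy <- make_toy_complex(scn)
  rc <- ca_matrix(toy$receptor)
  expect_equal(nrow(rc), 80L)
  steps <- sqrt(rowSums(diff(rc)^2))
  expect_true(all(abs(steps - 3.8) < 1e-3))
  # non-bonded self-avoidance
  dmat <- as.matrix(dist(rc))
  nb <- dmat[abs(row(dmat) - col(dmat)) > 1]
  expect_true(all(nb >= 4.0))
  # contact geometry of the true pose
  mob <- apply_transform(ca_matrix(toy$mobile), toy$true_transform)
  cross <- matrix(intmod:::cpp_cross_distances(rc, mob), nrow = nrow(rc))
  expect_gte(min(cross), 4.0)
  expect_gte(sum(cross < 12), 30)

  expect_identical(make_toy_complex(scn), toy)   # determinism
  expect_error(scenario(n_receptor = 10), ">= 20")

  # compactness bias: Rg within 20% of 2.2 n^0.38 across seeds (scaled to
  # 10 seeds to stay inside the test budget)
  ratios <- sapply(1:10, function(sd) {
    t2 <- make_toy_complex(scenario(seed = sd, n_receptor = 60,
                                    n_mobile = 30))
    radius_of_gyration(ca_matrix(t2$receptor)) / (2.2 * 60^0.38)
  })
  expect_true(all(ratios > 0.8 & ratios < 1.2))
})

test_that("simulated cross-links honour decoy arithmetic and truth labels", {
  # decoys need >50 A inter-domain pairs, so use the larger stated sizes
  scn <- scenario(seed = 5, n_receptor = 120, n_mobile = 100)
  toy <- make_toy_complex(scn)

  cs0 <- simulate_crosslinks(toy$assembly, n_links = 15, decoy_fraction = 0,
                             seed = 2)
  built <- build_restraints(deduplicate_links(cs0), toy$assembly,
                            chain_map = c(receptor = "A", mobile = "B"))
  rep0 <- evaluate_satisfaction(toy$assembly, built$restraints)
  expect_equal(rep0$fraction, 1)                # construction guarantee

  cs <- simulate_crosslinks(toy$assembly, n_links = 20, decoy_fraction = 0.1,
                            seed = 3)
  truth <- attr(cs, "truth")
  expect_equal(sum(truth$is_decoy), 2L)         # exactly round(20 * 0.1)
  expect_equal(nrow(truth), 20L)
  expect_true(all(truth$distance[!truth$is_decoy] <= 30))
  expect_true(all(truth$distance[truth$is_decoy] > 50))
  # BS3-like distances: mean near the 11.4 A chemistry mean
  expect_equal(mean(truth$distance[!truth$is_decoy]), 11.4, tolerance = 0.2)
  # scores span a plausible match-score range
  expect_true(all(cs$score >= 3))

  # deduplication recovers the CSM multiplicities
  dd <- deduplicate_links(cs)
  expect_equal(nrow(dd), 20L)
  expect_equal(sum(dd$n_matches), nrow(cs))

  expect_identical(simulate_crosslinks(toy$assembly, 20, "BS3", 0.1, seed = 3),
                   cs)
})

test_that("simulated SAXS curves are Debye-exact at zero noise and calibrated", {
  scn <- scenario(seed = 5, n_receptor = 60, n_mobile = 50)
  toy <- make_toy_complex(scn)
  s <- seq(0.003, 0.3, length.out = 80)

  clean <- simulate_saxs(toy$assembly, s_grid = s, noise_fraction = 0)
  ideal <- debye_profile(toy$assembly, s)
  expect_equal(clean$intensity, ideal$intensity)

  # Guinier Rg of the noiseless curve tracks the coordinate-space Rg
  # (electron-weighted, matching the scattering contrast)
  bd <- scattering_beads(toy$assembly)
  rg_coord <- radius_of_gyration(bd$coords, bd$weights)
  expect_equal(guinier_fit(clean)$Rg, rg_coord, tolerance = 0.02)

  # chi-square of the generating model against noisy replicates ~ 1
  ch <- sapply(1:25, function(sd) {
    noisy <- simulate_saxs(toy$assembly, s_grid = s, noise_fraction = 0.03,
                           seed = sd)
    chi_square(ideal, noisy)
  })
  expect_equal(mean(ch), 1, tolerance = 0.15)
  expect_identical(simulate_saxs(toy$assembly, s_grid = s, seed = 9),
                   simulate_saxs(toy$assembly, s_grid = s, seed = 9))
})

test_that("simulated HDX tables carry the interface signal at stated coverage", {
  iface <- 20:35
  pep <- simulate_hdx(100, iface, effect = -15, coverage = 2, seed = 4)
  expect_true(all(pep$end >= pep$start))
  lens <- pep$end - pep$start + 1
  expect_true(all(lens >= 5 & lens <= 13 | pep$end == 100))
  # every residue covered by at least `coverage` peptides
  m <- residue_protection_map(pep)
  expect_true(all(m$coverage[m$residue <= 100] >= 2))

  # power: strong protection effect is detected (peptide-level permutation,
  # the calibrated null for peptide-generated data)
  det <- sapply(1:5, function(sd) {
    p <- simulate_hdx(100, iface, effect = -15, coverage = 2, seed = sd)
    interface_enrichment_test(residue_protection_map(p), iface,
                              n_permutations = 2000, seed = sd,
                              peptides = p)$p_value
  })
  expect_true(all(det < 0.01))

  # null: with peptide-level (block) permutation the test is calibrated
  # under effect 0; residue-level permutation is anti-conservative on
  # peptide-correlated noise and is calibrated against iid residue scores
  # in the acceptance suite instead
  nulls <- sapply(1:40, function(sd) {
    p <- simulate_hdx(100, iface, effect = 0, coverage = 2, seed = 100 + sd)
    interface_enrichment_test(residue_protection_map(p), iface,
                              n_permutations = 200, seed = sd,
                              peptides = p)$p_value
  })
  expect_gt(mean(nulls), 0.3)
  expect_lt(mean(nulls), 0.7)
  expect_lte(mean(nulls < 0.05), 0.125)
  expect_identical(simulate_hdx(50, 5:10, seed = 3),
                   simulate_hdx(50, 5:10, seed = 3))
})

test_that("scenario directories serialize every fixture for a run", {
  dir <- withr::local_tempdir()
  scn <- scenario(seed = 11, n_receptor = 40, n_mobile = 30, n_links = 8,
                  decoy_fraction = 0)
  write_scenario(scn, dir)
  files <- c("receptor.pdb", "mobile.pdb", "links.csv", "curve.dat",
             "hdx.csv", "truth.json")
  expect_true(all(file.exists(file.path(dir, files))))
  rec <- read_structure(file.path(dir, "receptor.pdb"))
  expect_equal(nrow(rec), 40L)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$scenario$seed, 11L)
  expect_equal(dim(matrix(unlist(truth$true_transform$rotation), 3, 3)),
               c(3L, 3L))
})
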