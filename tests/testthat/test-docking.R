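# docking uses a shared small synthetic complex so the expensive generator
# runs once per file
scn_d <- scenario(seed = 5, n_receptor = 60, n_mobile = 50, n_links = 15,
                  decoy_fraction = 0)
toy_d <- make_toy_complex(scn_d)
csms_d <- simulate_crosslinks(toy_d$assembly, n_links = 15,
                              decoy_fraction = 0, seed = scn_d$seed + 1L)
built_d <- build_restraints(deduplicate_links(csms_d), toy_d$assembly,
                            chain_map = c(receptor = "A", mobile = "B"))

test_that("pose scoring matches the energy formula and decomposition", {
  rec <- ca_struct(rbind(c(0, 0, 0), c(40, 0, 0)), chain = "A")
  mob <- ca_struct(rbind(c(0, 10, 0), c(40, 10, 0)), chain = "B")
  asm <- new_assembly(list(r = rec, m = mob),
                      roles = c(r = "receptor", m = "mobile"))
  rs <- make_restraints(c("A", "A"), 1:2, c("B", "B"), 1:2)
  p <- score_pose(asm, rs)
  expect_equal(p$score_total, 0)     # all within target, no pair under 4 A
  expect_equal(p$satisfaction, 1)

  # single restraint at target + 2 -> (2)^2 * weight
  mob2 <- ca_struct(rbind(c(0, 13.4, 0), c(200, 0, 0)), chain = "B")
  asm2 <- new_assembly(list(r = rec, m = mob2),
                       roles = c(r = "receptor", m = "mobile"))
  rs1 <- make_restraints("A", 1, "B", 1, weight = 2)
  p2 <- score_pose(asm2, rs1)
  expect_equal(p2$score_restraint, 4 * 2)
  expect_equal(p2$score_total, p2$score_restraint + p2$score_clash)

  # clash term: one pair at 3 A -> (4-3)^2 * clash_weight
  mob3 <- ca_struct(rbind(c(0, 3, 0), c(200, 0, 0)), chain = "B")
  asm3 <- new_assembly(list(r = rec, m = mob3),
                       roles = c(r = "receptor", m = "mobile"))
  p3 <- score_pose(asm3, rs1,
                   clash_params = list(clash_dist = 4, clash_weight = 300,
                                       outlier_slope = 1,
                                       contact_weight = 0,
                                       contact_range = 10,
                                       flat_bottom = TRUE))
  expect_equal(p3$score_clash, 300)
})

test_that("the true pose scores no worse than random poses (noiseless links)", {
  p_true <- score_pose(toy_d$assembly, built_d$restraints)
  set.seed(77)
  worse <- replicate(100, {
    tr <- rigid_transform(random_rotation(), rnorm(3, 0, 25))
    asm <- set_mobile_transform(toy_d$assembly, tr)
    score_pose(asm, built_d$restraints)$score_total
  })
  expect_true(all(p_true$score_total <= worse))
  expect_equal(p_true$satisfaction, 1)  # simulator guarantees d <= cutoff
})

test_that("local refinement descends deterministically and never worsens", {
  start <- structure(list(transform = toy_d$true_transform), class = "pose")
  ref1 <- local_refine(start, toy_d$receptor, toy_d$mobile,
                       built_d$restraints)
  p_true <- score_pose(toy_d$assembly, built_d$restraints)
  expect_lte(ref1$score_total, p_true$score_total)
  # descent is monotone across repeated calls, and a pose already at a
  # minimum (zero energy on noiseless links) is returned unchanged
  ref2 <- local_refine(ref1, toy_d$receptor, toy_d$mobile, built_d$restraints,
                       max_evals = 4000)
  expect_lte(ref2$score_total, ref1$score_total)
  expect_lt(ref2$score_total, 1e-6)
  ref3 <- local_refine(ref2, toy_d$receptor, toy_d$mobile, built_d$restraints)
  expect_equal(ref3$score_total, ref2$score_total, tolerance = 1e-9)
  expect_identical(ref3$transform, ref2$transform)
  # determinism
  ref1b <- local_refine(start, toy_d$receptor, toy_d$mobile,
                        built_d$restraints)
  expect_identical(ref1$transform, ref1b$transform)
})

test_that("pose sampling is seeded, deduplicated, ranked, and validated", {
  a <- sample_poses(toy_d$receptor, toy_d$mobile, built_d$restraints,
                    n_starts = 4, seed = 42, max_evals = 100)
  b <- sample_poses(toy_d$receptor, toy_d$mobile, built_d$restraints,
                    n_starts = 4, seed = 42, max_evals = 100)
  expect_identical(a, b)                         # bit-identical given seed
  scores <- vapply(a, `[[`, 0.0, "score_total")
  expect_true(all(diff(scores) >= 0))            # ranked ascending
  one <- sample_poses(toy_d$receptor, toy_d$mobile, built_d$restraints,
                      n_starts = 1, seed = 7, max_evals = 100)
  expect_length(one, 1L)
  # intra-body-only restraints cannot drive docking
  rs_intra <- make_restraints("A", 1, "A", 5)
  expect_error(sample_poses(toy_d$receptor, toy_d$mobile, rs_intra,
                            n_starts = 1, seed = 1), "links the two bodies")
})

test_that("iterative refinement stops honestly in all three regimes", {
  start <- structure(list(transform = toy_d$true_transform), class = "pose")
  # noiseless restraints from the true pose: converges immediately at 1.0
  res <- iterative_refine(start, toy_d$receptor, toy_d$mobile,
                          built_d$restraints)
  expect_equal(res$stop_reason, "converged_satisfaction")
  expect_equal(res$satisfaction, 1)
  expect_lte(res$n_iterations, 2L)

  # one decoy in twenty: converges with the decoy still violated (>= 0.95);
  # needs a larger complex so >50 A decoy pairs exist
  scn_big <- scenario(seed = 5, n_receptor = 120, n_mobile = 100)
  toy_big <- make_toy_complex(scn_big)
  csms_1d <- simulate_crosslinks(toy_big$assembly, n_links = 20,
                                 decoy_fraction = 0.05,
                                 seed = scn_big$seed + 1L)
  built_1d <- build_restraints(deduplicate_links(csms_1d), toy_big$assembly,
                               chain_map = c(receptor = "A", mobile = "B"))
  start_big <- structure(list(transform = toy_big$true_transform),
                         class = "pose")
  res1 <- iterative_refine(start_big, toy_big$receptor, toy_big$mobile,
                           built_1d$restraints)
  expect_equal(res1$stop_reason, "converged_satisfaction")
  expect_gte(res1$satisfaction, 0.95)

  # contradictory restraints at threshold 1.0: runs out of iterations,
  # never throws
  rec2 <- ca_struct(rbind(c(0, 0, 0), c(100, 0, 0)), chain = "A")
  mob2 <- ca_struct(matrix(c(0, 5, 0), 1), chain = "B")
  rs2 <- make_restraints(c("A", "A"), c(1, 2), c("B", "B"), c(1, 1),
                         target = 5, upper = 8)
  st2 <- structure(list(transform = transform_identity()), class = "pose")
  res2 <- iterative_refine(st2, rec2, mob2, rs2,
                           satisfaction_threshold = 1.0, max_iterations = 5)
  expect_equal(res2$stop_reason, "max_iterations")
  expect_lt(res2$satisfaction, 1)
  expect_equal(res2$n_iterations, 5L)
})

test_that("scores and satisfaction are invariant under global rigid motion", {
  p0 <- score_pose(toy_d$assembly, built_d$restraints)
  set.seed(13)
  for (k in 1:5) {
    g <- rigid_transform(random_rotation(), rnorm(3, 0, 40))
    asm <- toy_d$assembly
    asm$transforms$receptor <- g
    asm$transforms$mobile <- transform_compose(g, toy_d$true_transform)
    # score via the public surface on physically moved copies
    rec_g <- apply_transform(toy_d$receptor, g)
    mob_g <- toy_d$mobile
    asm_g <- new_assembly(list(receptor = rec_g, mobile = mob_g),
                          transforms = list(
                            receptor = transform_identity(),
                            mobile = transform_compose(g, toy_d$true_transform)),
                          roles = c(receptor = "receptor", mobile = "mobile"))
    pg <- score_pose(asm_g, built_d$restraints)
    expect_equal(pg$score_total, p0$score_total, tolerance = 1e-6)
    expect_equal(pg$satisfaction, p0$satisfaction)
  }
})

test_that("SAXS gating keeps refinement from degrading the scattering fit", {
  curve <- simulate_saxs(toy_d$assembly, noise_fraction = 0.02,
                         seed = scn_d$seed + 2L)
  start <- structure(list(transform = toy_d$true_transform), class = "pose")
  res <- iterative_refine(start, toy_d$receptor, toy_d$mobile,
                          built_d$restraints, saxs_target = curve)
  expect_equal(res$stop_reason, "converged_satisfaction")
  expect_true(all(is.finite(res$chi2)))
  # no accepted iteration worsened chi2 by more than 20%
  if (length(res$chi2) > 1) {
    expect_true(all(diff(res$chi2) <= 0.2 * res$chi2[-length(res$chi2)] + 1e-9))
  }
})
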