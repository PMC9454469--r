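# Labeled-cell selection, activity sampling and radial profiles.

small_pop <- function(depth = Inf) {
  build_population(cluster_spec("sphere", list(radius = 40), 13, ref_cell(),
                                penetration_depth_um = depth))
}

test_that("labeled selection honors the request, clamps, and is seed-stable", {
  pop <- small_pop()
  p1 <- select_labeled(pop, 100, seed = 1)
  expect_true(all(p1$labeled))
  p2 <- select_labeled(pop, 50, seed = 1)
  expect_equal(sum(p2$labeled), round(0.5 * nrow(pop)))
  expect_true(all(p2$eligible[p2$labeled]))
  p3 <- select_labeled(pop, 50, seed = 1)
  expect_identical(p2$labeled, p3$labeled)
  p4 <- select_labeled(pop, 50, seed = 2)
  expect_equal(sum(p4$labeled), sum(p2$labeled))
  expect_false(identical(p2$labeled, p4$labeled))
  # drug-penetration cap: requesting 100 % of all cells exceeds the rim
  rim <- small_pop(depth = 12)
  expect_warning(p5 <- select_labeled(rim, 100, seed = 1), "clamping")
  expect_equal(sum(p5$labeled), sum(rim$eligible))
})

test_that("activity sampling matches its distributional contracts", {
  a <- sample_activities("uniform", 0.02, n = 10, seed = 1)
  expect_equal(a, rep(0.02, 10))
  # lognormal: the -sigma^2/2 shift makes E[A] equal the requested mean
  for (sg in c(0.5, 1, 2)) {
    a <- sample_activities("lognormal", 1.0, sigma = sg, n = 1e5, seed = 1)
    expect_true(all(a > 0))
    se <- sd(a) / sqrt(length(a))
    expect_lt(abs(mean(a) - 1.0), 3 * se)
  }
  # normal: sample SD ~ sigma when truncation is negligible
  a <- sample_activities("normal", 1.0, sigma = 0.05, n = 1e5, seed = 1)
  expect_true(all(a > 0))
  expect_equal(sd(a), 0.05, tolerance = 0.02)
  expect_equal(mean(a), 1.0, tolerance = 0.005)
  expect_error(sample_activities("normal", 1, sigma = -1, n = 5), "sigma")
})

test_that("radial profiles obey their closed forms", {
  lin <- radial_profile("radial_linear", c(0, 2))
  expect_equal(lin(0), 0)           # linear through zero: centre gets zero
  expect_equal(lin(10), 20)
  # degree-0 polynomial is the uniform profile
  p0 <- radial_profile("radial_polynomial", 3)
  expect_equal(p0(c(0, 5, 50)), rep(3, 3))
  expect_error(radial_profile("radial_polynomial", rep(1, 12)), "degree")
  p2 <- radial_profile("radial_polynomial", c(1, 0, 2))
  expect_equal(p2(3), 1 + 2 * 9)
  # continuous exponential decays inward from the anchor radius
  ex <- radial_profile("radial_exponential", 0.4, R_ref = 100)
  expect_equal(ex(100), 1)
  expect_equal(ex(90), exp(-4), tolerance = 1e-12)
  # layered evaluation: one shared value per whole cell layer
  exl <- radial_profile("radial_exponential", 0.4, R_ref = 100, layer_um = 12)
  expect_equal(exl(c(100, 95, 89, 87)), c(1, 1, 1, exp(-0.4 * 12)))
  # 4-parameter lognormal is non-negative and vanishes at its offset
  ln4 <- radial_profile("radial_lognormal4", c(2, 10, 5, 0.5))
  expect_equal(ln4(5), 0)
  expect_equal(ln4(15), 2)          # peak at c + b
  expect_true(all(ln4(seq(0, 100, by = 0.5)) >= 0))
})

test_that("assignment scales radial patterns to the activity cap and dilutes with labeling", {
  pop <- small_pop()
  spec_u <- activity_spec("uniform", mean_activity_Bq = 0.02)
  all_lab <- assign_activity(select_labeled(pop, 100, 1), spec_u)
  expect_equal(mean(all_lab$activity_Bq), 0.02)
  half <- assign_activity(select_labeled(pop, 50, 1), spec_u)
  expect_equal(mean(half$activity_Bq), 0.02 * sum(half$labeled) / nrow(half))
  # fixed seed reproduces the full assignment bit for bit
  spec_ln <- activity_spec("lognormal", mean_activity_Bq = 0.02, sigma = 1)
  a1 <- assign_activity(select_labeled(pop, 80, 3), spec_ln, seed = 3)
  a2 <- assign_activity(select_labeled(pop, 80, 3), spec_ln, seed = 3)
  expect_identical(a1$activity_Bq, a2$activity_Bq)
  expect_equal(sum(a1$activity_Bq == 0), nrow(pop) - sum(a1$labeled))
  # radial: the maximum over labeled cells equals the cap exactly
  spec_r <- activity_spec("radial_linear", radial_params = c(0, 1),
                          max_mean_activity_Bq = 0.05)
  ar <- assign_activity(select_labeled(pop, 100, 1), spec_r)
  expect_equal(max(ar$activity_Bq[ar$labeled]), 0.05)
})

test_that("a single labeled outer layer gets identical activities for any exponential factor", {
  rim <- suppressWarnings(select_labeled(small_pop(depth = 12), 100, seed = 1))
  for (k in c(0.1, 0.4, 2)) {
    spec <- activity_spec("radial_exponential", radial_params = k,
                          max_mean_activity_Bq = 0.02)
    a <- assign_activity(rim, spec)
    expect_equal(unique(a$activity_Bq[a$labeled]), 0.02)
  }
})

test_that("geometry restrictions on radial methods are enforced", {
  cm <- ref_cell()
  ell <- build_population(cluster_spec(
    "ellipsoid", list(semi_x = 60, semi_y = 45, semi_z = 45), 13, cm))
  ell <- select_labeled(ell, 100, 1)
  spec_r <- activity_spec("radial_exponential", radial_params = 0.4,
                          max_mean_activity_Bq = 0.02)
  expect_error(assign_activity(ell, spec_r), "ellipsoid")
  rod <- select_labeled(build_population(
    cluster_spec("rod", list(radius = 40, length = 80), 13, cm)), 100, 1)
  tab <- data.frame(radius_um = c(0, 50), relative_activity = c(1, 2))
  spec_t <- activity_spec("radial_user_table", radial_params = tab,
                          max_mean_activity_Bq = 0.02)
  expect_error(assign_activity(rod, spec_t), "spherical")
  # user table works on spheres, interpolating linearly
  sph <- select_labeled(small_pop(), 100, 1)
  at <- assign_activity(sph, spec_t)
  expect_equal(max(at$activity_Bq), 0.02)
  expect_true(all(at$activity_Bq > 0))
})

test_that("negative radial profiles over the labeled range are rejected", {
  sph <- select_labeled(small_pop(), 100, 1)
  spec_bad <- activity_spec("radial_linear", radial_params = c(-1, 0.001),
                            max_mean_activity_Bq = 0.02)
  expect_error(assign_activity(sph, spec_bad), "negative")
})
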