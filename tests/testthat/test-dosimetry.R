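# Decay accounting, per-cell dose accumulation and radial summaries.

test_that("decay counts follow activity x tau x 3600", {
  expect_equal(decays_per_cell(0, 5), 0)
  expect_equal(decays_per_cell(1, 1), 3600)
  expect_equal(decays_per_cell(0.02, 1.11), 79.92)
  expect_error(decays_per_cell(-1, 1), ">= 0")
  expect_error(decays_per_cell(1, 0), "> 0")
})

# Small two-cell fixture with a single labeled cell or both labeled.
pair_doses <- function(spectrum, both = FALSE, tau = 1) {
  cm <- ref_cell()
  pop <- build_population(cluster_spec("pair", spacing_um = 13, cell = cm))
  pop$labeled <- c(TRUE, both)
  pop$activity_Bq <- c(0.01, if (both) 0.01 else 0)
  attr(pop, "subcell") <- subcellular_split(f_CS = 1)
  d <- celldose:::lattice_distances(pop, 1e4)
  tab <- s_table(spectrum, cm, d, sources = "CS", targets = "N")
  compute_doses(pop, tab, tau_hours = tau, target = "N")
}

test_that("an isolated labeled cell has zero cross dose; labeled pairs are symmetric", {
  d1 <- pair_doses(e50(), both = FALSE)
  expect_gt(d1$self_Gy[1], 0)
  expect_equal(d1$cross_Gy[1], 0)
  expect_equal(d1$self_Gy[2], 0)
  expect_gt(d1$cross_Gy[2], 0)
  d2 <- pair_doses(e50(), both = TRUE)
  expect_equal(d2$cross_Gy[1], d2$cross_Gy[2])
  expect_equal(d2$total_Gy[1], d2$total_Gy[2])
})

test_that("doses are linear in activity", {
  cm <- ref_cell()
  pop <- build_population(cluster_spec("sphere", list(radius = 30), 13, cm))
  pop <- assign_activity(select_labeled(pop, 100, 1),
                         activity_spec("uniform", mean_activity_Bq = 0.01),
                         subcellular_split(f_CS = 1))
  d <- celldose:::lattice_distances(pop, 200)
  tab <- s_table(a5(), cm, d, sources = "CS", targets = "N")
  d1 <- compute_doses(pop, tab, tau_hours = 1, target = "N")
  pop2 <- pop; pop2$activity_Bq <- 3 * pop$activity_Bq
  d3 <- compute_doses(pop2, tab, tau_hours = 1, target = "N")
  expect_equal(d3$total_Gy, 3 * d1$total_Gy, tolerance = 1e-12)
  # and linear in tau as well
  dt <- compute_doses(pop, tab, tau_hours = 3, target = "N")
  expect_equal(dt$total_Gy, d3$total_Gy, tolerance = 1e-12)
})

test_that("cluster-level energy bookkeeping matches brute-force Monte Carlo", {
  # One labeled cell at the centre of a touching-sphere lattice, 4-MeV
  # alpha source in the nucleus.  The summed (dose x mass) over all cell
  # targets must equal the Monte Carlo tally of energy landing in the
  # same spheres.
  cm <- cell_model(6, 5)
  sp <- make_monoenergetic("alpha", 4.0)
  pop <- build_population(cluster_spec("sphere", list(radius = 48), 12, cm))
  ctr <- which.min(pop$r)
  pop$labeled <- seq_len(nrow(pop)) == ctr
  pop$activity_Bq <- ifelse(pop$labeled, 1, 0)
  attr(pop, "subcell") <- subcellular_split(f_N = 1, f_Cy = 0, f_CS = 0)
  dists <- celldose:::lattice_distances(pop, 26 + 12)
  tab <- s_table(sp, cm, dists, sources = "N", targets = "C")
  doses <- compute_doses(pop, tab, tau_hours = 1 / 3600, target = "C")
  analytic_MeV <- sum(doses$total_Gy) * region_mass(cm, "C") /
    1.602176634e-13   # one decay (tau h = 1/3600 -> 1 transition)
  # independent tally: energy deposited in every lattice sphere
  centres <- as.matrix(pop[, c("x", "y", "z")])
  centres <- sweep(centres, 2, as.numeric(pop[ctr, c("x", "y", "z")]))
  model <- range_energy_model("alpha")
  set.seed(31)
  n <- 2e4
  P <- celldose:::sample_source_points(cm, "N", n)
  W <- celldose:::sample_directions(n)
  mc_MeV <- 0
  for (i in seq_len(nrow(centres))) {
    if (sqrt(sum(centres[i, ]^2)) > 26 + 12) next
    mc_MeV <- mc_MeV +
      mean(celldose:::deposit_in_sphere(model, 4.0, P, W, centres[i, ], 6))
  }
  expect_equal(analytic_MeV, mc_MeV, tolerance = 0.02)
  # and the absorbed share is a sizeable but sub-unity fraction of E0
  expect_gt(analytic_MeV, 1); expect_lt(analytic_MeV, 4)
})

test_that("missing lattice distances in the S table are a hard error", {
  cm <- ref_cell()
  pop <- build_population(cluster_spec("sphere", list(radius = 30), 13, cm))
  pop$labeled <- rep(TRUE, nrow(pop))
  pop$activity_Bq <- rep(0.01, nrow(pop))
  attr(pop, "subcell") <- subcellular_split(f_CS = 1)
  tab <- s_table(a5(), cm, 13, sources = "CS", targets = "N")  # only d = 13
  expect_error(compute_doses(pop, tab, tau_hours = 1, target = "N"),
               "missing from the S table")
})

test_that("radial summaries report the six per-bin statistics with NA for empty bins", {
  cfg <- small_sphere_config()
  cfg$cluster$penetration_depth_um <- 12
  res <- suppressWarnings(run(cfg))
  rs <- radial_summary(res$doses, bin_width_um = 13)
  expect_named(rs, c("r_lo_um", "r_hi_um", "n_cells", "n_labeled",
                     "mean_activity_labeled_Bq", "mean_self_dose_labeled_Gy",
                     "mean_cross_dose_labeled_Gy",
                     "mean_cross_dose_unlabeled_Gy",
                     "mean_decays_labeled", "mean_dose_all_Gy"))
  expect_equal(sum(rs$n_cells), nrow(res$population))
  # interior bins hold no labeled cells: their labeled statistics are NA
  inner <- rs$n_labeled == 0
  expect_true(any(inner))
  expect_true(all(is.na(rs$mean_activity_labeled_Bq[inner])))
  # mean dose to all cells is bounded by the per-cell extremes
  for (b in which(rs$n_cells > 0)) {
    sel <- floor(res$population$r / 13) == b - 1
    expect_gte(rs$mean_dose_all_Gy[b], min(res$doses$total_Gy[sel]))
    expect_lte(rs$mean_dose_all_Gy[b], max(res$doses$total_Gy[sel]))
  }
  expect_error(radial_summary(res$doses, 0), "> 0")
})
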