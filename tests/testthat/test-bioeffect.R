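# LQ survival, Monte Carlo fates, SF curves and TCP.

test_that("simple LQ survival follows the closed form", {
  p <- lq_simple(alpha_self = 1, beta_self = 0.1,
                 alpha_cross = 0.5, beta_cross = 0)
  expect_equal(survival_simple(0, 0, p), 1)
  # D0-style pure-exponential response: alpha = 1/1.8 at D = 1.8 gives 1/e
  p18 <- lq_simple(alpha_self = 1 / 1.8, beta_self = 0)
  expect_equal(survival_simple(1.8, 0, p18), exp(-1))
  # a quadratic cross term strictly lowers survival
  pq <- lq_simple(alpha_self = 0, beta_self = 0,
                  alpha_cross = 0.3, beta_cross = 0.05)
  expect_lt(survival_simple(0, 2, pq), exp(-0.3 * 2))
  expect_error(survival_simple(-1, 0, p), ">= 0")
})

test_that("LQ tables validate, override, and round-trip losslessly", {
  tab <- default_lq_table()
  expect_true(isTRUE(attr(tab, "default")))
  expect_true(all(tab$alpha == 0.1) && all(tab$beta == 0.01))
  tab2 <- set_lq(tab, icode = "alpha", alpha = 0.56, beta = 0)
  expect_false(isTRUE(attr(tab2, "default")))
  expect_true(all(tab2$alpha[tab2$icode == "alpha"] == 0.56))
  expect_true(all(tab2$alpha[tab2$icode != "alpha"] == 0.1))
  expect_error(set_lq(tab, icode = "nope", alpha = 1), "no LQ table rows")
  f <- withr::local_tempfile(fileext = ".csv")
  write_lq_table(tab2, f)
  tab3 <- read_lq_table(f)
  expect_equal(as.data.frame(tab3), as.data.frame(tab2))
})

# A dose_result whose components give every cell the same single-icode dose.
uniform_dose_result <- function(D_self, D_cross = 0, n = 50) {
  cm <- ref_cell()
  pop <- build_population(cluster_spec("sphere", list(radius = 40), 13, cm))
  pop <- pop[seq_len(min(n, nrow(pop))), ]
  class(pop) <- c("cell_population", "data.frame")
  n <- nrow(pop)
  combos <- data.frame(icode = "alpha", source = "CS")
  structure(list(
    cells = pop, target = "N", combos = combos,
    dose_self = matrix(D_self, n, 1), dose_cross = matrix(D_cross, n, 1),
    self_Gy = rep(D_self, n), cross_Gy = rep(D_cross, n),
    total_Gy = rep(D_self + D_cross, n), tau_hours = 1,
    subcell = subcellular_split(f_CS = 1)), class = "dose_result")
}

test_that("the complex model reduces to the simple model for one matched component", {
  dr <- uniform_dose_result(1.3, 0.7)
  tab <- set_lq(default_lq_table(), alpha = 0.4, beta = 0.03)
  P <- survival_complex(dr, tab)
  ps <- lq_simple(0.4, 0.03, 0.4, 0.03)
  expect_equal(P, rep(survival_simple(1.3, 0.7, ps), nrow(dr$cells)))
  # all-zero doses survive with probability one
  expect_equal(survival_complex(uniform_dose_result(0, 0), tab),
               rep(1, 50))
})

test_that("a missing LQ parameter for a present component is a hard error", {
  dr <- uniform_dose_result(1, 0)
  tab <- default_lq_table()
  tab <- tab[!(tab$icode == "alpha" & tab$self_or_cross == "self"), ]
  class(tab) <- c("lq_table", "data.frame")
  attr(tab, "default") <- FALSE
  expect_error(survival_complex(dr, tab), "missing")
})

test_that("untouched default LQ parameters warn at compute time", {
  dr <- uniform_dose_result(1, 0)
  expect_warning(survival_complex(dr, default_lq_table()), "default")
})

test_that("Monte Carlo fates realize the probabilities", {
  expect_equal(monte_carlo_fates(rep(1, 100), 1)$SF, 1)
  expect_equal(monte_carlo_fates(rep(0, 100), 1)$SF, 0)
  f <- monte_carlo_fates(rep(0.5, 1e4), 1)
  expect_lt(abs(f$SF - 0.5), 5 * sqrt(0.25 / 1e4))
  expect_identical(monte_carlo_fates(rep(0.3, 1000), 9)$alive,
                   monte_carlo_fates(rep(0.3, 1000), 9)$alive)
  expect_error(monte_carlo_fates(c(0.5, 1.2), 1))
})

test_that("TCP formulations agree on their closed forms and identities", {
  expect_equal(tcp(rep(0.5, 2), SF = 0.5)$tcp_poisson, 0.25)
  expect_equal(tcp(rep(0, 5), SF = 0)$tcp_poisson, 1)
  expect_equal(tcp(c(1, 0.2))$tcp_product, 0)
  # equal probabilities: the two formulas coincide at (1 - p)^n
  p <- 0.37; n <- 40
  t2 <- tcp(rep(p, n))
  expect_equal(t2$tcp_poisson, (1 - p)^n)
  expect_equal(t2$tcp_product, (1 - p)^n)
  # heterogeneous probabilities at fixed mean: the product lies below the
  # Poisson value (AM-GM on the 1 - p_i)
  th <- tcp(c(0.9, 0.1), SF = 0.5)
  expect_lt(th$tcp_product, th$tcp_poisson)
  expect_equal(th$tcp_product, 0.9 * 0.1)
})

test_that("SF curves start at one, decrease in expectation, and recover the LQ closed form", {
  # uniform self-dose-only cluster: a very short-range electron source in
  # the nucleus, all cells identically labeled
  cm <- ref_cell()
  sp <- make_monoenergetic("electron", 0.003)
  pop <- build_population(cluster_spec("sphere", list(radius = 40), 13, cm))
  pop <- assign_activity(select_labeled(pop, 100, 1),
                         activity_spec("uniform", mean_activity_Bq = 0.01),
                         subcellular_split(f_N = 1, f_Cy = 0, f_CS = 0))
  dists <- celldose:::lattice_distances(pop, csda_range(
    range_energy_model("electron"), 0.003) + 12)
  tab <- s_table(sp, cm, dists, sources = "N", targets = "N")
  doses <- compute_doses(pop, tab, tau_hours = 2, target = "N")
  expect_equal(doses$cross_Gy, rep(0, nrow(pop)))   # self-dose only
  lq <- lq_simple(alpha_self = 0.35, beta_self = 0.04)
  curve <- sf_curve(doses, lq, n_points = 11, seed = 5)
  expect_equal(curve$sf_expected[1], 1)
  expect_equal(curve$sf_mc[1], 1)
  expect_true(all(diff(curve$sf_expected) <= 1e-12))
  D <- curve$mean_dose_all_Gy
  expect_equal(curve$sf_expected, exp(-0.35 * D - 0.04 * D^2),
               tolerance = 1e-12)
  # activity domains scale linearly along the sweep
  expect_equal(curve$mean_activity_per_cell_Bq,
               seq(0, 0.01, length.out = 11))
  expect_equal(curve$mean_decays_per_cell,
               seq(0, 0.01 * 2 * 3600, length.out = 11))
  # the MC column tracks the expectation within binomial noise
  expect_lt(max(abs(curve$sf_mc - curve$sf_expected)),
            5 * sqrt(0.25 / nrow(pop)))
})
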