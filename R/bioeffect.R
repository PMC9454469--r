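# Bioeffect modeling: linear-quadratic survival (simple and
# radiation-type-resolved), Monte Carlo cell fates, surviving-fraction
# curves over activity sweeps, and tumor control probability.

#' Simple LQ parameter set
#'
#' @param alpha_self,beta_self LQ coefficients for self-dose (1/Gy, 1/Gy^2).
#' @param alpha_cross,beta_cross LQ coefficients for cross-dose.
#' @return an object of class `lq_simple`.
#' @export
lq_simple <- function(alpha_self, beta_self = 0,
                      alpha_cross = alpha_self, beta_cross = beta_self) {
  p <- c(alpha_self = alpha_self, beta_self = beta_self,
         alpha_cross = alpha_cross, beta_cross = beta_cross)
  if (any(p < 0)) stop("LQ parameters must be >= 0")
  structure(as.list(p), class = "lq_simple")
}

#' Alpha coefficient from a mean lethal dose
#'
#' With beta = 0 the LQ model reduces to `exp(-D/D0)`; the linear
#' coefficient is the reciprocal of the mean lethal dose D0.
#'
#' @param D0_Gy mean lethal dose (Gy), > 0.
#' @return alpha in 1/Gy.
#' @export
alpha_from_d0 <- function(D0_Gy) {
  stopifnot(D0_Gy > 0)
  1 / D0_Gy
}

#' Complex LQ parameter table
#'
#' One (alpha, beta) pair per (radiation type, source region, self|cross,
#' target region) combination.  The shipped defaults (alpha = 0.1 1/Gy,
#' beta = 0.01 1/Gy^2 everywhere) are arbitrary placeholders: using them
#' unmodified at compute time emits a warning.
#'
#' @param targets target regions to include.
#' @param alpha,beta default values filled into every row.
#' @return an object of class `lq_table`: a data frame with columns
#'   `icode`, `source_region`, `self_or_cross`, `target`, `alpha`, `beta`.
#' @export
default_lq_table <- function(targets = REGIONS_TARGET,
                             alpha = 0.1, beta = 0.01) {
  tab <- expand.grid(icode = ICODES[!ICODES %in% PHOTON_ICODES],
                     source_region = REGIONS_SOURCE,
                     self_or_cross = c("self", "cross"),
                     target = targets,
                     stringsAsFactors = FALSE)
  tab$alpha <- alpha
  tab$beta <- beta
  attr(tab, "out.attrs") <- NULL
  structure(tab, class = c("lq_table", "data.frame"), default = TRUE)
}

#' Override entries of an LQ table
#'
#' @param tab an `lq_table`.
#' @param icode,source_region,self_or_cross,target selectors (NULL = all).
#' @param alpha,beta new values (NULL = leave unchanged).
#' @return the modified table (no longer flagged as all-default).
#' @export
set_lq <- function(tab, icode = NULL, source_region = NULL,
                   self_or_cross = NULL, target = NULL,
                   alpha = NULL, beta = NULL) {
  stopifnot(inherits(tab, "lq_table"))
  sel <- rep(TRUE, nrow(tab))
  if (!is.null(icode)) sel <- sel & tab$icode %in% icode
  if (!is.null(source_region)) sel <- sel & tab$source_region %in% source_region
  if (!is.null(self_or_cross)) sel <- sel & tab$self_or_cross %in% self_or_cross
  if (!is.null(target)) sel <- sel & tab$target %in% target
  if (!any(sel)) stop("no LQ table rows match the selectors")
  if (!is.null(alpha)) { stopifnot(alpha >= 0); tab$alpha[sel] <- alpha }
  if (!is.null(beta)) { stopifnot(beta >= 0); tab$beta[sel] <- beta }
  attr(tab, "default") <- FALSE
  tab
}

#' Read / write LQ parameter tables
#'
#' CSV round-trip with columns
#' `icode,source_region,self_or_cross,target,alpha,beta`; lossless.
#'
#' @param path file path.
#' @return `read_lq_table()`: an `lq_table`; `write_lq_table()`: `path`,
#'   invisibly.
#' @export
read_lq_table <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("icode", "source_region", "self_or_cross", "target",
            "alpha", "beta")
  if (!all(need %in% names(tab)))
    stop("LQ table must have columns: ", paste(need, collapse = ","))
  if (any(tab$alpha < 0 | tab$beta < 0)) stop("LQ parameters must be >= 0")
  structure(tab[, need], class = c("lq_table", "data.frame"), default = FALSE)
}

#' @rdname read_lq_table
#' @param tab an `lq_table`.
#' @export
write_lq_table <- function(tab, path) {
  stopifnot(inherits(tab, "lq_table"))
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' Simple LQ survival probability
#'
#' `exp(-a_s D_s - b_s D_s^2) * exp(-a_c D_c - b_c D_c^2)`: self- and
#' cross-dose act independently.
#'
#' @param D_self,D_cross absorbed doses (Gy), >= 0; vectorized.
#' @param params an [lq_simple()].
#' @return survival probabilities in [0, 1].
#' @export
survival_simple <- function(D_self, D_cross, params) {
  stopifnot(inherits(params, "lq_simple"))
  if (any(D_self < 0) || any(D_cross < 0)) stop("doses must be >= 0")
  exp(-params$alpha_self * D_self - params$beta_self * D_self^2) *
    exp(-params$alpha_cross * D_cross - params$beta_cross * D_cross^2)
}

# Look up (alpha, beta) rows for the components of a dose_result; a
# missing parameter for a present dose component is a hard error.
lq_lookup <- function(tab, combos, self_or_cross, target) {
  key <- paste(tab$icode, tab$source_region, tab$self_or_cross, tab$target)
  want <- paste(combos$icode, combos$source, self_or_cross, target)
  idx <- match(want, key)
  if (anyNA(idx))
    stop("LQ parameters missing for component(s): ",
         paste(want[is.na(idx)], collapse = "; "))
  tab[idx, c("alpha", "beta")]
}

#' Complex LQ survival probabilities
#'
#' Independent-interaction model: the survival probability of each cell is
#' the product, over radiation types and over (source region, self|cross)
#' dose components, of `exp(-alpha D - beta D^2)` with the component's own
#' LQ parameters.
#'
#' @param doses a [compute_doses()] result.
#' @param tab an `lq_table` covering every present component for the
#'   result's target region.
#' @return per-cell survival probabilities in [0, 1].
#' @export
survival_complex <- function(doses, tab) {
  stopifnot(inherits(doses, "dose_result"), inherits(tab, "lq_table"))
  if (isTRUE(attr(tab, "default")))
    warning("using the shipped all-default LQ parameters (arbitrary placeholders)")
  logp <- numeric(nrow(doses$cells))
  for (sc in c("self", "cross")) {
    D <- if (sc == "self") doses$dose_self else doses$dose_cross
    ab <- lq_lookup(tab, doses$combos, sc, doses$target)
    for (i in seq_len(nrow(doses$combos)))
      logp <- logp - ab$alpha[i] * D[, i] - ab$beta[i] * D[, i]^2
  }
  exp(logp)
}

#' Monte Carlo cell fates
#'
#' Each cell survives iff an independent uniform draw `u in [0, 1)` from
#' the seeded stream satisfies `u < P`, realizing survival with
#' probability exactly P.
#'
#' @param probabilities per-cell survival probabilities in [0, 1].
#' @param seed master seed (stream `"cell_fates"`).
#' @return list with `alive` (logical) and `SF` (surviving fraction).
#' @export
monte_carlo_fates <- function(probabilities, seed = 1) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1))
  alive <- with_stream(seed, "cell_fates",
                       stats::runif(length(probabilities)) < probabilities)
  list(alive = alive, SF = mean(alive))
}

#' Tumor control probability
#'
#' Two formulations: the Poisson model `TCP = (1 - SF)^n` with n the total
#' number of cells in the cluster, and the per-cell product
#' `TCP = prod(1 - P_i)` over the (pre-draw) survival probabilities.
#'
#' @param probabilities per-cell survival probabilities.
#' @param SF surviving fraction to use in the Poisson expression
#'   (defaults to `mean(probabilities)`, the expected SF).
#' @return list `tcp_poisson`, `tcp_product`.
#' @export
tcp <- function(probabilities, SF = mean(probabilities)) {
  n <- length(probabilities)
  list(tcp_poisson = (1 - SF)^n,
       tcp_product = prod(1 - probabilities))
}

#' Surviving-fraction and TCP curve over an activity sweep
#'
#' Scales the assigned activity pattern linearly from zero to its nominal
#' value over `n_points` sweep points (the labeling pattern held fixed;
#' doses are linear in activity, so the full-dose breakdown is scaled per
#' point).  At each point the per-cell survival probabilities are
#' evaluated, one fresh Monte Carlo fate draw is made (sub-stream per
#' point), and both TCP formulations are computed from the probabilities.
#'
#' @param doses a [compute_doses()] result at the full (nominal) activity
#'   pattern.
#' @param lq an [lq_simple()] or `lq_table`.
#' @param n_points number of sweep points including zero (default 21).
#' @param seed master seed for the fate draws.
#' @return an object of class `sf_curve`: a data frame with the sweep
#'   domains (mean activity per cell / per labeled cell, mean absorbed
#'   dose to all / labeled / unlabeled cells, mean decays per cell / per
#'   labeled cell), `sf_expected` (mean survival probability),
#'   `sf_mc` (Monte Carlo realization), `tcp_poisson`, `tcp_product`.
#' @export
sf_curve <- function(doses, lq, n_points = 21, seed = 1) {
  stopifnot(inherits(doses, "dose_result"), n_points >= 2)
  pop <- doses$cells
  lab <- pop$labeled
  fracs <- seq(0, 1, length.out = n_points)
  scale_doses <- function(s) {
    d <- doses
    d$dose_self <- doses$dose_self * s
    d$dose_cross <- doses$dose_cross * s
    d$self_Gy <- doses$self_Gy * s
    d$cross_Gy <- doses$cross_Gy * s
    d$total_Gy <- doses$total_Gy * s
    d
  }
  rows <- lapply(seq_along(fracs), function(i) {
    s <- fracs[i]
    d <- scale_doses(s)
    P <- if (inherits(lq, "lq_simple"))
      survival_simple(d$self_Gy, d$cross_Gy, lq)
    else suppressWarnings(survival_complex(d, lq))
    fate <- monte_carlo_fates(P, stream_seed(seed, sprintf("sweep_%03d", i)))
    t2 <- tcp(P)
    data.frame(
      mean_activity_per_cell_Bq = s * mean(pop$activity_Bq),
      mean_activity_per_labeled_cell_Bq = s * mean(pop$activity_Bq[lab]),
      mean_dose_all_Gy = mean(d$total_Gy),
      mean_dose_labeled_Gy = mean(d$total_Gy[lab]),
      mean_dose_unlabeled_Gy = if (any(!lab)) mean(d$total_Gy[!lab]) else NA_real_,
      mean_decays_per_cell = s * mean(pop$decays),
      mean_decays_per_labeled_cell = s * mean(pop$decays[lab]),
      sf_expected = mean(P),
      sf_mc = fate$SF,
      tcp_poisson = t2$tcp_poisson,
      tcp_product = t2$tcp_product)
  })
  out <- do.call(rbind, rows)
  if (inherits(lq, "lq_table") && isTRUE(attr(lq, "default")))
    warning("using the shipped all-default LQ parameters (arbitrary placeholders)")
  structure(out, class = c("sf_curve", "data.frame"))
}

#' @export
print.sf_curve <- function(x, ...) {
  cat(sprintf("SF/TCP curve: %d sweep points, final mean dose %.4g Gy, final SF(exp) %.4g\n",
              nrow(x), x$mean_dose_all_Gy[nrow(x)], x$sf_expected[nrow(x)]))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot an SF curve
#'
#' @param x an [sf_curve()] result.
#' @param domain column to use for the horizontal axis.
#' @param ... passed to [plot()].
#' @export
plot.sf_curve <- function(x, domain = "mean_dose_all_Gy", ...) {
  graphics::plot(x[[domain]], x$sf_expected, log = "y", type = "l",
                 xlab = domain, ylab = "surviving fraction", ...)
  graphics::points(x[[domain]], x$sf_mc, pch = 20)
  graphics::legend("topright", c("expected SF", "MC SF"),
                   lty = c(1, NA), pch = c(NA, 20), bty = "n")
  invisible(x)
}
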