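# Radiolabeling: selection of labeled cells among those the drug reaches,
# sampling of initial activities (uniform / normal / lognormal), built-in
# and user-supplied radial activity profiles, and the subcellular split of
# activity among nucleus, cytoplasm and cell surface.

RADIAL_METHODS <- c("radial_linear", "radial_exponential", "radial_polynomial",
                    "radial_lognormal4", "radial_user_table")
LABEL_METHODS <- c("uniform", "normal", "lognormal", RADIAL_METHODS)

#' Activity-distribution specification
#'
#' @param method one of `"uniform"`, `"normal"`, `"lognormal"` (random
#'   per-cell activities) or `"radial_linear"`, `"radial_exponential"`,
#'   `"radial_polynomial"`, `"radial_lognormal4"`, `"radial_user_table"`
#'   (mean activity a function of distance from the cluster centre).
#' @param mean_activity_Bq mean initial activity per labeled cell (random
#'   methods).
#' @param sigma SD in Bq (normal) or dimensionless shape parameter
#'   (lognormal).
#' @param radial_params parameters of the radial profile:
#'   `c(intercept, slope)` (linear), `c(factor)` in 1/um (exponential,
#'   profile `exp(factor * (r - R_ref))` anchored at the outermost labeled
#'   radius `R_ref`), polynomial coefficients lowest order first (degree
#'   <= 10), `c(a, b, c, s)` (4-parameter lognormal
#'   `a * exp(-(ln((r - c)/b))^2 / (2 s^2))`), or a data frame / file path
#'   with columns `radius_um`, `relative_activity` (user table, spherical
#'   clusters only; linear interpolation, constant beyond the ends).
#' @param percent_labeled percentage of eligible cells to label, in
#'   (0, 100].
#' @param max_mean_activity_Bq maximum mean activity per cell: the scale
#'   of the radial profiles and the upper end of the activity sweep in
#'   [sf_curve()].
#' @return an object of class `activity_spec`.
#' @export
activity_spec <- function(method = LABEL_METHODS, mean_activity_Bq = NULL,
                          sigma = NULL, radial_params = NULL,
                          percent_labeled = 100,
                          max_mean_activity_Bq = NULL) {
  method <- match.arg(method)
  if (percent_labeled <= 0 || percent_labeled > 100)
    stop("percent_labeled must lie in (0, 100]")
  if (method %in% c("normal", "lognormal")) {
    if (is.null(sigma) || sigma <= 0) stop(method, " requires sigma > 0")
  }
  if (method %in% c("uniform", "normal", "lognormal")) {
    if (is.null(mean_activity_Bq))
      mean_activity_Bq <- max_mean_activity_Bq
    if (is.null(mean_activity_Bq) || mean_activity_Bq < 0)
      stop("mean_activity_Bq (or max_mean_activity_Bq) must be given and >= 0")
    if (is.null(max_mean_activity_Bq)) max_mean_activity_Bq <- mean_activity_Bq
  } else {
    if (is.null(max_mean_activity_Bq) || max_mean_activity_Bq < 0)
      stop("radial methods require max_mean_activity_Bq >= 0")
    if (is.null(radial_params)) stop(method, " requires radial_params")
  }
  structure(list(method = method, mean_activity_Bq = mean_activity_Bq,
                 sigma = sigma, radial_params = radial_params,
                 percent_labeled = percent_labeled,
                 max_mean_activity_Bq = max_mean_activity_Bq),
            class = "activity_spec")
}

#' Subcellular activity split
#'
#' Fractions of each cell's activity residing in the nucleus, cytoplasm
#' and on the cell surface; they must sum to 1.
#'
#' @param f_N,f_Cy,f_CS fractions in `[0, 1]`, `f_N + f_Cy + f_CS = 1`.
#' @return an object of class `subcellular_split` (named vector).
#' @export
subcellular_split <- function(f_N = 0, f_Cy = 0, f_CS = 1) {
  f <- c(N = f_N, Cy = f_Cy, CS = f_CS)
  if (any(f < 0 | f > 1)) stop("fractions must lie in [0, 1]")
  if (abs(sum(f) - 1) > 1e-9) stop("f_N + f_Cy + f_CS must equal 1")
  structure(f, class = "subcellular_split")
}

#' Randomly select the labeled cells
#'
#' Labels a uniform random subset of the eligible cells.  The requested
#' count is `round(percent_labeled/100 * n_eligible)`; a request
#' exceeding the eligible count is clamped to all eligible cells with a
#' warning (as when a drug-penetration depth caps the labelable
#' population).
#'
#' @param pop a [build_population()] result (eligibility already set).
#' @param percent_labeled percentage of *all* cells to label, in (0, 100].
#' @param seed master seed (the selection uses a private stream).
#' @return the population with `labeled` flags set.
#' @export
select_labeled <- function(pop, percent_labeled, seed) {
  stopifnot(inherits(pop, "cell_population"))
  elig <- which(pop$eligible)
  if (length(elig) == 0L) stop("no cells are eligible for labeling")
  want <- round(percent_labeled / 100 * nrow(pop))
  want <- max(want, 1L)
  if (want > length(elig)) {
    warning(sprintf(
      "requested %d labeled cells but only %d lie within the penetration depth; clamping",
      want, length(elig)))
    want <- length(elig)
  }
  pick <- with_stream(seed, "label_selection",
                      if (want == length(elig)) elig
                      else sample(elig, want))
  pop$labeled <- FALSE
  pop$labeled[pick] <- TRUE
  pop
}

#' Sample initial activities for labeled cells
#'
#' Uniform: every cell receives `mean_activity_Bq`.  Normal: draws from
#' Normal(mean, sigma^2), redrawn until positive.  Lognormal:
#' `ln A ~ Normal(ln(mean) - sigma^2/2, sigma^2)`, whose analytic mean is
#' exactly `mean_activity_Bq`.
#'
#' @param method `"uniform"`, `"normal"` or `"lognormal"`.
#' @param mean_activity_Bq mean activity per labeled cell.
#' @param sigma SD (normal, Bq) or shape (lognormal, dimensionless).
#' @param n number of draws.
#' @param seed master seed (private stream `"activity_sampling"`).
#' @return numeric vector of n positive activities (Bq).
#' @export
sample_activities <- function(method = c("uniform", "normal", "lognormal"),
                              mean_activity_Bq, sigma = NULL, n, seed = 1) {
  method <- match.arg(method)
  stopifnot(n >= 1)
  if (mean_activity_Bq < 0) stop("mean_activity_Bq must be >= 0")
  with_stream(seed, "activity_sampling", switch(method,
    uniform = rep(mean_activity_Bq, n),
    normal = {
      if (is.null(sigma) || sigma <= 0) stop("normal requires sigma > 0")
      a <- stats::rnorm(n, mean_activity_Bq, sigma)
      while (any(bad <- a <= 0))
        a[bad] <- stats::rnorm(sum(bad), mean_activity_Bq, sigma)
      a
    },
    lognormal = {
      if (is.null(sigma) || sigma <= 0) stop("lognormal requires sigma > 0")
      stats::rlnorm(n, log(mean_activity_Bq) - sigma^2 / 2, sigma)
    }))
}

#' Radial mean-activity profile
#'
#' Returns the (unnormalized) relative mean-activity profile as a
#' function of distance r from the cluster centre (r = 0 is the centre).
#'
#' @param method a radial method name (see [activity_spec()]).
#' @param params profile parameters (see [activity_spec()]).
#' @param R_ref anchor radius for the exponential profile (outermost
#'   labeled radius).
#' @param layer_um optional layer thickness (um) for the exponential
#'   profile: when given, the depth `R_ref - r` is discretized into whole
#'   layers of this thickness before the exponential decay is applied, so
#'   all cells of one concentric cell layer share one activity (a
#'   radiopharmaceutical binds layer by layer).  `NULL` keeps the profile
#'   continuous in r.
#' @return function of r (um) returning relative mean activity.
#' @export
radial_profile <- function(method, params, R_ref = 0, layer_um = NULL) {
  switch(method,
    radial_linear = function(r) params[1] + params[2] * r,
    radial_exponential = function(r) {
      depth <- pmax(R_ref - r, 0)
      if (!is.null(layer_um))
        depth <- layer_um * floor(depth / layer_um + 1e-9)
      exp(-params[1] * depth)
    },
    radial_polynomial = {
      if (length(params) > 11L) stop("polynomial degree is limited to 10")
      function(r) {
        out <- 0
        for (i in seq_along(params)) out <- out + params[i] * r^(i - 1)
        out
      }
    },
    radial_lognormal4 = function(r) {
      a <- params[1]; b <- params[2]; cc <- params[3]; s <- params[4]
      out <- numeric(length(r))
      pos <- r > cc
      out[pos] <- a * exp(-(log((r[pos] - cc) / b))^2 / (2 * s^2))
      out
    },
    radial_user_table = {
      tab <- params
      if (is.character(tab)) tab <- utils::read.csv(tab, comment.char = "#")
      stopifnot(all(c("radius_um", "relative_activity") %in% names(tab)))
      stats::approxfun(tab$radius_um, tab$relative_activity, rule = 2)
    },
    stop("not a radial method: ", method))
}

#' Assign initial activities to a labeled population
#'
#' Unlabeled cells get zero activity.  For the random methods each
#' labeled cell draws from the selected distribution; for the radial
#' methods each labeled cell's activity is `profile(r)`, rescaled so the
#' maximum over labeled cells equals `max_mean_activity_Bq`.  Every cell
#' carries the same subcellular split.
#'
#' @param pop a [select_labeled()] result.
#' @param dist_spec an [activity_spec()].
#' @param subcell a [subcellular_split()].
#' @param seed master seed.
#' @return the population with `activity_Bq` set and the split and spec
#'   stored as attributes.
#' @export
assign_activity <- function(pop, dist_spec, subcell = subcellular_split(),
                            seed = 1) {
  stopifnot(inherits(pop, "cell_population"),
            inherits(dist_spec, "activity_spec"))
  spec <- attr(pop, "spec")
  lab <- which(pop$labeled)
  if (length(lab) == 0L) stop("no labeled cells; run select_labeled() first")
  m <- dist_spec$method
  if (m %in% RADIAL_METHODS && spec$shape == "ellipsoid")
    stop("radial labeling methods are not available for ellipsoid clusters; ",
         "use uniform, normal or lognormal")
  if (m == "radial_user_table" && spec$shape != "sphere")
    stop("user radial tables are available only for spherical clusters")
  if (m %in% RADIAL_METHODS) {
    prof <- radial_profile(m, dist_spec$radial_params,
                           R_ref = max(pop$r[lab]),
                           layer_um = 2 * spec$cell$r_cell_um)
    rel <- prof(pop$r[lab])
    if (any(rel < 0))
      stop("radial profile is negative over the labeled range")
    if (max(rel) == 0) stop("radial profile is zero over the labeled range")
    act <- rel / max(rel) * dist_spec$max_mean_activity_Bq
  } else {
    act <- sample_activities(m, dist_spec$mean_activity_Bq, dist_spec$sigma,
                             length(lab), seed)
  }
  pop$activity_Bq <- 0
  pop$activity_Bq[lab] <- act
  attr(pop, "subcell") <- subcell
  attr(pop, "activity_spec") <- dist_spec
  pop
}

#' One-call labeling pipeline
#'
#' Convenience wrapper: [select_labeled()] then [assign_activity()].
#'
#' @inheritParams assign_activity
#' @param seed master seed for both the selection and sampling streams.
#' @return the labeled, activity-assigned population.
#' @export
label_population <- function(pop, dist_spec, subcell = subcellular_split(),
                             seed = 1) {
  pop <- select_labeled(pop, dist_spec$percent_labeled, seed)
  assign_activity(pop, dist_spec, subcell, seed)
}
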