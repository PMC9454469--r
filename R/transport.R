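# Range-energy relations and point-source dose kernels for electrons and
# alpha particles in unit-density liquid water.  These are the physics
# under every S coefficient: charged particles travel straight lines
# (continuous-slowing-down approximation) and lose energy according to an
# empirical range-energy relation; photons are ignored throughout.

# Piecewise log-log linear interpolation with log-log linear extrapolation
# beyond the table ends (monotone tables only).
loglog_interp_fun <- function(x, y) {
  lx <- log(x); ly <- log(y)
  n <- length(lx)
  slope_lo <- (ly[2L] - ly[1L]) / (lx[2L] - lx[1L])
  slope_hi <- (ly[n] - ly[n - 1L]) / (lx[n] - lx[n - 1L])
  function(q) {
    lq <- log(q)
    out <- stats::approx(lx, ly, xout = lq, rule = 2)$y
    lo <- lq < lx[1L]
    hi <- lq > lx[n]
    out[lo] <- ly[1L] + slope_lo * (lq[lo] - lx[1L])
    out[hi] <- ly[n] + slope_hi * (lq[hi] - lx[n])
    exp(out)
  }
}

#' Range-energy model for charged-particle transport
#'
#' Builds the range-energy relation used by the analytic S-coefficient
#' engine and the Monte Carlo oracle.  Electrons default to the Cole-type
#' empirical power law
#' \deqn{R(\mu m) = 0.0431\,(E_{keV} + 0.367)^{1.77} - 0.007,}
#' long used in cellular dosimetry; a tabulated-CSDA alternative
#' (`relation = "tabulated"`) interpolates the packaged electron range
#' table in log-log space.  Alpha particles use the packaged range table
#' (log-log interpolated).  Density is 1 g/cm^3 everywhere.
#'
#' @param particle `"electron"` or `"alpha"`.
#' @param relation `"cole"` (electrons only, default) or `"tabulated"`.
#' @return an object of class `range_energy_model` with closures
#'   `range_um(E)`, `energy_from_range(R)` and a stated validity window
#'   (MeV); outside the window values are extrapolated (see
#'   [csda_range()]).
#' @export
range_energy_model <- function(particle = c("electron", "alpha"),
                               relation = NULL) {
  particle <- match.arg(particle)
  if (is.null(relation)) relation <- if (particle == "alpha") "tabulated" else "cole"
  if (particle == "alpha" && relation != "tabulated")
    stop("alpha particles support only the 'tabulated' relation")
  if (particle == "electron" && !relation %in% c("cole", "tabulated"))
    stop("electron relations are 'cole' or 'tabulated'")
  if (relation == "cole") {
    range_um <- function(E) 0.0431 * (1000 * E + 0.367)^1.77 - 0.007
    energy_from_range <- function(R) {
      E <- (pmax(R + 0.007, 0) / 0.0431)^(1 / 1.77) - 0.367
      pmax(E, 0) / 1000
    }
    validity <- c(1e-3, 2)
  } else {
    tab <- if (particle == "alpha") read_extdata_csv("alpha_range_water.csv")
           else read_extdata_csv("electron_range_water.csv")
    fwd <- loglog_interp_fun(tab$energy_MeV, tab$range_um)
    inv <- loglog_interp_fun(tab$range_um, tab$energy_MeV)
    range_um <- function(E) fwd(E)
    energy_from_range <- function(R) ifelse(R <= 0, 0, inv(pmax(R, 1e-300)))
    validity <- range(tab$energy_MeV)
  }
  structure(list(particle = particle, relation = relation,
                 range_um = range_um, energy_from_range = energy_from_range,
                 validity_MeV = validity),
            class = "range_energy_model")
}

#' @export
print.range_energy_model <- function(x, ...) {
  cat(sprintf("Range-energy model: %s, relation '%s', valid %.4g-%.4g MeV\n",
              x$particle, x$relation, x$validity_MeV[1], x$validity_MeV[2]))
  invisible(x)
}

# Model for an icode, using the electron model for every electron-type
# category (beta average-energy lines transported as monoenergetic
# electrons at the average energy).  Photons have no transport model.
model_for_icode <- function(icode, electron_relation = "cole") {
  if (icode == "alpha") range_energy_model("alpha")
  else if (icode %in% ELECTRON_ICODES)
    range_energy_model("electron", electron_relation)
  else NULL
}

#' Continuous-slowing-down range in unit-density water
#'
#' @param model a [range_energy_model()].
#' @param energy_MeV initial energy (MeV), > 0; vectorized.
#' @return range in micrometers.  A warning is emitted (once per call) when
#'   any energy lies outside the relation's stated validity window; the
#'   value is then an extrapolation.
#' @export
csda_range <- function(model, energy_MeV) {
  stopifnot(inherits(model, "range_energy_model"))
  if (any(energy_MeV <= 0)) stop("energy_MeV must be > 0")
  v <- model$validity_MeV
  if (any(energy_MeV < v[1] | energy_MeV > v[2]))
    warning(sprintf("energy outside validity window [%.4g, %.4g] MeV; range extrapolated",
                    v[1], v[2]))
  model$range_um(energy_MeV)
}

#' Residual energy after a path length in water
#'
#' Inverts the range relation: a particle of initial energy `E0` that has
#' traveled `depth_um` has the energy whose residual range is
#' `range(E0) - depth_um`; zero at or beyond the full range.
#'
#' @param model a [range_energy_model()].
#' @param E0 initial energy (MeV).
#' @param depth_um path length (um), >= 0; vectorized over `depth_um`.
#' @return residual energy in MeV.
#' @export
residual_energy <- function(model, E0, depth_um) {
  stopifnot(inherits(model, "range_energy_model"))
  if (any(depth_um < 0)) stop("depth_um must be >= 0")
  R0 <- model$range_um(E0)
  rem <- R0 - depth_um
  out <- numeric(length(rem))
  pos <- rem > 0
  out[pos] <- model$energy_from_range(rem[pos])
  pmin(out, E0)
}

# Linear stopping power (MeV/um) at energy E, from the inverse slope of
# the range relation (central difference in log E; exact enough for both
# the closed-form and tabulated relations).
stopping_power <- function(model, E) {
  h <- 1e-4
  dR <- (model$range_um(E * (1 + h)) - model$range_um(E * (1 - h))) / (2 * E * h)
  1 / dR
}

#' Absorbed dose at a point from an isotropic point source
#'
#' The straight-track CSDA point kernel: dose at distance `r_um` equals the
#' linear stopping power at the residual energy divided by the spherical
#' shell factor, \eqn{D(r) = S(E(r)) / (4 \pi r^2 \rho)}, in unit-density
#' water.  Zero at or beyond the particle range.
#'
#' @param model a [range_energy_model()].
#' @param E0 initial energy (MeV).
#' @param r_um distance from the source (um), > 0; vectorized.
#' @return dose in Gy per emitted particle.
#' @export
point_dose <- function(model, E0, r_um) {
  stopifnot(inherits(model, "range_energy_model"))
  if (any(r_um <= 0)) stop("r_um must be > 0 (the kernel is singular at 0)")
  R0 <- model$range_um(E0)
  out <- numeric(length(r_um))
  inside <- r_um < R0
  if (any(inside)) {
    Eres <- residual_energy(model, E0, r_um[inside])
    pos <- Eres > 0                      # measure-zero endpoint excluded
    D <- numeric(sum(inside))
    D[pos] <- stopping_power(model, Eres[pos]) *
      MEV_PER_UM3_TO_GY / (4 * pi * r_um[inside][pos]^2)
    out[inside] <- D
  }
  out
}
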