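# Cellular self- and cross-dose S coefficients for the two-concentric-
# spheres cell model.  The absorbed fraction phi(target <- source) is
# computed by Gauss-Legendre quadrature of the straight-track CSDA kernel:
# an isotropic point emission at distance u from the centre of a target
# sphere deposits, along each ray, the difference of residual energies at
# the chord entry and exit points; averaging over ray directions, source
# position within the source region, and (for cross dose) the angular
# position of the source point reduces everything to nested 1-D
# quadratures.

#' Concentric-sphere cell model
#'
#' Cells are two concentric spheres of unit-density water: the cell
#' (radius `r_cell_um`) and its nucleus (radius `r_nucleus_um`).  Source
#' regions are cell (C), nucleus (N), cytoplasm (Cy) and cell surface
#' (CS); target regions are C, N and Cy.
#'
#' @param r_cell_um cell radius (um), > 0.
#' @param r_nucleus_um nucleus radius (um), in (0, r_cell_um].
#' @return an object of class `cell_model` carrying the radii and the
#'   region masses in kg.  A warning is emitted for cell radii above 10 um,
#'   where the analytic engine is less thoroughly exercised.
#' @export
cell_model <- function(r_cell_um, r_nucleus_um) {
  stopifnot(is.numeric(r_cell_um), is.numeric(r_nucleus_um))
  if (r_nucleus_um <= 0 || r_nucleus_um > r_cell_um)
    stop("need 0 < r_nucleus_um <= r_cell_um")
  if (r_cell_um > 10)
    warning("cell radius above 10 um: results are extrapolations beyond the well-tested regime")
  vol <- function(r) 4 / 3 * pi * r^3            # um^3
  mC <- vol(r_cell_um) * WATER_DENSITY_KG_PER_UM3
  mN <- vol(r_nucleus_um) * WATER_DENSITY_KG_PER_UM3
  structure(list(r_cell_um = r_cell_um, r_nucleus_um = r_nucleus_um,
                 mass_kg = c(C = mC, N = mN, Cy = mC - mN)),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("Cell model: r_cell = %g um, r_nucleus = %g um\n",
              x$r_cell_um, x$r_nucleus_um))
  cat(sprintf("  masses (kg): C = %.4g, N = %.4g, Cy = %.4g\n",
              x$mass_kg["C"], x$mass_kg["N"], x$mass_kg["Cy"]))
  invisible(x)
}

#' Region mass of a cell model
#' @param cell a [cell_model()].
#' @param region `"C"`, `"N"` or `"Cy"`.
#' @return mass in kg.
#' @export
region_mass <- function(cell, region) {
  stopifnot(inherits(cell, "cell_model"))
  region <- match.arg(region, REGIONS_TARGET)
  unname(cell$mass_kg[region])
}

# Default quadrature orders (documented in the methods vignette; relative
# accuracy ~1e-3 or better for the geometries exercised).
quad_defaults <- function(quad = NULL) {
  q <- list(n_dir = 48, n_src = 24, n_ang = 32)
  if (!is.null(quad)) q[names(quad)] <- quad
  q
}

# Mean energy (MeV) absorbed in a sphere of radius Rt whose centre is at
# distance u from an isotropic point emission of energy E0.  Vectorized
# over u.
absorbed_in_sphere <- function(model, E0, u, Rt, n_dir = 48) {
  out <- numeric(length(u))
  R0 <- model$range_um(E0)
  reach <- u - Rt < R0
  if (!any(reach)) return(out)
  ui <- u[reach]
  inside <- ui < Rt
  res <- numeric(length(ui))
  if (any(inside)) {
    uu <- ui[inside]
    gl <- gauss_legendre(n_dir, -1, 1)
    # t_out(c) for each (u, node): matrix n_u x n_dir
    tm <- outer(uu, gl$x, function(u, c)
      -u * c + sqrt(pmax(Rt^2 - u^2 * (1 - c^2), 0)))
    Eout <- matrix(residual_energy(model, E0, as.vector(tm)), nrow = length(uu))
    res[inside] <- (E0 - Eout) %*% gl$w / 2
  }
  if (any(!inside)) {
    uu <- ui[!inside]
    gl0 <- gauss_legendre(n_dir, 0, 1)   # mapped per-u onto [-1, -c0(u)]
    c0 <- sqrt(pmax(1 - (Rt / uu)^2, 0))
    U <- matrix(uu, length(uu), n_dir)
    cm <- -1 + (1 - c0) %o% gl0$x        # direction-cosine nodes
    disc <- pmax(Rt^2 - U^2 * (1 - cm^2), 0)
    tin <- pmax(-U * cm - sqrt(disc), 0)
    tout <- pmax(-U * cm + sqrt(disc), 0)
    dep <- matrix(residual_energy(model, E0, as.vector(tin)) -
                    residual_energy(model, E0, as.vector(tout)),
                  nrow = length(uu))
    res[!inside] <- rowSums(dep * ((1 - c0) %o% gl0$w)) / 2
  }
  out[reach] <- res
  out
}

# Cached piecewise-linear profile of absorbed_in_sphere over u for one
# (model, E0, Rt) triple; used by the cross-dose quadrature, where the
# same profile is re-evaluated for hundreds of lattice distances.  Dense
# grid on both sides of the u = Rt kink; exact zero beyond Rt + range.
.F_cache <- new.env(parent = emptyenv())
absorbed_profile <- function(model, E0, Rt, n_dir = 48) {
  key <- paste(model$particle, model$relation, E0, Rt, n_dir)
  f <- .F_cache[[key]]
  if (!is.null(f)) return(f)
  R0 <- model$range_um(E0)
  u_in <- seq(0, Rt, length.out = 481)
  u_out <- Rt + seq(0, 1, length.out = 1441)^1.5 * R0
  u <- c(u_in, u_out[-1])
  Fv <- absorbed_in_sphere(model, E0, u, Rt, n_dir)
  Fv[length(Fv)] <- 0
  f <- stats::approxfun(u, Fv, rule = 2, yright = 0)
  .F_cache[[key]] <- f
  f
}

# Radial bounds of a source region.
source_bounds <- function(cell, source) {
  switch(source,
         N = c(0, cell$r_nucleus_um),
         Cy = c(cell$r_nucleus_um, cell$r_cell_um),
         C = c(0, cell$r_cell_um),
         CS = c(cell$r_cell_um, cell$r_cell_um),
         stop("unknown source region: ", source))
}

# Mean energy absorbed in a sphere of radius Rt centred at distance d from
# the cell centre, for emissions of energy E0 distributed uniformly over
# the source region of `cell`.  d = 0 gives the concentric (self) case.
absorbed_region_sphere <- function(model, E0, cell, source, Rt, d = 0,
                                   quad = NULL) {
  q <- quad_defaults(quad)
  b <- source_bounds(cell, source)
  if (b[1] == b[2]) {            # surface shell source
    rs <- b[1]; wr <- 1
  } else {                       # uniform-in-volume: weight r^2
    gl <- gauss_legendre(q$n_src, b[1], b[2])
    rs <- gl$x
    wr <- gl$w * rs^2
    wr <- wr / sum(wr)
  }
  if (d == 0) {
    F <- absorbed_in_sphere(model, E0, rs, Rt, q$n_dir)
    return(sum(F * wr))
  }
  # distance from a source point at radius rs to the target centre:
  # u = sqrt(rs^2 + d^2 - 2 rs d w), w uniform on [-1, 1]
  glw <- gauss_legendre(q$n_ang, -1, 1)
  prof <- absorbed_profile(model, E0, Rt, q$n_dir)
  U <- sqrt(pmax(outer(rs^2 + d^2, rep(1, q$n_ang)) -
                   outer(2 * rs * d, glw$x), 0))
  Fm <- matrix(prof(as.vector(U)), nrow = length(rs))
  sum(wr * (Fm %*% glw$w)) / 2
}

#' Absorbed fraction for one emission line
#'
#' Fraction of the energy of a monoenergetic emission, uniformly
#' distributed over the source region of one cell, that is absorbed in a
#' target region whose cell centre lies `d_um` away (0 = the same cell).
#'
#' @param model a [range_energy_model()] (NULL, for photons, returns 0).
#' @param E0 emission energy (MeV).
#' @param cell a [cell_model()].
#' @param source source region (`"C"`, `"N"`, `"Cy"`, `"CS"`).
#' @param target target region (`"C"`, `"N"`, `"Cy"`).
#' @param d_um centre-to-centre distance to the target cell (um).
#' @param quad optional quadrature overrides (`n_dir`, `n_src`, `n_ang`).
#' @return the absorbed fraction phi in [0, 1].
#' @export
absorbed_fraction <- function(model, E0, cell, source, target, d_um = 0,
                              quad = NULL) {
  if (is.null(model)) return(0)
  source <- match.arg(source, REGIONS_SOURCE)
  target <- match.arg(target, REGIONS_TARGET)
  stopifnot(inherits(cell, "cell_model"))
  EN <- function() absorbed_region_sphere(model, E0, cell, source,
                                          cell$r_nucleus_um, d_um, quad)
  EC <- function() absorbed_region_sphere(model, E0, cell, source,
                                          cell$r_cell_um, d_um, quad)
  e <- switch(target, N = EN(), C = EC(), Cy = EC() - EN())
  max(e, 0) / E0
}

# Shared worker: per-icode S values (Gy per decay) at distance d (0 = self).
s_values <- function(spectrum, cell, source, target, d_um = 0,
                     electron_relation = "cole", quad = NULL) {
  stopifnot(inherits(spectrum, "radiation_spectrum"),
            inherits(cell, "cell_model"))
  source <- match.arg(source, REGIONS_SOURCE)
  target <- match.arg(target, REGIONS_TARGET)
  m <- region_mass(cell, target)
  out <- stats::setNames(numeric(length(ICODES)), ICODES)
  for (i in seq_len(nrow(spectrum$lines))) {
    ln <- spectrum$lines[i, ]
    if (!ln$dosimetric || ln$delta_MeV == 0) next
    model <- model_for_icode(ln$icode, electron_relation)
    if (d_um > 0 &&
        d_um > model$range_um(ln$energy_MeV) + 2 * cell$r_cell_um) next
    phi <- absorbed_fraction(model, ln$energy_MeV, cell, source, target,
                             d_um, quad)
    out[ln$icode] <- out[ln$icode] +
      ln$delta_MeV * phi * 1.602176634e-13 / m
  }
  out
}

#' Self-dose S coefficient
#'
#' Absorbed dose to a target region of a cell per nuclear transition in a
#' source region of the same cell, \eqn{S = \sum \Delta_i \phi_i / m},
#' resolved by radiation-type code.  Photon lines contribute zero.
#'
#' @inheritParams absorbed_fraction
#' @param spectrum a [radiation_spectrum()].
#' @param electron_relation electron range-energy relation (see
#'   [range_energy_model()]).
#' @return named numeric vector over radiation-type codes, Gy/(Bq s).
#' @export
self_s <- function(spectrum, cell, source, target,
                   electron_relation = "cole", quad = NULL) {
  s_values(spectrum, cell, source, target, 0, electron_relation, quad)
}

#' Cross-dose S coefficient
#'
#' Absorbed dose to a target region of one cell per nuclear transition in
#' a source region of another identical cell whose centre lies `d_um`
#' away.  Exactly zero beyond the maximum particle range plus one cell
#' diameter.  The full source-region geometry is integrated (no
#' point-source approximation).
#'
#' @inheritParams self_s
#' @param d_um centre-to-centre distance (um), >= 2 r_cell.
#' @return named numeric vector over radiation-type codes, Gy/(Bq s).
#' @export
cross_s <- function(spectrum, cell, d_um, source, target,
                    electron_relation = "cole", quad = NULL) {
  if (d_um < 2 * cell$r_cell_um - 1e-9)
    stop("overlapping cells: d_um must be >= 2 * r_cell_um")
  s_values(spectrum, cell, source, target, d_um, electron_relation, quad)
}

#' Precompute the full S-coefficient table for a set of distances
#'
#' The cluster lattice realizes a finite set of centre-to-centre
#' distances; this builds the complete self and cross tables once so dose
#' accumulation is exact lookup.
#'
#' @inheritParams self_s
#' @param distances_um numeric vector of centre-to-centre distances (um).
#' @param sources source regions to tabulate (default all).
#' @param targets target regions to tabulate (default all).
#' @return an object of class `s_coefficient_set`: arrays `self`
#'   (icode x target x source) and `cross` (icode x target x source x
#'   distance), plus the distance grid.
#' @export
s_table <- function(spectrum, cell, distances_um,
                    sources = REGIONS_SOURCE, targets = REGIONS_TARGET,
                    electron_relation = "cole", quad = NULL) {
  sources <- match.arg(sources, REGIONS_SOURCE, several.ok = TRUE)
  targets <- match.arg(targets, REGIONS_TARGET, several.ok = TRUE)
  distances_um <- sort(unique(distances_um))
  self <- array(0, dim = c(length(ICODES), length(targets), length(sources)),
                dimnames = list(ICODES, targets, sources))
  cross <- array(0, dim = c(length(ICODES), length(targets), length(sources),
                            length(distances_um)),
                 dimnames = list(ICODES, targets, sources,
                                 format(distances_um, trim = TRUE)))
  for (src in sources) for (tg in targets) {
    self[, tg, src] <- self_s(spectrum, cell, src, tg, electron_relation, quad)
    for (k in seq_along(distances_um))
      cross[, tg, src, k] <- cross_s(spectrum, cell, distances_um[k], src, tg,
                                     electron_relation, quad)
  }
  # beyond the longest particle range plus one cell diameter every cross
  # term is exactly zero; dose accumulation prunes pairs past this cutoff
  rmax <- 0
  for (i in seq_len(nrow(spectrum$lines))) {
    ln <- spectrum$lines[i, ]
    if (!ln$dosimetric) next
    model <- model_for_icode(ln$icode, electron_relation)
    rmax <- max(rmax, model$range_um(ln$energy_MeV))
  }
  structure(list(self = self, cross = cross, distances_um = distances_um,
                 cutoff_um = rmax + 2 * cell$r_cell_um,
                 cell = cell, spectrum_name = spectrum$name,
                 electron_relation = electron_relation),
            class = "s_coefficient_set")
}

#' @export
print.s_coefficient_set <- function(x, ...) {
  cat("S-coefficient set for", x$spectrum_name, "\n")
  cat(sprintf("  cell r = %g um, nucleus r = %g um; %d cross distances (%g-%g um)\n",
              x$cell$r_cell_um, x$cell$r_nucleus_um, length(x$distances_um),
              min(x$distances_um), max(x$distances_um)))
  invisible(x)
}

#' Export an S-coefficient set as CSV
#'
#' One row per distance (the self row first, distance 0), one column per
#' (target <- source, icode) combination with a nonzero entry anywhere.
#'
#' @param s_set an [s_table()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_s_table <- function(s_set, path) {
  stopifnot(inherits(s_set, "s_coefficient_set"))
  dn <- dimnames(s_set$self)
  cols <- expand.grid(icode = dn[[1]], target = dn[[2]], source = dn[[3]],
                      stringsAsFactors = FALSE)
  keep <- vapply(seq_len(nrow(cols)), function(i)
    s_set$self[cols$icode[i], cols$target[i], cols$source[i]] != 0 ||
      any(s_set$cross[cols$icode[i], cols$target[i], cols$source[i], ] != 0),
    logical(1))
  cols <- cols[keep, , drop = FALSE]
  mk_row <- function(get) vapply(seq_len(nrow(cols)), function(i)
    get(cols$icode[i], cols$target[i], cols$source[i]), numeric(1))
  rows <- rbind(
    mk_row(function(ic, tg, src) s_set$self[ic, tg, src]),
    t(vapply(seq_along(s_set$distances_um), function(k)
      mk_row(function(ic, tg, src) s_set$cross[ic, tg, src, k]),
      numeric(nrow(cols)))))
  df <- data.frame(distance_um = c(0, s_set$distances_um), rows)
  names(df)[-1] <- sprintf("S_%s_from_%s_%s", cols$target, cols$source,
                           cols$icode)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
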