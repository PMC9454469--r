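# Cluster construction: identical spherical cells on a simple cubic
# lattice filling 1-D pairs, 2-D colonies and 3-D clusters, plus
# drug-penetration (cold core) classification and tomographic slicing.
#
# Lattice convention (frozen): simple cubic lattice of pitch = spacing,
# axis-aligned, anchored at the cluster centre with a fixed fractional
# offset of ANCHOR_FRACTION * spacing along each axis; a lattice point
# belongs to the cluster when it lies inside the nominal shape shrunk by
# MARGIN_FRACTION * spacing.  The two fractions were calibrated once
# against the reference spheroid configuration (cluster radius 125 um,
# cell radius 6 um, spacing 13 um -> 3,473 cells) and are frozen; see the
# methods vignette.
ANCHOR_FRACTION <- 0.07
MARGIN_FRACTION <- 0.23

#' Cluster specification
#'
#' @param shape one of `"pair"` (1-D), `"circle"`, `"rectangle"`,
#'   `"ellipse"` (2-D, cells on the z = 0 plane), `"sphere"`,
#'   `"ellipsoid"`, `"rod"`, `"cone"` (3-D).
#' @param dims named list of shape dimensions in um: `radius` (sphere,
#'   circle, rod base, cone base), `semi_x`/`semi_y`/`semi_z` (ellipse,
#'   ellipsoid), `len_x`/`len_y` (rectangle), `length` (rod), `height`
#'   (cone).  Ignored for `"pair"`.
#' @param spacing_um centre-to-centre lattice spacing (um),
#'   >= 2 * r_cell.
#' @param cell a [cell_model()].
#' @param penetration_depth_um depth from the outer surface to which the
#'   radiopharmaceutical penetrates; cells deeper than this form the
#'   unlabeled cold core.  `Inf` (default) labels the whole cluster
#'   eligible.
#' @return an object of class `cluster_spec`.
#' @export
cluster_spec <- function(shape = c("sphere", "ellipsoid", "rod", "cone",
                                   "circle", "rectangle", "ellipse", "pair"),
                         dims = list(), spacing_um, cell,
                         penetration_depth_um = Inf) {
  shape <- match.arg(shape)
  stopifnot(inherits(cell, "cell_model"))
  if (spacing_um < 2 * cell$r_cell_um)
    stop("spacing_um must be >= 2 * r_cell_um (cells must not overlap)")
  need <- switch(shape,
                 pair = character(),
                 circle = , sphere = "radius",
                 rectangle = c("len_x", "len_y"),
                 ellipse = c("semi_x", "semi_y"),
                 ellipsoid = c("semi_x", "semi_y", "semi_z"),
                 rod = c("radius", "length"),
                 cone = c("radius", "height"))
  miss <- setdiff(need, names(dims))
  if (length(miss) > 0L)
    stop("missing dims for ", shape, ": ", paste(miss, collapse = ", "))
  if (any(unlist(dims[need]) <= 0)) stop("all dims must be > 0")
  dimensionality <- switch(shape, pair = 1L,
                           circle = , rectangle = , ellipse = 2L, 3L)
  if (penetration_depth_um < 0) stop("penetration_depth_um must be >= 0 (use Inf for full penetration)")
  structure(list(shape = shape, dimensionality = dimensionality,
                 dims = dims, spacing_um = spacing_um, cell = cell,
                 penetration_depth_um = penetration_depth_um),
            class = "cluster_spec")
}

# Exact distance from an interior point to the surface of the shape
# (non-negative inside).  pts is an n x 3 matrix.
surface_distance <- function(spec, pts) {
  d <- spec$dims
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  rho <- sqrt(x^2 + y^2)
  switch(spec$shape,
    pair = rep(0, nrow(pts)),
    sphere = d$radius - sqrt(x^2 + y^2 + z^2),
    circle = d$radius - rho,
    rectangle = pmin(d$len_x / 2 - abs(x), d$len_y / 2 - abs(y)),
    ellipse = ellipsoid_surface_distance(cbind(x, y),
                                         c(d$semi_x, d$semi_y)),
    ellipsoid = ellipsoid_surface_distance(cbind(x, y, z),
                                           c(d$semi_x, d$semi_y, d$semi_z)),
    rod = pmin(d$radius - rho, d$length / 2 - abs(z)),
    cone = cone_surface_distance(rho, z, d$radius, d$height))
}

# Exact distance from points to an axis-aligned ellipsoid surface (any
# dimension), via the Lagrange-parameter root of
# sum(a_i^2 x_i^2 / (a_i^2 + t)^2) = 1; negative t for interior points.
ellipsoid_surface_distance <- function(pts, axes) {
  a2 <- axes^2
  apply(pts, 1, function(p) {
    if (all(p == 0)) return(min(axes))
    f <- function(t) sum(a2 * p^2 / (a2 + t)^2) - 1
    lo <- -min(a2) + 1e-12
    hi <- max(axes) * (sqrt(sum(p^2 / a2)) + 1)  # generous outer bracket
    t <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
    foot <- a2 * p / (a2 + t)
    dist <- sqrt(sum((p - foot)^2))
    if (sum(p^2 / a2) > 1) dist <- -dist   # outside: signed negative
    dist
  })
}

# Distance from interior points to a right circular cone (base radius R
# in the z = 0 plane, apex at z = h): min of distance to the base plane
# and to the lateral surface (distance to the generating segment in the
# (rho, z) half-plane).
cone_surface_distance <- function(rho, z, R, h) {
  # segment from (R, 0) to (0, h) in the (rho, z) plane
  vx <- -R; vz <- h
  L2 <- vx^2 + vz^2
  t <- pmin(pmax(((rho - R) * vx + z * vz) / L2, 0), 1)
  dl <- sqrt((rho - (R + t * vx))^2 + (z - t * vz)^2)
  pmin(dl, z)
}

#' Build a cell population on the cubic lattice
#'
#' Enumerates lattice points (pitch = spacing, anchored per the frozen
#' convention) whose shrunk-shape membership rule holds, and returns them
#' in deterministic (z, y, x) order.
#'
#' @param spec a [cluster_spec()].
#' @return an object of class `cell_population`: a data frame with columns
#'   `index`, `x`, `y`, `z` (um), `r` (distance from the cluster centre),
#'   `surface_distance`, `eligible`, `labeled`, `activity_Bq`, carrying the
#'   spec as an attribute.  Penetration eligibility is already classified
#'   per `spec$penetration_depth_um`.
#' @examples
#' cm <- cell_model(6, 5)
#' pop <- build_population(cluster_spec("sphere", list(radius = 125),
#'                                      13, cm, penetration_depth_um = 12))
#' nrow(pop)  # 3473
#' @export
build_population <- function(spec) {
  stopifnot(inherits(spec, "cluster_spec"))
  sp <- spec$spacing_um
  margin <- MARGIN_FRACTION * sp
  if (spec$shape == "pair") {
    pts <- rbind(c(0, 0, 0), c(sp, 0, 0))
    ic <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L))
  } else {
    ext <- switch(spec$shape,
      sphere = , circle = rep(spec$dims$radius, 3),
      rectangle = c(spec$dims$len_x / 2, spec$dims$len_y / 2, 0),
      ellipse = c(spec$dims$semi_x, spec$dims$semi_y, 0),
      ellipsoid = c(spec$dims$semi_x, spec$dims$semi_y, spec$dims$semi_z),
      rod = c(spec$dims$radius, spec$dims$radius, spec$dims$length / 2),
      cone = c(spec$dims$radius, spec$dims$radius, spec$dims$height))
    m <- ceiling(ext / sp) + 1
    ks <- if (spec$dimensionality == 2L) 0L else seq(-m[3], m[3])
    zoff <- if (spec$dimensionality == 2L) 0 else ANCHOR_FRACTION
    g <- expand.grid(i = seq(-m[1], m[1]), j = seq(-m[2], m[2]), k = ks)
    pts <- cbind(sp * (g$i + ANCHOR_FRACTION), sp * (g$j + ANCHOR_FRACTION),
                 sp * (g$k + zoff))
    inside <- shrunk_membership(spec, pts, margin)
    pts <- pts[inside, , drop = FALSE]
    ic <- as.matrix(g[inside, , drop = FALSE])
  }
  if (nrow(pts) == 0L)
    stop("cluster specification produces zero cells (dims too small for the spacing?)")
  ord <- order(pts[, 3], pts[, 2], pts[, 1])
  pts <- pts[ord, , drop = FALSE]
  ic <- ic[ord, , drop = FALSE]
  sd <- surface_distance(spec, pts)
  pop <- data.frame(index = seq_len(nrow(pts)),
                    x = pts[, 1], y = pts[, 2], z = pts[, 3],
                    r = sqrt(rowSums(pts^2)),
                    surface_distance = sd,
                    eligible = spec$dimensionality == 1L |
                      sd <= spec$penetration_depth_um,
                    labeled = FALSE, activity_Bq = 0)
  attr(pop, "spec") <- spec
  attr(pop, "icoords") <- unname(ic)
  class(pop) <- c("cell_population", "data.frame")
  pop
}

# Membership of lattice points in the shape shrunk by `margin`.
shrunk_membership <- function(spec, pts, margin) {
  d <- spec$dims
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  rho2 <- x^2 + y^2
  switch(spec$shape,
    sphere = rho2 + z^2 <= (d$radius - margin)^2,
    circle = rho2 <= (d$radius - margin)^2,
    rectangle = abs(x) <= d$len_x / 2 - margin &
                abs(y) <= d$len_y / 2 - margin,
    ellipse = (x / (d$semi_x - margin))^2 +
              (y / (d$semi_y - margin))^2 <= 1,
    ellipsoid = (x / (d$semi_x - margin))^2 +
                (y / (d$semi_y - margin))^2 +
                (z / (d$semi_z - margin))^2 <= 1,
    rod = rho2 <= (d$radius - margin)^2 & abs(z) <= d$length / 2 - margin,
    cone = {
      h <- d$height - margin
      ok <- z >= 0 & z <= h
      ok & sqrt(rho2) <= (d$radius - margin) * pmax(1 - z / h, 0)
    })
}

#' @export
print.cell_population <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("Cell population: %d cells, %s (%d-D), spacing %g um\n",
              nrow(x), spec$shape, spec$dimensionality, spec$spacing_um))
  cat(sprintf("  eligible for labeling: %d; labeled: %d; total activity %.4g Bq\n",
              sum(x$eligible), sum(x$labeled), sum(x$activity_Bq)))
  invisible(x)
}

#' Reclassify penetration eligibility
#'
#' A cell is eligible for labeling iff its exact distance from the
#' cluster's outer surface does not exceed the penetration depth.
#'
#' @param pop a [build_population()] result.
#' @param penetration_depth_um new penetration depth (um), or `Inf`.
#' @return the population with `eligible` recomputed (labels cleared).
#' @export
classify_penetration <- function(pop, penetration_depth_um) {
  stopifnot(inherits(pop, "cell_population"))
  spec <- attr(pop, "spec")
  spec$penetration_depth_um <- penetration_depth_um
  pop$eligible <- spec$dimensionality == 1L |
    pop$surface_distance <= penetration_depth_um
  pop$labeled <- FALSE
  pop$activity_Bq <- 0
  attr(pop, "spec") <- spec
  pop
}

#' Tomographic slicing of a 3-D population
#'
#' Partitions the cells of a 3-D cluster into axial layers of thickness
#' `axial_height` cell diameters, mirroring tomographic sections.
#'
#' @param pop a 3-D [build_population()] result.
#' @param axial_height layer thickness in cell diameters (> 0).
#' @param alive optional logical vector of alive flags to annotate.
#' @return the population data frame with a `layer` column (integer,
#'   0-based from the lowest cell) and, if given, an `alive` column; the
#'   layers partition the population.
#' @export
slice_population <- function(pop, axial_height = 1, alive = NULL) {
  stopifnot(inherits(pop, "cell_population"))
  spec <- attr(pop, "spec")
  if (spec$dimensionality != 3L) stop("slicing requires a 3-D population")
  if (axial_height <= 0) stop("axial_height must be > 0")
  h <- axial_height * 2 * spec$cell$r_cell_um
  pop$layer <- as.integer(floor((pop$z - min(pop$z)) / h + 1e-9))
  if (!is.null(alive)) {
    stopifnot(length(alive) == nrow(pop))
    pop$alive <- alive
  }
  pop
}

#' Export tomographic slices as CSV
#'
#' @param sliced a [slice_population()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_slices <- function(sliced, path) {
  cols <- intersect(c("index", "x", "y", "z", "layer", "labeled", "alive"),
                    names(sliced))
  utils::write.csv(as.data.frame(sliced)[, cols], path, row.names = FALSE)
  invisible(path)
}

# Distinct centre-to-centre distances realizable on the population's
# lattice up to a cutoff (a superset of the realized pair distances).
lattice_distances <- function(pop, max_d_um) {
  spec <- attr(pop, "spec")
  sp <- spec$spacing_um
  if (spec$shape == "pair") return(sp)
  # no realized pair distance can exceed the population's diameter
  diam <- sqrt(diff(range(pop$x))^2 + diff(range(pop$y))^2 +
                 diff(range(pop$z))^2)
  max_d_um <- min(max_d_um, diam)
  kmax <- floor((max_d_um / sp)^2 + 1e-9)
  if (kmax < 1) return(numeric())
  m <- floor(sqrt(kmax))
  g <- expand.grid(i = 0:m, j = 0:m, k = 0:m)
  s <- g$i^2 + g$j^2 + g$k^2
  sp * sqrt(sort(unique(s[s >= 1 & s <= kmax])))
}
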