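# Per-cell dosimetry: cumulated decays, self/cross absorbed-dose
# breakdowns resolved by radiation type and source region, and radial
# summaries.

#' Decays per cell from initial activity
#'
#' `activity * tau * 3600`: the time-integrated activity coefficient tau
#' (hours per unit initial activity) converts initial activity to the
#' number of nuclear transitions.  For pure physical decay tau = Tp/ln 2
#' (see [tau_physical_hours()]); any override models biological clearance.
#'
#' @param activity_Bq initial activity (Bq), >= 0; vectorized.
#' @param tau_hours time-integrated activity coefficient (h), > 0.
#' @return number of decays.
#' @export
decays_per_cell <- function(activity_Bq, tau_hours) {
  if (any(activity_Bq < 0)) stop("activity_Bq must be >= 0")
  if (tau_hours <= 0) stop("tau_hours must be > 0")
  activity_Bq * tau_hours * 3600
}

# Dose-component bookkeeping: columns are (icode, source region) pairs
# with nonzero subcellular fraction and a nonzero S entry somewhere.
dose_combos <- function(s_set, subcell, target) {
  srcs <- names(subcell)[unclass(subcell) > 0]
  srcs <- intersect(srcs, dimnames(s_set$self)[[3]])
  combos <- expand.grid(icode = ICODES, source = srcs,
                        stringsAsFactors = FALSE)
  keep <- vapply(seq_len(nrow(combos)), function(i) {
    ic <- combos$icode[i]; src <- combos$source[i]
    s_set$self[ic, target, src] != 0 ||
      any(s_set$cross[ic, target, src, ] != 0)
  }, logical(1))
  combos[keep, , drop = FALSE]
}

#' Compute per-cell absorbed-dose breakdowns
#'
#' Self components: `f_region * decays_k * S_self(target <- region)`.
#' Cross components: sum over labeled cells j != k of
#' `f_region * decays_j * S_cross(target_k <- region_j, d_kj)`, looked up
#' exactly in the precomputed distance table (a missing lattice distance
#' is a hard error).  Photons contribute nothing.  Accumulation runs in
#' fixed cell order, so totals are reproducible bit for bit.
#'
#' @param pop a labeled, activity-assigned [cell_population].
#' @param s_set an [s_table()] covering every realized lattice distance up
#'   to the range cutoff.
#' @param subcell a [subcellular_split()] (defaults to the one stored on
#'   the population).
#' @param tau_hours time-integrated activity coefficient (h).
#' @param target target region for the breakdown (`"N"`, `"C"`, `"Cy"`).
#' @return an object of class `dose_result`: the population with a
#'   `decays` column, plus matrices `dose_self` and `dose_cross`
#'   (cells x components, Gy), the component table, and totals.
#' @export
compute_doses <- function(pop, s_set, subcell = NULL, tau_hours,
                          target = "N") {
  stopifnot(inherits(pop, "cell_population"),
            inherits(s_set, "s_coefficient_set"))
  target <- match.arg(target, REGIONS_TARGET)
  if (!target %in% dimnames(s_set$self)[[2]])
    stop("s_set does not tabulate target region ", target)
  subcell <- subcell %||% attr(pop, "subcell")
  if (is.null(subcell)) stop("no subcellular split given or stored on pop")
  n <- nrow(pop)
  decays <- decays_per_cell(pop$activity_Bq, tau_hours)
  combos <- dose_combos(s_set, subcell, target)
  nc <- nrow(combos)
  lbl <- sprintf("%s_from_%s", combos$icode, combos$source)
  dose_self <- matrix(0, n, nc, dimnames = list(NULL, lbl))
  dose_cross <- matrix(0, n, nc, dimnames = list(NULL, lbl))
  f <- unclass(subcell)[combos$source]
  s_self_vec <- vapply(seq_len(nc), function(i)
    s_set$self[combos$icode[i], target, combos$source[i]], numeric(1))
  for (i in seq_len(nc))
    dose_self[, i] <- f[i] * decays * s_self_vec[i]
  # cross: lattice distances are exact multiples of known keys
  sources <- which(decays > 0)
  if (length(sources) > 0L && n > 1L) {
    ndist <- length(s_set$distances_um)
    cross_mat <- if (ndist == 0L) matrix(0, nc, 0) else
      t(vapply(seq_len(nc), function(i)
        s_set$cross[combos$icode[i], target, combos$source[i], ],
        numeric(ndist)))                           # nc x ndist
    keys <- round(s_set$distances_um, 6)
    P <- as.matrix(pop[, c("x", "y", "z")])
    cutoff2 <- (s_set$cutoff_um + 1e-6)^2
    for (j in sources) {
      d2 <- (P[, 1] - P[j, 1])^2 + (P[, 2] - P[j, 2])^2 +
        (P[, 3] - P[j, 3])^2
      near <- which(d2 > 1e-12 & d2 <= cutoff2)
      if (length(near) == 0L) next
      idx <- match(round(sqrt(d2[near]), 6), keys)
      if (anyNA(idx))
        stop("realized lattice distance missing from the S table: ",
             paste(utils::head(sqrt(d2[near][is.na(idx)])), collapse = ", "))
      contrib <- t(cross_mat[, idx, drop = FALSE]) * decays[j]  # near x nc
      contrib <- sweep(contrib, 2, f, `*`)
      dose_cross[near, ] <- dose_cross[near, ] + contrib
    }
  }
  pop$decays <- decays
  structure(list(cells = pop, target = target, combos = combos,
                 dose_self = dose_self, dose_cross = dose_cross,
                 self_Gy = rowSums(dose_self), cross_Gy = rowSums(dose_cross),
                 total_Gy = rowSums(dose_self) + rowSums(dose_cross),
                 tau_hours = tau_hours, subcell = subcell),
            class = "dose_result")
}

#' @export
print.dose_result <- function(x, ...) {
  cat(sprintf("Dose result: target %s, %d cells, tau = %g h\n",
              x$target, nrow(x$cells), x$tau_hours))
  cat(sprintf("  mean dose %.4g Gy (self %.4g, cross %.4g); max %.4g Gy\n",
              mean(x$total_Gy), mean(x$self_Gy), mean(x$cross_Gy),
              max(x$total_Gy)))
  invisible(x)
}

#' Radial summary of activity, decays and dose
#'
#' Bins the cells of a 3-D cluster by distance from the cluster centre and
#' reports, per bin: mean activity per labeled cell, mean self-dose to
#' labeled cells, mean cross-dose to labeled cells, mean cross-dose to
#' unlabeled cells, mean decays per labeled cell, and mean dose to all
#' cells.  Bins with no qualifying cells report `NA` (not zero).
#'
#' @param doses a [compute_doses()] result for a 3-D population.
#' @param bin_width_um radial bin width (um), > 0.
#' @return data frame, one row per radial bin.
#' @export
radial_summary <- function(doses, bin_width_um) {
  stopifnot(inherits(doses, "dose_result"))
  if (bin_width_um <= 0) stop("bin_width_um must be > 0")
  pop <- doses$cells
  if (attr(pop, "spec")$dimensionality != 3L)
    stop("radial summaries require a 3-D population")
  bin <- floor(pop$r / bin_width_um)
  bins <- seq(0, max(bin))
  lab <- pop$labeled
  stat <- function(v, sel) vapply(bins, function(b) {
    i <- bin == b & sel
    if (!any(i)) NA_real_ else mean(v[i])
  }, numeric(1))
  data.frame(
    r_lo_um = bins * bin_width_um,
    r_hi_um = (bins + 1) * bin_width_um,
    n_cells = vapply(bins, function(b) sum(bin == b), numeric(1)),
    n_labeled = vapply(bins, function(b) sum(bin == b & lab), numeric(1)),
    mean_activity_labeled_Bq = stat(pop$activity_Bq, lab),
    mean_self_dose_labeled_Gy = stat(doses$self_Gy, lab),
    mean_cross_dose_labeled_Gy = stat(doses$cross_Gy, lab),
    mean_cross_dose_unlabeled_Gy = stat(doses$cross_Gy, !lab),
    mean_decays_labeled = stat(pop$decays, lab),
    mean_dose_all_Gy = stat(doses$total_Gy, rep(TRUE, nrow(pop))))
}

#' Export the per-cell dose table as CSV
#'
#' @param doses a [compute_doses()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(doses, path) {
  stopifnot(inherits(doses, "dose_result"))
  pop <- doses$cells
  icodes <- unique(doses$combos$icode)
  per_icode <- vapply(icodes, function(ic) {
    sel <- doses$combos$icode == ic
    rowSums(doses$dose_self[, sel, drop = FALSE]) +
      rowSums(doses$dose_cross[, sel, drop = FALSE])
  }, numeric(nrow(pop)))
  colnames(per_icode) <- paste0("dose_", icodes, "_Gy")
  df <- data.frame(index = pop$index, x = pop$x, y = pop$y, z = pop$z,
                   labeled = pop$labeled, activity_Bq = pop$activity_Bq,
                   decays = pop$decays,
                   self_dose_Gy = doses$self_Gy,
                   cross_dose_Gy = doses$cross_Gy,
                   total_dose_Gy = doses$total_Gy)
  utils::write.csv(cbind(df, per_icode), path, row.names = FALSE)
  invisible(path)
}
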