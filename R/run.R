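# Run configuration and the full pipeline: source spectrum -> cell model
# -> cluster -> labeling -> S table -> per-cell doses -> survival/TCP ->
# output dump.  A run is fully reproducible from its echoed configuration
# and master seed.

#' Load and validate a run configuration
#'
#' The configuration is a named list (or a YAML file of one) with blocks:
#' \describe{
#'   \item{source}{`type` = `"radionuclide"` (with `name`, chain-expanded),
#'     `"monoenergetic"` (with `particle`, `energy_MeV`, optional `yield`)
#'     or `"file"` (with `path`).}
#'   \item{cell}{`r_cell_um`, `r_nucleus_um`.}
#'   \item{cluster}{`shape`, `dims` (named list, um), `spacing_um`,
#'     optional `penetration_depth_um`.}
#'   \item{labeling}{`method`, `percent_labeled`, and the method's
#'     parameters (`mean_activity_Bq`, `sigma`, `radial_params`,
#'     `max_mean_activity_Bq`).}
#'   \item{subcellular}{`f_N`, `f_Cy`, `f_CS` (default: all on the cell
#'     surface).}
#'   \item{tau_h}{time-integrated activity coefficient in hours, or
#'     `"physical"` for Tp/ln 2 of the source radionuclide.}
#'   \item{lq}{either `simple = list(alpha_self, beta_self, alpha_cross,
#'     beta_cross)` or `complex = list(path = <csv>, set = list(...))`
#'     where each `set` entry holds selectors and new `alpha`/`beta` for
#'     [set_lq()].}
#'   \item{sweep}{`n_points` (default 21).}
#'   \item{seed}{master seed (default 1).}
#'   \item{target}{target region (default `"N"`).}
#' }
#'
#' @param config a named list or path to a YAML file.
#' @return the validated configuration (class `run_config`).
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (block in c("source", "cell", "cluster", "labeling", "tau_h"))
    if (is.null(config[[block]]))
      stop("configuration is missing the required field '", block, "'")
  st <- config$source$type %||%
    stop("configuration field 'source$type' is missing")
  if (!st %in% c("radionuclide", "monoenergetic", "file"))
    stop("unknown source$type: ", st)
  if (st == "radionuclide" && is.null(config$source$name))
    stop("source$name is required for type 'radionuclide'")
  if (identical(config$tau_h, "physical") && st != "radionuclide")
    stop("tau_h = 'physical' requires a radionuclide source")
  config$subcellular <- config$subcellular %||% list(f_N = 0, f_Cy = 0, f_CS = 1)
  config$seed <- config$seed %||% 1L
  config$target <- config$target %||% "N"
  config$sweep <- config$sweep %||% list(n_points = 21)
  structure(config, class = c("run_config", "list"))
}

config_spectrum <- function(config) {
  s <- config$source
  switch(s$type,
    radionuclide = expand_chain(get_radionuclide(s$name)),
    monoenergetic = make_monoenergetic(s$particle, s$energy_MeV,
                                       s$yield %||% 1),
    file = read_radiation_file(s$path))
}

config_tau_hours <- function(config) {
  if (identical(config$tau_h, "physical"))
    tau_physical_hours(get_radionuclide(config$source$name))
  else as.numeric(config$tau_h)
}

config_lq <- function(config) {
  lq <- config$lq
  if (is.null(lq)) return(default_lq_table())
  if (!is.null(lq$simple)) return(do.call(lq_simple, lq$simple))
  cx <- lq$complex %||% stop("lq block must contain 'simple' or 'complex'")
  tab <- if (!is.null(cx$path)) read_lq_table(cx$path) else default_lq_table()
  for (s in cx$set %||% list()) tab <- do.call(set_lq, c(list(tab), s))
  tab
}

# Maximum dosimetric particle range of a spectrum (um).
max_range_um <- function(spectrum, electron_relation = "cole") {
  rs <- 0
  for (i in seq_len(nrow(spectrum$lines))) {
    ln <- spectrum$lines[i, ]
    if (!ln$dosimetric) next
    model <- model_for_icode(ln$icode, electron_relation)
    rs <- max(rs, model$range_um(ln$energy_MeV))
  }
  rs
}

#' Execute a full run
#'
#' Runs the whole pipeline and (optionally) writes the output dump:
#' configuration echo, self/cross S-coefficient tables, per-cell dose
#' table, radial summaries, SF/TCP curves, tomographic slices and a run
#' log of warnings.
#'
#' @param config a [run_config()] (or anything it accepts).
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @return an object of class `run_result` with the population, S table,
#'   dose result, SF/TCP curve, final-point fates, radial summary and the
#'   collected warnings.
#' @export
run <- function(config, out_dir = NULL) {
  config <- run_config(config)
  warn_log <- character()
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warn_log <<- c(warn_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  spectrum <- config_spectrum(config)
  cellm <- collect(cell_model(config$cell$r_cell_um, config$cell$r_nucleus_um))
  cspec <- cluster_spec(config$cluster$shape, config$cluster$dims,
                        config$cluster$spacing_um, cellm,
                        config$cluster$penetration_depth_um %||% Inf)
  pop <- build_population(cspec)
  aspec <- activity_spec(config$labeling$method,
                         config$labeling$mean_activity_Bq,
                         config$labeling$sigma,
                         config$labeling$radial_params,
                         config$labeling$percent_labeled %||% 100,
                         config$labeling$max_mean_activity_Bq)
  subcell <- do.call(subcellular_split, config$subcellular)
  pop <- collect(label_population(pop, aspec, subcell, config$seed))
  tau <- config_tau_hours(config)
  rmax <- max_range_um(spectrum)
  dists <- lattice_distances(pop, rmax + 2 * cellm$r_cell_um)
  srcs <- names(subcell)[unclass(subcell) > 0]
  s_set <- s_table(spectrum, cellm, dists, sources = srcs,
                   targets = config$target)
  doses <- compute_doses(pop, s_set, subcell, tau, config$target)
  lq <- config_lq(config)
  curve <- collect(sf_curve(doses, lq, config$sweep$n_points %||% 21,
                            config$seed))
  P <- if (inherits(lq, "lq_simple"))
    survival_simple(doses$self_Gy, doses$cross_Gy, lq)
  else collect(survival_complex(doses, lq))
  fates <- monte_carlo_fates(P, stream_seed(config$seed,
                                            sprintf("sweep_%03d", nrow(curve))))
  radial <- if (cspec$dimensionality == 3L)
    radial_summary(doses, config$radial_bin_um %||% cspec$spacing_um)
  sliced <- if (cspec$dimensionality == 3L)
    slice_population(pop, 1, alive = fates$alive)
  res <- structure(list(config = config, population = pop, s_set = s_set,
                        doses = doses, curve = curve, survival = P,
                        fates = fates, radial = radial, sliced = sliced,
                        warnings = warn_log),
                   class = "run_result")
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

#' @export
print.run_result <- function(x, ...) {
  cat("celldose run:", x$config$source$type, "source,",
      nrow(x$population), "cells\n")
  cat(sprintf("  labeled %d; final SF(expected) %.4g, SF(MC) %.4g; TCP(Poisson) %.4g, TCP(product) %.4g\n",
              sum(x$population$labeled),
              x$curve$sf_expected[nrow(x$curve)],
              x$curve$sf_mc[nrow(x$curve)],
              x$curve$tcp_poisson[nrow(x$curve)],
              x$curve$tcp_product[nrow(x$curve)]))
  if (length(x$warnings))
    cat("  warnings:", paste(unique(x$warnings), collapse = " | "), "\n")
  invisible(x)
}

#' Write the output dump of a run
#'
#' @param res a [run()] result.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(res, out_dir) {
  stopifnot(inherits(res, "run_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  yaml::write_yaml(unclass(res$config), p("config_echo.yaml"))
  write_s_table(res$s_set, p("s_coefficients.csv"))
  write_cell_table(res$doses, p("cells.csv"))
  utils::write.csv(as.data.frame(res$curve), p("sf_curve.csv"),
                   row.names = FALSE)
  if (!is.null(res$radial))
    utils::write.csv(res$radial, p("radial_summary.csv"), row.names = FALSE)
  if (!is.null(res$sliced)) write_slices(res$sliced, p("slices.csv"))
  writeLines(c(sprintf("celldose run log"),
               sprintf("cells: %d, labeled: %d", nrow(res$population),
                       sum(res$population$labeled)),
               sprintf("warnings (%d):", length(res$warnings)),
               paste(" -", res$warnings)), p("run.log"))
  invisible(out_dir)
}
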