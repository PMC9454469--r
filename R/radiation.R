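# Radiation source definitions: emission lines, radionuclides, decay-chain
# expansion under secular equilibrium, and the user radiation-file format.

#' Construct a radiation spectrum from emission lines
#'
#' A radiation spectrum is the list of emission lines of a source, each
#' carrying a radiation-type code (ICODE category), a yield per nuclear
#' transition of the parent, and an energy in MeV.  Beta decays are
#' represented by their average-energy line.  Photon lines (gamma, X ray)
#' are retained in the spectrum but flagged non-dosimetric: they contribute
#' nothing to any absorbed dose computed by this package.
#'
#' @param lines data frame with columns `icode`, `yield_per_decay`,
#'   `energy_MeV`.
#' @param name source name.
#' @return an object of class `radiation_spectrum`.  The `lines` element
#'   gains columns `delta_MeV` (mean energy emitted per parent transition,
#'   yield x energy) and `dosimetric` (FALSE for photons).
#' @seealso [make_monoenergetic()], [expand_chain()], [read_radiation_file()]
#' @export
radiation_spectrum <- function(lines, name = "custom") {
  stopifnot(is.data.frame(lines),
            all(c("icode", "yield_per_decay", "energy_MeV") %in% names(lines)))
  if (nrow(lines) == 0L) stop("spectrum has no emission lines")
  bad <- setdiff(unique(lines$icode), ICODES)
  if (length(bad) > 0L)
    stop("unknown radiation-type code(s): ", paste(bad, collapse = ", "),
         " (expected one of: ", paste(ICODES, collapse = ", "), ")")
  if (any(lines$yield_per_decay < 0))
    stop("yield_per_decay must be >= 0")
  if (any(lines$energy_MeV <= 0))
    stop("energy_MeV must be > 0")
  lines <- lines[, c("icode", "yield_per_decay", "energy_MeV")]
  lines$delta_MeV <- lines$yield_per_decay * lines$energy_MeV
  lines$dosimetric <- !(lines$icode %in% PHOTON_ICODES)
  structure(list(name = name, lines = lines), class = "radiation_spectrum")
}

#' @export
print.radiation_spectrum <- function(x, ...) {
  cat("Radiation spectrum:", x$name, "\n")
  cat(sprintf("  %d emission lines; Delta(total) = %.4g MeV/decay (%.4g dosimetric)\n",
              nrow(x$lines), sum(x$lines$delta_MeV),
              sum(x$lines$delta_MeV[x$lines$dosimetric])))
  print(x$lines, row.names = FALSE)
  invisible(x)
}

#' Monoenergetic particle source
#'
#' @param particle `"electron"` or `"alpha"`.
#' @param energy_MeV particle energy (MeV), > 0.
#' @param yield emissions per decay, > 0.
#' @return a [radiation_spectrum()] with a single line; electrons are coded
#'   as internal-conversion electrons for transport purposes (all electron
#'   categories share the electron range-energy model).
#' @examples
#' make_monoenergetic("electron", 0.050)
#' @export
make_monoenergetic <- function(particle = c("electron", "alpha"),
                               energy_MeV, yield = 1) {
  particle <- match.arg(particle)
  if (!is.numeric(energy_MeV) || length(energy_MeV) != 1L || energy_MeV <= 0)
    stop("energy_MeV must be a single positive number")
  if (!is.numeric(yield) || length(yield) != 1L || yield <= 0)
    stop("yield must be a single positive number")
  icode <- if (particle == "alpha") "alpha" else "ic_electron"
  radiation_spectrum(
    data.frame(icode = icode, yield_per_decay = yield, energy_MeV = energy_MeV),
    name = sprintf("monoenergetic %s %.4g MeV", particle, energy_MeV))
}

#' Define a radionuclide
#'
#' @param name nuclide name.
#' @param half_life_s physical half-life in seconds (> 0; `Inf` for a
#'   stable chain terminator).
#' @param emissions data frame of emission lines (as for
#'   [radiation_spectrum()]); may have zero rows for a terminator.
#' @param daughters list of `list(nuclide = <radionuclide>, fraction = f)`
#'   branches; fractions in `[0, 1]` summing to at most 1.
#' @return an object of class `radionuclide`.
#' @export
radionuclide <- function(name, half_life_s, emissions = NULL,
                         daughters = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(half_life_s) || half_life_s <= 0)
    stop("half_life_s must be > 0")
  if (is.null(emissions))
    emissions <- data.frame(icode = character(), yield_per_decay = numeric(),
                            energy_MeV = numeric())
  fr <- vapply(daughters, function(d) d$fraction, numeric(1))
  if (any(fr < 0 | fr > 1)) stop("branching fractions must lie in [0, 1]")
  if (sum(fr) > 1 + 1e-9) stop("branching fractions sum to more than 1")
  structure(list(name = name, half_life_s = half_life_s,
                 emissions = emissions, daughters = daughters),
            class = "radionuclide")
}

#' Time-integrated activity coefficient for pure physical decay
#'
#' For a source that decays in place with no biological clearance the
#' time-integrated activity per unit initial activity is Tp / ln 2.
#'
#' @param x a `radionuclide`, or a half-life in seconds.
#' @return tau in hours.
#' @export
tau_physical_hours <- function(x) {
  tp <- if (inherits(x, "radionuclide")) x$half_life_s else x
  stopifnot(is.numeric(tp), tp > 0, is.finite(tp))
  tp / log(2) / 3600
}

#' Expand a decay chain under secular equilibrium
#'
#' All emissions of every descendant are merged into a single spectrum,
#' with each nuclide's yields scaled by the product of branching fractions
#' along the chain from the parent (daughters assumed in equilibrium with
#' the parent, i.e. one daughter transition per parent transition times the
#' cumulative branching).
#'
#' @param parent a [radionuclide()] heading a finite acyclic chain.
#' @return a [radiation_spectrum()] named `"<parent> + daughters"`.
#' @export
expand_chain <- function(parent) {
  stopifnot(inherits(parent, "radionuclide"))
  rows <- list()
  walk <- function(nuc, cum, path) {
    if (nuc$name %in% path)
      stop("cyclic chain definition at nuclide ", nuc$name)
    if (nrow(nuc$emissions) > 0L) {
      em <- nuc$emissions
      em$yield_per_decay <- em$yield_per_decay * cum
      em$nuclide <- nuc$name
      rows[[length(rows) + 1L]] <<- em
    }
    for (d in nuc$daughters)
      walk(d$nuclide, cum * d$fraction, c(path, nuc$name))
  }
  walk(parent, 1, character())
  if (length(rows) == 0L) stop("chain emits no radiation")
  all <- do.call(rbind, rows)
  sp <- radiation_spectrum(all, name = paste(parent$name, "+ daughters"))
  sp$lines$nuclide <- all$nuclide
  sp
}

# ---- packaged sources ------------------------------------------------------

load_nuclide_db <- function() {
  list(nuclides = read_extdata_csv("nuclides.csv"),
       emissions = read_extdata_csv("emissions.csv"),
       branches = read_extdata_csv("branches.csv"))
}

#' Retrieve a packaged radionuclide (with its decay chain)
#'
#' @param name nuclide name as listed by [list_sources()], e.g. `"Bi-213"`.
#' @return a [radionuclide()] whose daughters are populated recursively from
#'   the packaged chain tables.
#' @export
get_radionuclide <- function(name) {
  db <- load_nuclide_db()
  build <- function(nm, path = character()) {
    if (nm %in% path) stop("cyclic packaged chain at ", nm)
    row <- db$nuclides[db$nuclides$name == nm, ]
    if (nrow(row) == 0L) stop("unknown packaged nuclide: ", nm)
    em <- db$emissions[db$emissions$nuclide == nm,
                       c("icode", "yield_per_decay", "energy_MeV")]
    kids <- db$branches[db$branches$parent == nm, ]
    daughters <- list()
    if (!row$terminal && nrow(kids) > 0L) {
      daughters <- lapply(seq_len(nrow(kids)), function(i)
        list(nuclide = build(kids$daughter[i], c(path, nm)),
             fraction = kids$fraction[i]))
    }
    radionuclide(nm, as.numeric(row$half_life_s), em, daughters)
  }
  build(name)
}

#' List the packaged radiation sources
#'
#' @return character vector of packaged nuclide names (chain parents and
#'   their descendants).
#' @export
list_sources <- function() {
  db <- load_nuclide_db()
  db$nuclides$name[!as.logical(db$nuclides$terminal)]
}

# ---- user radiation files --------------------------------------------------

#' Read a user-defined radiation file
#'
#' The file is CSV with header `icode,yield,energy_MeV`; comment lines
#' start with `#`.  One emission per row.  Malformed rows are reported with
#' their line numbers.
#'
#' @param path file path.
#' @param name source name (defaults to the file name).
#' @return a [radiation_spectrum()].
#' @export
read_radiation_file <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineno <- which(keep)
  raw <- raw[keep]
  if (length(raw) < 2L) stop("radiation file has no emission rows: ", path)
  hdr <- tolower(trimws(strsplit(raw[1L], ",")[[1L]]))
  if (!identical(hdr[1:3], c("icode", "yield", "energy_mev")))
    stop("radiation file header must be 'icode,yield,energy_MeV'")
  rows <- lapply(seq_along(raw[-1L]), function(i) {
    f <- trimws(strsplit(raw[i + 1L], ",")[[1L]])
    ln <- lineno[i + 1L]
    if (length(f) < 3L)
      stop(sprintf("line %d: expected 3 fields, got %d", ln, length(f)))
    y <- suppressWarnings(as.numeric(f[2L]))
    e <- suppressWarnings(as.numeric(f[3L]))
    if (!(f[1L] %in% ICODES))
      stop(sprintf("line %d: unknown icode token '%s'", ln, f[1L]))
    if (is.na(y) || y < 0)
      stop(sprintf("line %d: yield must be a non-negative number", ln))
    if (is.na(e) || e <= 0)
      stop(sprintf("line %d: energy_MeV must be a positive number", ln))
    data.frame(icode = f[1L], yield_per_decay = y, energy_MeV = e)
  })
  radiation_spectrum(do.call(rbind, rows), name = name)
}

#' Write a radiation spectrum in the user radiation-file format
#'
#' @param spectrum a [radiation_spectrum()].
#' @param path output path.
#' @return `path`, invisibly.  `read_radiation_file()` on the result
#'   reproduces the spectrum.
#' @export
write_radiation_file <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "radiation_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# ", spectrum$name), "icode,yield,energy_MeV"), con)
  writeLines(sprintf("%s,%.10g,%.10g", spectrum$lines$icode,
                     spectrum$lines$yield_per_decay,
                     spectrum$lines$energy_MeV), con)
  invisible(path)
}
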