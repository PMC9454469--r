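# Internal constants and helpers shared across modules.

# Radiation-type codes (ICODE categories).  Photon types are parsed and
# stored but excluded from all dose computation.
ICODES <- c("alpha", "beta_minus", "beta_plus", "ic_electron", "auger",
            "gamma", "xray")
ELECTRON_ICODES <- c("beta_minus", "beta_plus", "ic_electron", "auger")
PHOTON_ICODES <- c("gamma", "xray")

REGIONS_SOURCE <- c("C", "N", "Cy", "CS")
REGIONS_TARGET <- c("C", "N", "Cy")

# 1 MeV deposited per kg of unit-density water, with lengths in um:
# J/MeV divided by kg/um^3 (rho = 1 g/cm^3 = 1e-15 kg/um^3).
MEV_PER_UM3_TO_GY <- 1.602176634e-13 / 1e-15

WATER_DENSITY_KG_PER_UM3 <- 1e-15

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "celldose")
  if (!nzchar(p)) stop("packaged data file not found: ", file)
  p
}

read_extdata_csv <- function(file) {
  utils::read.csv(extdata_path(file), comment.char = "#",
                  stringsAsFactors = FALSE)
}

# Gauss-Legendre nodes/weights on [a, b], cached per order.
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n, a = -1, b = 1) {
  key <- as.character(n)
  gl <- .gl_cache[[key]]
  if (is.null(gl)) {
    gl <- pracma::gaussLegendre(n, -1, 1)
    .gl_cache[[key]] <- gl
  }
  list(x = (a + b) / 2 + (b - a) / 2 * gl$x,
       w = (b - a) / 2 * gl$w)
}

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All stochastic steps (labeled-cell selection, activity sampling, Monte
#' Carlo cell fates, the Monte Carlo S-coefficient oracle) draw from
#' independent named streams derived from one master seed, so changing one
#' stochastic choice does not perturb the draws of another.
#'
#' @param master integer master seed.
#' @param stream character stream name.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
stream_seed <- function(master, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (as.double(master) %% 2147483647) * 48271) %% 2147483646 + 1)
}

# Evaluate expr with the RNG seeded from (master, stream), restoring the
# caller's RNG state afterwards.
with_stream <- function(master, stream, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(stream_seed(master, stream))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
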