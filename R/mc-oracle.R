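# Independent straight-line Monte Carlo estimator of absorbed fractions
# and S coefficients.  It shares only the range-energy model with the
# analytic engine; positions, directions and chord bookkeeping are sampled
# brute-force, so agreement between the two is a genuine cross-check of
# the analytic quadrature.

# Energy deposited inside a sphere (centre ctr, radius R) by straight
# tracks from points P (n x 3) along unit directions W (n x 3), for
# particles of energy E0.  Exact under CSDA: difference of residual
# energies at the clamped chord entry/exit points.
deposit_in_sphere <- function(model, E0, P, W, ctr, R) {
  range0 <- model$range_um(E0)
  rel <- sweep(P, 2, ctr)
  b <- rowSums(rel * W)
  c0 <- rowSums(rel * rel) - R^2
  disc <- b^2 - c0
  dep <- numeric(nrow(P))
  hit <- disc > 0
  if (any(hit)) {
    sq <- sqrt(disc[hit])
    t1 <- pmin(pmax(-b[hit] - sq, 0), range0)
    t2 <- pmin(pmax(-b[hit] + sq, 0), range0)
    ok <- t2 > t1
    if (any(ok)) {
      i <- which(hit)[ok]
      dep[i] <- residual_energy(model, E0, t1[ok]) -
        residual_energy(model, E0, t2[ok])
    }
  }
  dep
}

# Sample n points uniformly in the source region of `cell` (cell centred
# at the origin).
sample_source_points <- function(cell, source, n) {
  b <- source_bounds(cell, source)
  r <- if (b[1] == b[2]) rep(b[1], n)
       else (b[1]^3 + stats::runif(n) * (b[2]^3 - b[1]^3))^(1 / 3)
  z <- stats::runif(n, -1, 1)
  ph <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(r * s * cos(ph), r * s * sin(ph), r * z)
}

sample_directions <- function(n) {
  z <- stats::runif(n, -1, 1)
  ph <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(s * cos(ph), s * sin(ph), z)
}

#' Monte Carlo estimate of a cellular S coefficient
#'
#' Brute-force estimator under the same straight-line CSDA physics as the
#' analytic engine: decay positions are sampled uniformly in the source
#' region, directions isotropically, and the energy deposited in the
#' target region is tallied from residual energies at the chord
#' entry/exit points (exact per track, no stepping artifacts).
#'
#' @inheritParams self_s
#' @param d_um centre-to-centre distance to the target cell (0 = self).
#' @param n_histories number of decay histories (>= 1000).
#' @param seed integer seed for the oracle's private RNG stream.
#' @return an object of class `oracle_estimate` with elements
#'   `S_Gy_per_decay` (summed over dosimetric lines), `per_icode`,
#'   `standard_error`, and `n_histories`.
#' @export
mc_estimate_s <- function(spectrum, cell, source, target, d_um = 0,
                          n_histories = 1e5, seed = 1,
                          electron_relation = "cole") {
  stopifnot(inherits(spectrum, "radiation_spectrum"),
            inherits(cell, "cell_model"))
  source <- match.arg(source, REGIONS_SOURCE)
  target <- match.arg(target, REGIONS_TARGET)
  if (n_histories < 1000)
    stop("n_histories < 1000 gives meaningless error bars")
  if (d_um > 0 && d_um < 2 * cell$r_cell_um - 1e-9)
    stop("overlapping cells: d_um must be >= 2 * r_cell_um")
  m <- region_mass(cell, target)
  ctr <- c(d_um, 0, 0)
  per_icode <- stats::setNames(numeric(length(ICODES)), ICODES)
  var_sum <- 0
  with_stream(seed, "mc_oracle", {
    for (i in seq_len(nrow(spectrum$lines))) {
      ln <- spectrum$lines[i, ]
      if (!ln$dosimetric || ln$delta_MeV == 0) next
      model <- model_for_icode(ln$icode, electron_relation)
      P <- sample_source_points(cell, source, n_histories)
      W <- sample_directions(n_histories)
      dep <- deposit_in_sphere(model, ln$energy_MeV, P, W, ctr,
                               cell$r_cell_um)
      if (target != "C") {
        depN <- deposit_in_sphere(model, ln$energy_MeV, P, W, ctr,
                                  cell$r_nucleus_um)
        dep <- if (target == "N") depN else dep - depN
      }
      scale <- ln$yield_per_decay * 1.602176634e-13 / m
      per_icode[ln$icode] <- per_icode[ln$icode] + mean(dep) * scale
      var_sum <- var_sum + stats::var(dep) / n_histories * scale^2
    }
  })
  structure(list(S_Gy_per_decay = sum(per_icode), per_icode = per_icode,
                 standard_error = sqrt(var_sum), n_histories = n_histories,
                 source = source, target = target, d_um = d_um),
            class = "oracle_estimate")
}

#' @export
print.oracle_estimate <- function(x, ...) {
  cat(sprintf("MC oracle: S(%s <- %s%s) = %.6g +/- %.2g Gy/decay (%g histories)\n",
              x$target, x$source,
              if (x$d_um > 0) sprintf(", d = %g um", x$d_um) else "",
              x$S_Gy_per_decay, x$standard_error, x$n_histories))
  invisible(x)
}
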