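# Shared fixtures: the reference cell geometry and a couple of spectra.

ref_cell <- function() cell_model(6, 5)

e50 <- function() make_monoenergetic("electron", 0.050)
a5 <- function() make_monoenergetic("alpha", 5.0)

# Worked-example configuration: surface-labeled 213Bi on a 125-um
# spheroid (outer-layer labeling, alpha-only response).
worked_example_config <- function(seed = 42) {
  list(
    source = list(type = "radionuclide", name = "Bi-213"),
    cell = list(r_cell_um = 6, r_nucleus_um = 5),
    cluster = list(shape = "sphere", dims = list(radius = 125),
                   spacing_um = 13, penetration_depth_um = 12),
    labeling = list(method = "radial_exponential", percent_labeled = 100,
                    radial_params = 0.4, max_mean_activity_Bq = 0.02),
    subcellular = list(f_N = 0, f_Cy = 0, f_CS = 1),
    tau_h = 1.11,
    lq = list(complex = list(set = list(
      list(icode = "alpha", alpha = 0.56, beta = 0),
      list(icode = c("beta_minus", "beta_plus", "ic_electron", "auger"),
           alpha = 0, beta = 0)))),
    seed = seed)
}

# A small spherical cluster that runs the full pipeline quickly.
small_sphere_config <- function(seed = 7) {
  cfg <- worked_example_config(seed)
  cfg$cluster$dims$radius <- 40
  cfg$cluster$penetration_depth_um <- Inf
  cfg$labeling <- list(method = "uniform", percent_labeled = 100,
                       mean_activity_Bq = 0.01)
  cfg
}
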