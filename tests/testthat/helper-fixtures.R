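# Canonical symmetric pair: 1.6 cm apart, 1 mm conductor radius, 1300 V.
std_pair <- function(voltage = 1300, rho0 = 0.001) {
  electrical_axes(electrode(-0.008, 0, "anode", "a"),
                  electrode(0.008, 0, "cathode", "c"),
                  rho0 = rho0, voltage = voltage)
}

std_layout <- function(voltage = 1300, spacing = 0.016) {
  make_fixture_layout("pair", spacing = spacing, voltage = voltage)
}

# Synthetic field map with prescribed values (V/m) on a small mesh; used to
# exercise coverage analytics on exactly known inputs.
synthetic_map <- function(values, layout, mask = NULL) {
  spec <- mesh_spec(layout$tissue_side, ncol(values), nrow(values))
  if (is.null(mask)) mask <- matrix(FALSE, nrow(values), ncol(values))
  vals <- values
  vals[mask] <- NA_real_
  structure(list(spec = spec, values = vals, mask = mask, layout = layout),
            class = "nf_field_map")
}

# Random admissible (d_AB, rho0) draws for property sweeps.
random_pair_params <- function(n, d_range = c(5e-3, 5e-2),
                               ratio_range = c(0.02, 0.45)) {
  d <- runif(n, d_range[1], d_range[2])
  rho0 <- d * runif(n, ratio_range[1], ratio_range[2]) / 2
  data.frame(d = d, rho0 = rho0)
}
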