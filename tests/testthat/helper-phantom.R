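# Small-scale geometries and phantoms shared across tests. Full instrument
# resolution (5012 A-lines x 4050 B-scans) is never needed to exercise the
# algorithms; these sizes keep every property visible while staying fast.

small_geom <- function(a_lines = 240L, n_bscans = 4L, n_depth = 300L) {
  scan_geometry(a_lines_per_bscan = a_lines, n_bscans = n_bscans,
                n_depth_samples = n_depth)
}

# phantom with all stochastic artifacts disabled (deterministic geometry)
quiet_phantom <- function(seed = 1L, ...) {
  phantom_spec(speckle_model = list(type = "none"), noise_floor = 0,
               detachment = list(n_gaps = 0L, angular_width = 0,
                                 max_radial_offset = 0),
               motion_jitter = list(radial_sd_um = 0, angular_sd_deg = 0),
               crypt_modulation = list(amplitude = 0, angular_period = 12),
               surface_undulation = 0, wall_modulation = 0,
               interface_gain = 0, seed = seed, ...)
}

# four named layers with chosen thicknesses/attenuations
make_layers <- function(thickness, attenuation,
                        reflectivity = c(0.25, 0.18, 0.22, 0.15)) {
  nm <- c("colonic_mucosa", "muscularis_mucosa", "submucosa",
          "muscularis_propria")
  mapply(layer_spec, nm, thickness, attenuation, reflectivity,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}
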