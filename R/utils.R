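# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Depth sample index (0-based, fractional) of a radius in mm. Depth sample 0
# sits `depth0_margin_px` samples inside the sheath inner radius so that both
# sheath walls are visible in the recorded A-scan.
depth0_margin_px <- 10L

depth0_radius <- function(geom) {
  geom$sheath_inner_radius - depth0_margin_px * geom$axial_pixel_pitch / 1000
}

radius_to_depth <- function(r_mm, geom, r0_mm = depth0_radius(geom)) {
  (r_mm - r0_mm) * 1000 / geom$axial_pixel_pitch
}

depth_to_radius <- function(d, geom, r0_mm = depth0_radius(geom)) {
  r0_mm + d * geom$axial_pixel_pitch / 1000
}

# micrometres (physical, in tissue) per depth sample
um_per_sample <- function(geom) geom$axial_pixel_pitch / geom$refractive_index

# mm of physical tissue depth per depth sample
mm_per_sample <- function(geom) um_per_sample(geom) / 1000
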