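#' Layer description for the synthetic colon wall
#'
#' The murine colon wall is modelled, lumen to serosa, as four layers:
#' colonic mucosa, muscularis mucosa, submucosa and muscularis propria.
#' Each layer carries a physical thickness, a total attenuation coefficient
#' (the sum of scattering and absorption, which is all that a Beer-Lambert
#' intensity fit can recover), and a backscatter reflectivity that sets the
#' intensity level just below the layer's top interface.
#'
#' @param name Layer name; one of `"colonic_mucosa"`, `"muscularis_mucosa"`,
#'   `"submucosa"`, `"muscularis_propria"`.
#' @param thickness Layer thickness in micrometres (physical).
#' @param attenuation Total attenuation coefficient in 1/mm.
#' @param surface_reflectivity Dimensionless backscatter intensity at the
#'   layer's top interface (relative to the illumination).
#' @return A `LayerSpec` list.
#' @export
layer_spec <- function(name, thickness, attenuation, surface_reflectivity) {
  valid <- c("colonic_mucosa", "muscularis_mucosa", "submucosa",
             "muscularis_propria")
  name <- match.arg(name, valid)
  stopifnot(thickness > 0, attenuation >= 0, surface_reflectivity >= 0)
  structure(list(name = name, thickness = thickness,
                 attenuation = attenuation,
                 surface_reflectivity = surface_reflectivity),
            class = "LayerSpec")
}

default_layers <- function() {
  list(
    layer_spec("colonic_mucosa",     thickness = 200, attenuation = 2.5,
               surface_reflectivity = 0.25),
    layer_spec("muscularis_mucosa",  thickness = 30,  attenuation = 1.6,
               surface_reflectivity = 0.18),
    layer_spec("submucosa",          thickness = 50,  attenuation = 1.1,
               surface_reflectivity = 0.22),
    layer_spec("muscularis_propria", thickness = 100, attenuation = 2.0,
               surface_reflectivity = 0.15)
  )
}

#' Specification of a synthetic cylindrical colon phantom
#'
#' Describes a four-layer cylindrical colon wall wrapped around a
#' transparent probe sheath, with the noise and artifact structure a helical
#' endoscopic scan produces: multiplicative speckle, a detector noise floor,
#' sheath-detachment gaps where the wall lifts off the sheath, per-frame
#' motion jitter, and an angular crypt texture on the mucosal surface.
#'
#' Layer thicknesses default to murine-plausible values (mucosa 200 um,
#' muscularis mucosa 30 um, submucosa 50 um, muscularis propria 100 um);
#' they are configurable and all accuracy checks compare against the
#' generated ground truth rather than these defaults.
#'
#' @param layers Ordered list of [layer_spec()] objects, lumen to serosa.
#' @param lumen_radius Relaxed lumen radius in mm (>= sheath outer radius);
#'   detachment gaps displace the wall toward this radius.
#' @param sheath List with `inner_radius` (mm), `outer_radius` (mm) and
#'   `reflectivity` of the transparent sheath, rendered as two thin bright
#'   rings.
#' @param speckle_model List with `type` `"exponential"` (fully developed
#'   speckle: unit-mean multiplicative exponential intensity noise) or
#'   `"none"`.
#' @param noise_floor Additive background intensity level.
#' @param detachment List with `n_gaps`, `angular_width` (degrees) and
#'   `max_radial_offset` (um): angular spans where the wall detaches from
#'   the sheath.
#' @param motion_jitter List with `radial_sd_um` and `angular_sd_deg`:
#'   per-frame rigid displacement scales emulating tissue/probe motion.
#' @param crypt_modulation List with `amplitude` (relative reflectivity
#'   modulation) and `angular_period` (degrees): surface texture emulating
#'   colonic crypts.
#' @param surface_undulation RMS amplitude (depth samples) of the smooth
#'   angular undulation of the wall surface; 0 gives a perfectly circular
#'   (constant-radius) surface.
#' @param wall_modulation Relative amplitude of the smooth angular/pullback
#'   variation of wall thickness (biological non-uniformity).
#' @param interface_gain Multiplier for the single-sample specular spike
#'   rendered at each layer interface.
#' @param seed Integer seed; a fixed seed makes the rendered volume
#'   bit-reproducible.
#' @return A `PhantomSpec` list.
#' @export
phantom_spec <- function(layers = default_layers(),
                         lumen_radius = 1.15,
                         sheath = list(inner_radius = 0.95,
                                       outer_radius = 1.15,
                                       reflectivity = 0.5),
                         speckle_model = list(type = "exponential"),
                         noise_floor = 5e-4,
                         detachment = list(n_gaps = 1L,
                                           angular_width = 40,
                                           max_radial_offset = 120),
                         motion_jitter = list(radial_sd_um = 8,
                                              angular_sd_deg = 0.5),
                         crypt_modulation = list(amplitude = 0.3,
                                                 angular_period = 12),
                         surface_undulation = 2,
                         wall_modulation = 0.03,
                         interface_gain = 4,
                         seed = 1L) {
  if (!length(layers) || !all(vapply(layers, inherits, TRUE, "LayerSpec")))
    stop("'layers' must be a non-empty list of layer_spec() objects",
         call. = FALSE)
  if (!(sheath$inner_radius < sheath$outer_radius &&
        sheath$outer_radius <= lumen_radius))
    stop("radii must satisfy sheath inner < sheath outer <= lumen radius",
         call. = FALSE)
  if (!speckle_model$type %in% c("exponential", "none"))
    stop("speckle_model$type must be 'exponential' or 'none'", call. = FALSE)
  structure(list(layers = layers, lumen_radius = lumen_radius,
                 sheath = sheath, speckle_model = speckle_model,
                 noise_floor = noise_floor, detachment = detachment,
                 motion_jitter = motion_jitter,
                 crypt_modulation = crypt_modulation,
                 surface_undulation = surface_undulation,
                 wall_modulation = wall_modulation,
                 interface_gain = interface_gain,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

layer_field <- function(phantom, field) {
  vapply(phantom$layers, `[[`, numeric(1), field)
}

layer_names <- function(phantom) {
  vapply(phantom$layers, `[[`, character(1), "name")
}

#' Colitis effect schedule for synthetic studies
#'
#' Encodes the phenomenology of acute DSS colitis as per-day multipliers on
#' wall-layer thickness (swelling increases thickness) and attenuation
#' coefficient (inflammation decreases attenuation). The baseline day must
#' map to multipliers of exactly 1. Defaults place peak inflammation at
#' day 9 (thickness x1.5, attenuation x0.7) and near-complete recovery at
#' day 24.
#'
#' @param day_schedule Named list mapping day (as character) to
#'   `c(thickness = ..., attenuation = ...)` multipliers applied to
#'   challenged mice.
#' @return A `ColitisEffect` list.
#' @export
colitis_effect <- function(day_schedule = list(
                             "0"  = c(thickness = 1,    attenuation = 1),
                             "9"  = c(thickness = 1.5,  attenuation = 0.7),
                             "24" = c(thickness = 1.05, attenuation = 0.95))) {
  m <- do.call(rbind, day_schedule)
  if (any(m <= 0)) stop("effect multipliers must be > 0", call. = FALSE)
  if (!"0" %in% names(day_schedule) ||
      any(day_schedule[["0"]] != 1))
    stop("day 0 multipliers must equal 1 (baseline)", call. = FALSE)
  structure(list(day_schedule = day_schedule), class = "ColitisEffect")
}

effect_multipliers <- function(effect, day, group) {
  if (group != "challenged") return(c(thickness = 1, attenuation = 1))
  sched <- effect$day_schedule[[as.character(day)]]
  if (is.null(sched))
    stop("no effect multipliers scheduled for day ", day, call. = FALSE)
  sched
}

#' Simulate a single noise-free or speckled A-scan
#'
#' Renders one depth-resolved intensity profile through a stack of layers
#' following the round-trip Beer-Lambert model: within a layer of
#' attenuation coefficient `mu` starting at interface depth `z0`, the mean
#' backscattered intensity is `I(z) = I_L0 * exp(-2 * mu * (z - z0))`, where
#' `I_L0` is the layer reflectivity attenuated by the cumulative round-trip
#' decay of all layers above. Speckle is applied as unit-mean multiplicative
#' exponential noise and a constant noise floor is added.
#'
#' @param boundaries Sorted numeric vector of interface depths in samples
#'   (0-based, possibly fractional): the tissue surface followed by the
#'   bottom of each layer; length `n_layers + 1`.
#' @param layer_attns Attenuation coefficient per layer in 1/mm.
#' @param geom A [scan_geometry()] object (supplies the depth calibration).
#' @param reflectivity Backscatter reflectivity per layer.
#' @param speckle `"none"` or `"exponential"`.
#' @param noise_floor Additive background intensity.
#' @param interface_gain Specular spike multiplier at each interface (set 0
#'   to disable).
#' @return Numeric intensity profile of length `geom$n_depth_samples`
#'   (linear scale, >= 0).
#' @export
simulate_ascan <- function(boundaries, layer_attns, geom,
                           reflectivity = rep(0.2, length(layer_attns)),
                           speckle = c("none", "exponential"),
                           noise_floor = 0, interface_gain = 0) {
  speckle <- match.arg(speckle)
  nl <- length(layer_attns)
  if (length(boundaries) != nl + 1L)
    stop("need length(boundaries) == length(layer_attns) + 1", call. = FALSE)
  if (is.unsorted(boundaries, strictly = TRUE))
    stop("boundaries must be strictly increasing", call. = FALSE)
  if (any(layer_attns < 0)) stop("attenuations must be >= 0", call. = FALSE)
  nd <- geom$n_depth_samples
  d <- seq_len(nd) - 1
  prof <- numeric(nd)
  mmps <- mm_per_sample(geom)
  # cumulative round-trip attenuation above each layer (natural-log units)
  thick_mm <- diff(boundaries) * mmps
  cum <- c(0, cumsum(layer_attns * thick_mm))
  for (l in seq_len(nl)) {
    inside <- d >= boundaries[l] & d < boundaries[l + 1L]
    z_rel <- (d[inside] - boundaries[l]) * mmps
    prof[inside] <- reflectivity[l] *
      exp(-2 * (cum[l] + layer_attns[l] * z_rel))
    if (interface_gain > 0) {
      k <- round(boundaries[l])
      if (k >= 0 && k < nd)
        prof[k + 1L] <- prof[k + 1L] +
          interface_gain * reflectivity[l] * exp(-2 * cum[l])
    }
  }
  if (speckle == "exponential") prof <- prof * stats::rexp(nd)
  prof + noise_floor
}

# Smooth periodic field over A-line angle: sum of a few low-order Fourier
# modes with rng-drawn coefficients, normalised to unit RMS amplitude.
smooth_angular_field <- function(theta, n_modes = 3L) {
  f <- numeric(length(theta))
  for (k in seq_len(n_modes)) {
    f <- f + stats::rnorm(1) * sin(k * theta + stats::runif(1, 0, 2 * pi)) / k
  }
  s <- stats::sd(f)
  if (s > 0) f / s else f
}

# Continuous per-(bscan, a_line) boundary model for one phantom volume.
# Returns everything downstream rendering and ground truth need.
phantom_boundaries <- function(phantom, geom) {
  nb <- geom$n_bscans
  na <- geom$a_lines_per_bscan
  theta <- 2 * pi * (seq_len(na) - 1) / na
  pitch_opt <- geom$axial_pixel_pitch              # um per sample, in air
  n_idx <- geom$refractive_index

  base_top <- radius_to_depth(phantom$sheath$outer_radius, geom) + 16

  # smooth angular undulation of the surface (px), slow drift along pullback
  su <- phantom$surface_undulation
  ang <- smooth_angular_field(theta) * su
  drift <- if (nb > 1 && su > 0)
    0.75 * su * sin(2 * pi * (seq_len(nb) - 1) / nb + stats::runif(1, 0, 2 * pi))
  else rep(0, nb)

  # detachment gaps: smooth raised-cosine bumps pushing the wall outward
  gap_bump <- numeric(na)
  detached <- rep(FALSE, na)
  det <- phantom$detachment
  if (det$n_gaps > 0) {
    centers <- stats::runif(det$n_gaps, 0, 2 * pi)
    hw <- det$angular_width * pi / 180 / 2
    off_px <- det$max_radial_offset / pitch_opt    # radial offset, air path
    for (cth in centers) {
      dth <- abs(((theta - cth + pi) %% (2 * pi)) - pi)
      inb <- dth < hw
      gap_bump[inb] <- pmax(gap_bump[inb],
                            off_px * 0.5 * (1 + cos(pi * dth[inb] / hw)))
      detached <- detached | inb
    }
  }

  # per-frame rigid motion jitter
  jit_r <- stats::rnorm(nb, 0, phantom$motion_jitter$radial_sd_um / pitch_opt)
  jit_a <- stats::rnorm(nb, 0, phantom$motion_jitter$angular_sd_deg / 360 * na)

  # smooth multiplicative non-uniformity of total wall thickness
  wm <- phantom$wall_modulation
  thick_mod_ang <- if (wm > 0) 1 + wm * smooth_angular_field(theta) else rep(1, na)
  thick_mod_pb <- if (wm > 0 && nb > 1)
    1 + wm * sin(2 * pi * (seq_len(nb) - 1) / nb + stats::runif(1, 0, 2 * pi))
  else rep(1, nb)

  # crypt texture: angular reflectivity modulation of the mucosa, with a
  # slowly drifting phase along the pullback
  cm <- phantom$crypt_modulation
  crypt_phase <- if (nb > 1)
    2 * pi * (seq_len(nb) - 1) / nb * 2 + stats::runif(1, 0, 2 * pi)
  else stats::runif(1, 0, 2 * pi)
  pattern <- outer(crypt_phase, theta, function(ph, th)
    sin(th * (360 / cm$angular_period) + ph))

  # layer thicknesses in samples (optical): um * n / pitch
  t_px <- layer_field(phantom, "thickness") * n_idx / pitch_opt

  top <- outer(drift + jit_r, ang, `+`) + base_top +
    matrix(gap_bump, nb, na, byrow = TRUE)
  detached_mat <- matrix(detached, nb, na, byrow = TRUE)
  # angular jitter: roll the angular profile per frame (nearest A-line)
  if (any(jit_a != 0)) {
    for (b in seq_len(nb)) {
      sh <- round(jit_a[b]) %% na
      if (sh != 0) {
        ord <- c((sh + 1):na, 1:sh)
        top[b, ] <- top[b, ord]
        pattern[b, ] <- pattern[b, ord]
        detached_mat[b, ] <- detached_mat[b, ord]
      }
    }
  }

  tmod <- outer(thick_mod_pb, thick_mod_ang)      # [bscan, a_line]
  list(top = top, t_px = t_px, tmod = tmod, pattern = pattern,
       detached = detached_mat, theta = theta)
}

#' Simulate a helical-scan OCT volume of the colon phantom
#'
#' Renders `n_bscans` frames of `a_lines_per_bscan` A-scans each, following
#' the round-trip Beer-Lambert model per layer with the phantom's speckle,
#' sheath rings, detachment gaps, motion jitter and crypt texture, and
#' returns the volume together with exact ground truth (boundaries, wall
#' mask, thickness map, per-layer attenuations).
#'
#' With `render = "truth"` only the ground truth is computed (no intensity
#' rendering); this is the fast path for study-level statistical
#' simulations where boundary geometry, not image formation, is being
#' exercised.
#'
#' @param phantom A [phantom_spec()].
#' @param geom A [scan_geometry()]; its sheath radii must match the
#'   phantom's.
#' @param render `"volume"` (full intensity rendering) or `"truth"`.
#' @param thickness_scale,attenuation_scale Global multipliers applied to
#'   all layer thicknesses / attenuations (used by [simulate_study()] to
#'   impose colitis effects and session variability).
#' @return A list with elements `volume` (an [oct_volume()], or `NULL` for
#'   `render = "truth"`) and `truth` (a `GroundTruth` list with `top`,
#'   `bottom`, `layer_bounds`, `wall_mask`, `thickness_um`,
#'   `layer_attenuation`, `pattern`, `detached`).
#' @export
simulate_volume <- function(phantom, geom, render = c("volume", "truth"),
                            thickness_scale = 1, attenuation_scale = 1) {
  render <- match.arg(render)
  stopifnot(inherits(phantom, "PhantomSpec"), inherits(geom, "ScanGeometry"))
  if (abs(phantom$sheath$inner_radius - geom$sheath_inner_radius) > 1e-9 ||
      abs(phantom$sheath$outer_radius - geom$sheath_outer_radius) > 1e-9)
    stop("phantom sheath radii do not match scan geometry", call. = FALSE)

  with_seed(phantom$seed, {
    bd <- phantom_boundaries(phantom, geom)
    nb <- geom$n_bscans
    na <- geom$a_lines_per_bscan
    nd <- geom$n_depth_samples
    nl <- length(phantom$layers)

    t_px <- bd$t_px * thickness_scale
    mus <- layer_field(phantom, "attenuation") * attenuation_scale
    refl <- layer_field(phantom, "surface_reflectivity")

    # continuous interface depths: starts[[l]] is [bscan, a_line]
    starts <- vector("list", nl + 1L)
    starts[[1L]] <- bd$top
    for (l in seq_len(nl)) starts[[l + 1L]] <- starts[[l]] + t_px[l] * bd$tmod
    bottom <- starts[[nl + 1L]]
    if (max(bottom) >= nd)
      stop("phantom wall extends beyond n_depth_samples (deepest boundary ",
           sprintf("%.1f", max(bottom)), " >= ", nd,
           "); increase n_depth_samples or reduce wall thickness",
           call. = FALSE)

    mmps <- mm_per_sample(geom)
    top_i <- round(bd$top)
    bottom_i <- round(bottom)
    thickness_um <- (bottom - bd$top) * um_per_sample(geom)

    truth <- structure(list(
      top = top_i, bottom = bottom_i,
      layer_bounds = lapply(starts, round),
      top_continuous = bd$top, bottom_continuous = bottom,
      wall_mask = NULL,
      thickness_um = thickness_um,
      layer_attenuation = stats::setNames(mus, layer_names(phantom)),
      pattern = bd$pattern, detached = bd$detached,
      geom = geom), class = "GroundTruth")

    if (render == "truth") return(list(volume = NULL, truth = truth))

    ring_in <- depth0_margin_px
    ring_out <- round(radius_to_depth(phantom$sheath$outer_radius, geom))
    cm_amp <- phantom$crypt_modulation$amplitude
    speckled <- phantom$speckle_model$type == "exponential"

    data <- array(0, dim = c(nb, na, nd))
    didx <- matrix(rep(seq_len(nd) - 1, each = na), na, nd)   # depth index
    mask <- array(FALSE, dim = c(nb, na, nd))
    for (b in seq_len(nb)) {
      img <- matrix(0, na, nd)
      cum <- rep(0, na)
      for (l in seq_len(nl)) {
        s <- starts[[l]][b, ]                    # per a-line start (samples)
        tpx <- starts[[l + 1L]][b, ] - s
        r_l <- rep(refl[l], na)
        if (l == 1L) r_l <- r_l * (1 + cm_amp * bd$pattern[b, ])
        inside <- didx >= s & didx < (s + tpx)
        zrel <- (didx - s) * mmps
        contrib <- (r_l * exp(-2 * cum)) * exp(-2 * mus[l] * zrel)
        img[inside] <- contrib[inside]
        # single-sample specular spike at the interface
        if (phantom$interface_gain > 0) {
          k <- round(s)
          ok <- k >= 0 & k < nd
          idx <- cbind(seq_len(na)[ok], k[ok] + 1L)
          img[idx] <- img[idx] +
            phantom$interface_gain * r_l[ok] * exp(-2 * cum[ok])
        }
        cum <- cum + mus[l] * tpx * mmps
      }
      # sheath: two thin bright rings at fixed depth
      for (rr in c(ring_in, ring_out))
        if (rr >= 0 && rr < nd)
          img[, rr + 1L] <- img[, rr + 1L] + phantom$sheath$reflectivity
      if (speckled) {
        img <- img * matrix(stats::rexp(na * nd), na, nd)
        img <- img + phantom$noise_floor *
          matrix(stats::rexp(na * nd), na, nd)
      } else {
        img <- img + phantom$noise_floor
      }
      data[b, , ] <- img
      mask[b, , ] <- didx >= top_i[b, ] & didx < bottom_i[b, ]
    }
    truth$wall_mask <- mask
    list(volume = oct_volume(data, geom), truth = truth)
  })
}

#' Design of a longitudinal two-group imaging study
#'
#' @param groups Group labels; the first is the DSS-challenged group, the
#'   second the unchallenged control group.
#' @param days Imaging days; must include the baseline day 0.
#' @param n_per_group Mice per group.
#' @param seed Integer base seed for the study.
#' @return A `StudyDesign` list.
#' @export
study_design <- function(groups = c("challenged", "unchallenged"),
                         days = c(0, 9, 24), n_per_group = 3L, seed = 1L) {
  stopifnot(length(groups) >= 1, n_per_group >= 1)
  if (!0 %in% days) stop("days must include the baseline day 0", call. = FALSE)
  structure(list(groups = groups, days = days,
                 n_per_group = as.integer(n_per_group),
                 seed = as.integer(seed)),
            class = "StudyDesign")
}

#' Simulate a longitudinal colitis imaging study
#'
#' Generates one phantom volume (or ground truth only) per mouse per
#' imaging day. Challenged mice have their layer thicknesses and
#' attenuation coefficients scaled by the [colitis_effect()] schedule;
#' every mouse-day additionally receives independent lognormal session
#' multipliers emulating the combined animal and probe-repositioning
#' variability between imaging sessions.
#'
#' Random streams are keyed per (mouse, day) from the design seed, so
#' adding a mouse or a day never perturbs the draws of existing ones.
#'
#' @param design A [study_design()].
#' @param phantom A [phantom_spec()] describing the baseline (day-0) colon.
#' @param effect A [colitis_effect()].
#' @param geom A [scan_geometry()].
#' @param render `"volume"` or `"truth"` (see [simulate_volume()]).
#' @param session_sd Lognormal sdlog of the per-(mouse, day) session
#'   multipliers applied to thickness and attenuation.
#' @return A list with one element per mouse-day: a list with `mouse`,
#'   `group`, `day`, `volume`, `truth` and the applied `multipliers`.
#' @export
simulate_study <- function(design, phantom = phantom_spec(),
                           effect = colitis_effect(),
                           geom, render = c("volume", "truth"),
                           session_sd = 0.05) {
  render <- match.arg(render)
  stopifnot(inherits(design, "StudyDesign"))
  out <- list()
  for (gi in seq_along(design$groups)) {
    grp <- design$groups[gi]
    for (mi in seq_len(design$n_per_group)) {
      uid <- gi * 1000L + mi
      mouse <- sprintf("%s_%d", substr(grp, 1, 4), mi)
      for (day in design$days) {
        md_seed <- (design$seed + 7919 * uid + day) %% .Machine$integer.max
        eff <- effect_multipliers(effect, day, grp)
        sess <- with_seed(md_seed, stats::rlnorm(2, 0, session_sd))
        ph <- phantom
        ph$seed <- as.integer((md_seed + 1) %% .Machine$integer.max)
        sim <- simulate_volume(
          ph, geom, render = render,
          thickness_scale = eff[["thickness"]] * sess[1],
          attenuation_scale = eff[["attenuation"]] * sess[2])
        out[[length(out) + 1L]] <- list(
          mouse = mouse, group = grp, day = day,
          volume = sim$volume, truth = sim$truth,
          multipliers = c(thickness = unname(eff[["thickness"]] * sess[1]),
                          attenuation = unname(eff[["attenuation"]] * sess[2])))
      }
    }
  }
  out
}
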