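#' Per-A-line wall thickness map
#'
#' Converts per-A-line boundary indices to physical thickness:
#' `(bottom - top) * axial_pixel_pitch / refractive_index` micrometres.
#' A-lines without a detected wall yield `NA` and are excluded from all
#' downstream summaries.
#'
#' @param wm A `WallMask` (from [segment_volume()]) or `GroundTruth` with
#'   `top`/`bottom` matrices and a geometry.
#' @param geom A [scan_geometry()]; defaults to the one stored in `wm`.
#' @return Numeric matrix `[bscan, a_line]` of thickness in micrometres.
#' @export
thickness_map <- function(wm, geom = wm$geom) {
  stopifnot(!is.null(wm$top), !is.null(wm$bottom))
  (wm$bottom - wm$top) * um_per_sample(geom)
}

#' Thickness profile at sampled pullback locations
#'
#' Divides the pullback axis into `n_locations` equal bins and reports the
#' median of the available per-A-line thicknesses in each bin, emulating
#' thickness measurement at a fixed number of locations along the colon.
#'
#' @param tmap Thickness matrix `[bscan, a_line]` from [thickness_map()].
#' @param geom A [scan_geometry()].
#' @param n_locations Number of pullback bins (default 10).
#' @return A data.frame with `location`, `position_mm` (bin centre) and
#'   `thickness_um` (`NA`, with a warning, for bins without data).
#' @export
sample_thickness <- function(tmap, geom, n_locations = 10L) {
  stopifnot(n_locations >= 1)
  nb <- nrow(tmap)
  bins <- cut(seq_len(nb) - 0.5, breaks = seq(0, nb, length.out = n_locations + 1),
              labels = FALSE, include.lowest = TRUE)
  centers <- (seq_len(n_locations) - 0.5) / n_locations * geom$pullback_length
  th <- vapply(seq_len(n_locations), function(i) {
    v <- tmap[bins == i, , drop = FALSE]
    stats::median(v, na.rm = TRUE)
  }, numeric(1))
  if (anyNA(th))
    warning("thickness profile: ", sum(is.na(th)),
            " bin(s) contain no measurable A-lines")
  data.frame(location = seq_len(n_locations), position_mm = centers,
             thickness_um = th)
}

#' Fit the Beer-Lambert attenuation coefficient of one A-scan window
#'
#' The round-trip Beer-Lambert model `I(z) = I0 * exp(-2 * muA * z)` is
#' linear in log-intensity, so the total attenuation coefficient is
#' recovered as `-slope / 2` of an ordinary least-squares fit of `ln(I)`
#' on physical depth `z` over the window `[start, end)`. Intensities are
#' clipped to the noise floor before the log. On noiseless exponential
#' data the fit is exact; on speckled data, A-scans should be averaged in
#' linear intensity before fitting (see [layer_attenuation()]).
#'
#' @param ascan Numeric intensity profile (linear scale).
#' @param start,end Window in depth samples (0-based, half-open);
#'   `end - start >= 4`.
#' @param geom A [scan_geometry()] (depth calibration).
#' @param noise_floor Clipping floor applied before the log.
#' @return An `AttenuationResult` list: `mu_A` (1/mm), `fit_intercept`
#'   (log-intensity), `r_squared`, `window`, `n_alines_averaged`.
#' @export
fit_attenuation <- function(ascan, start, end, geom, noise_floor = 1e-12) {
  stopifnot(inherits(geom, "ScanGeometry"))
  if (end - start < 4)
    stop("attenuation window must span at least 4 samples", call. = FALSE)
  idx <- (start:(end - 1)) + 1L
  if (max(idx) > length(ascan))
    stop("window exceeds A-scan length", call. = FALSE)
  y <- suppressWarnings(log(pmax(ascan[idx], noise_floor)))
  if (!all(is.finite(y)))
    stop("attenuation window contains non-finite log-intensities",
         call. = FALSE)
  z_mm <- depth_to_physical(start:(end - 1), geom) / 1000
  fit <- stats::lm(y ~ z_mm)
  sl <- unname(stats::coef(fit)[2])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(mu_A = -sl / 2,
                 fit_intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 window = c(start = start, end = end),
                 n_alines_averaged = 1L),
            class = "AttenuationResult")
}

#' Choose a usable fit window end from an averaged A-scan
#'
#' Returns the last depth sample (exclusive) at which the averaged profile
#' still exceeds `snr_factor` times the noise floor, so that fits stop
#' before the signal drowns in the background.
#'
#' @param profile Averaged linear-intensity A-scan.
#' @param start First sample of the candidate window (0-based).
#' @param noise_floor Background intensity level.
#' @param snr_factor Required signal-to-floor ratio.
#' @return 0-based exclusive window end (>= `start`).
#' @export
usable_window_end <- function(profile, start, noise_floor, snr_factor = 20) {
  above <- profile > snr_factor * noise_floor
  n <- length(profile)
  e <- start
  while (e < n && above[e + 1L]) e <- e + 1L
  e
}

#' Per-layer attenuation coefficients from a flattened volume
#'
#' For each pullback bin (the same equal bins as the thickness profile)
#' and each layer: averages the A-scans of the bin in linear intensity
#' (reducing speckle before the log), skips `guard` samples below the
#' layer's top interface (specular-peak guard) and `trailing_guard`
#' samples above its far interface, and fits the Beer-Lambert slope with
#' [fit_attenuation()]. Layer windows come from configuration or ground
#' truth, not image-derived sub-segmentation.
#'
#' Each entry of `layer_offsets` is either a constant window
#' `c(start, end)` in samples below the flattened surface, or a list
#' `list(start = M0, end = M1)` of per-`[bscan, a_line]` offset matrices
#' (e.g. derived from generator ground truth). With matrices, every A-scan
#' is re-aligned on its own layer-top interface before averaging, which
#' keeps the average strictly exponential even when the layer boundaries
#' undulate; with constant windows, interface undulation smears the
#' averaged interfaces and generous guards are advisable.
#'
#' @param flat A `FlattenedVolume` (see [flatten_volume()]).
#' @param layer_offsets Named list, one entry per layer (see Details).
#' @param geom A [scan_geometry()].
#' @param n_bins Number of pullback bins.
#' @param guard Samples excluded below each layer's top interface.
#' @param trailing_guard Samples excluded above the far interface;
#'   defaults to `guard`.
#' @param min_frac Minimum fraction of valid A-lines a bin must have;
#'   sparser bins are reported as missing.
#' @param noise_floor Clipping floor for the log.
#' @return A data.frame with `location`, `position_mm`, `layer`, `mu_A`,
#'   `r_squared`, `n_alines`; missing bins/layers have `NA` `mu_A`.
#' @export
layer_attenuation <- function(flat, layer_offsets, geom = flat$geom,
                              n_bins = 10L, guard = 3L,
                              trailing_guard = guard, min_frac = 0.25,
                              noise_floor = 1e-6) {
  stopifnot(inherits(flat, "FlattenedVolume"))
  nb <- dim(flat$data)[1]
  na <- dim(flat$data)[2]
  bins <- cut(seq_len(nb) - 0.5, breaks = seq(0, nb, length.out = n_bins + 1),
              labels = FALSE, include.lowest = TRUE)
  centers <- (seq_len(n_bins) - 0.5) / n_bins * geom$pullback_length
  rows <- list()
  for (i in seq_len(n_bins)) {
    bsel <- which(bins == i)
    hsub <- flat$height[bsel, , drop = FALSE]
    valid <- !is.na(hsub)
    frac <- if (length(valid)) mean(valid) else 0
    for (ln in names(layer_offsets)) {
      win <- layer_offsets[[ln]]
      res <- list(location = i, position_mm = centers[i], layer = ln,
                  mu_A = NA_real_, r_squared = NA_real_,
                  n_alines = sum(valid))
      if (is.list(win)) {
        s_mat <- win$start[bsel, , drop = FALSE]
        e_mat <- win$end[bsel, , drop = FALSE]
        w_len <- floor(min(e_mat - s_mat, na.rm = TRUE)) - guard -
          trailing_guard
        s0 <- guard
      } else {
        s_mat <- NULL
        s0 <- win[1] + guard
        w_len <- (win[2] - trailing_guard) - s0
      }
      if (frac < min_frac) {
        warning("bin ", i, ": only ", round(100 * frac),
                "% valid A-lines; reported missing")
      } else if (w_len < 4) {
        warning("bin ", i, " layer ", ln,
                ": usable window shorter than 4 samples; skipped")
      } else if (is.null(s_mat) && s0 + w_len > flat$crop_depth) {
        warning("bin ", i, " layer ", ln, ": window beyond crop; skipped")
      } else {
        ok <- as.vector(valid)
        bi <- rep(bsel, na)[ok]
        ai <- rep(seq_len(na), each = length(bsel))[ok]
        if (is.null(s_mat)) {
          starts <- rep.int(s0, length(bi))
        } else {
          starts <- pmax(round(as.vector(s_mat))[ok] + guard, 0L)
          keep <- starts + w_len <= flat$crop_depth
          bi <- bi[keep]; ai <- ai[keep]; starts <- starts[keep]
        }
        if (length(bi) < 1) {
          warning("bin ", i, " layer ", ln, ": no usable A-lines; skipped")
        } else {
          prof <- vapply(seq_len(w_len), function(j)
            mean(flat$data[cbind(bi, ai, starts + j)]), numeric(1))
          fit <- fit_attenuation(prof, 0L, w_len, geom, noise_floor)
          res$mu_A <- fit$mu_A
          res$r_squared <- fit$r_squared
        }
      }
      rows[[length(rows) + 1L]] <- res
    }
  }
  do.call(rbind.data.frame, rows)
}

#' Per-layer offset matrices from generator ground truth
#'
#' Converts the absolute layer boundaries of a `GroundTruth` into
#' flattened-surface-relative start/end matrices suitable for
#' [layer_attenuation()].
#'
#' @param truth A `GroundTruth` from [simulate_volume()].
#' @param top Reference surface the offsets are relative to; defaults to
#'   the ground-truth top, but pass the segmented top when the volume was
#'   flattened on segmentation output.
#' @return Named list, one `list(start, end)` matrix pair per layer.
#' @export
truth_layer_offsets <- function(truth, top = truth$top) {
  nl <- length(truth$layer_attenuation)
  out <- lapply(seq_len(nl), function(l)
    list(start = truth$layer_bounds[[l]] - top,
         end = truth$layer_bounds[[l + 1L]] - top))
  stats::setNames(out, names(truth$layer_attenuation))
}

#' Layer windows (flattened depth samples) from layer thicknesses
#'
#' Converts per-layer physical thicknesses to half-open depth-sample
#' windows below the flattened surface, in the order given.
#'
#' @param thickness_um Named numeric vector of layer thicknesses, lumen to
#'   serosa.
#' @param geom A [scan_geometry()].
#' @return Named list of `c(start, end)` 0-based sample windows.
#' @export
layer_windows <- function(thickness_um, geom) {
  t_px <- thickness_um / um_per_sample(geom)
  edges <- round(cumsum(c(0, t_px)))
  out <- lapply(seq_along(thickness_um), function(i) c(edges[i], edges[i + 1]))
  stats::setNames(out, names(thickness_um))
}

#' Normalise longitudinal measurements to each mouse's baseline
#'
#' Expresses every value as a percent change from the mouse's own mean at
#' the baseline day: `100 * (value - baseline_mean) / baseline_mean`. Mice
#' without a baseline measurement are excluded with a warning.
#'
#' @param df Data.frame with at least `mouse`, `day` and the value column.
#' @param value_col Name of the value column.
#' @param baseline_day Baseline day identifier (default 0).
#' @return `df` with an added `pct_change` column, baseline-less mice
#'   dropped.
#' @export
normalize_to_baseline <- function(df, value_col, baseline_day = 0) {
  stopifnot(all(c("mouse", "day", value_col) %in% names(df)))
  base <- df[df$day == baseline_day, ]
  bm <- tapply(base[[value_col]], base$mouse, mean, na.rm = TRUE)
  missing <- setdiff(unique(df$mouse), names(bm)[!is.na(bm)])
  if (length(missing)) {
    warning("no baseline for mouse/mice ", paste(missing, collapse = ", "),
            "; excluded")
    df <- df[!df$mouse %in% missing, ]
  }
  df$pct_change <- as.vector(100 * (df[[value_col]] - bm[df$mouse]) /
                               bm[df$mouse])
  df
}

#' Quantify one simulated study into a long-format table
#'
#' For each mouse-day of a [simulate_study()] result, measures the
#' 10-location thickness profile and (optionally) per-layer attenuation
#' coefficients, producing the long table the study-level ANOVA consumes.
#'
#' With `boundaries = "truth"` the generator's ground-truth boundaries and
#' attenuations are used directly (fast path exercising study-level
#' statistics, not image formation); with `"segment"` each volume is
#' segmented, flattened and fitted.
#'
#' @param study Result of [simulate_study()].
#' @param geom A [scan_geometry()].
#' @param n_locations Pullback bins per mouse-day.
#' @param boundaries `"truth"` or `"segment"`.
#' @param measures Character subset of `c("thickness", "attenuation")`.
#' @param params [seg_params()] used when `boundaries = "segment"`.
#' @return Data.frame with columns `mouse`, `group`, `day`, `location`,
#'   `position_mm`, `layer`, `thickness_um`, `mu_A` (layer `"wall"` rows
#'   carry the thickness; per-layer rows carry attenuation).
#' @export
quantify_study <- function(study, geom, n_locations = 10L,
                           boundaries = c("truth", "segment"),
                           measures = c("thickness", "attenuation"),
                           params = seg_params()) {
  boundaries <- match.arg(boundaries)
  measures <- match.arg(measures, c("thickness", "attenuation"),
                        several.ok = TRUE)
  out <- list()
  for (md in study) {
    truth <- md$truth
    wm <- if (boundaries == "truth") truth else segment_volume(md$volume, params)
    base <- data.frame(mouse = md$mouse, group = md$group, day = md$day)
    if ("thickness" %in% measures) {
      tp <- sample_thickness(thickness_map(wm, geom), geom, n_locations)
      out[[length(out) + 1L]] <- cbind(base, tp, layer = "wall",
                                       mu_A = NA_real_)
    }
    if ("attenuation" %in% measures) {
      lt <- truth$layer_attenuation
      if (boundaries == "truth" && is.null(md$volume)) {
        # no rendered intensities: report the generated per-layer truths
        att <- data.frame(location = rep(seq_len(n_locations), each = length(lt)),
                          position_mm = rep((seq_len(n_locations) - 0.5) /
                                              n_locations * geom$pullback_length,
                                            each = length(lt)),
                          layer = rep(names(lt), n_locations),
                          mu_A = rep(unname(lt), n_locations))
      } else {
        flat <- flatten_volume(md$volume, wm)
        la <- layer_attenuation(flat, truth_layer_offsets(truth, wm$top),
                                geom, n_bins = n_locations)
        att <- la[, c("location", "position_mm", "layer", "mu_A")]
      }
      att$thickness_um <- NA_real_
      out[[length(out) + 1L]] <- cbind(base[rep(1, nrow(att)), ], att)
    }
  }
  res <- do.call(rbind, lapply(out, function(d)
    d[, c("mouse", "group", "day", "location", "position_mm", "layer",
          "thickness_um", "mu_A")]))
  rownames(res) <- NULL
  res
}

# per-layer mean physical thickness (um) of one mouse-day, from ground truth
layer_truth_thickness <- function(md) {
  truth <- md$truth
  g <- truth$geom
  nl <- length(truth$layer_attenuation)
  th <- vapply(seq_len(nl), function(l)
    mean(truth$layer_bounds[[l + 1L]] - truth$layer_bounds[[l]]) *
      um_per_sample(g), numeric(1))
  stats::setNames(th, names(truth$layer_attenuation))
}
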