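#' Write / read an OCT volume as multi-page TIFF
#'
#' One 32-bit float page per B-scan (`[a_line, depth]`). Float TIFF
#' storage is defined on `[0, 1]`, so intensities are divided by a scale
#' factor on write; the factor, the intensity scale and the acquisition
#' geometry are recorded in a YAML sidecar (`<path>.yaml`) and restored on
#' read, making the round trip lossless to 32-bit float precision.
#'
#' @param vol An [oct_volume()].
#' @param path Output TIFF path; the sidecar is written next to it.
#' @rdname volume_io
#' @return `write_volume` returns `path` invisibly; `read_volume` returns
#'   an [oct_volume()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "OCTVolume"))
  mx <- max(vol$data, 1e-300)
  pages <- lapply(seq_len(dim(vol$data)[1]),
                  function(b) vol$data[b, , ] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(c(unclass(vol$geom),
                     list(intensity_scale = mx, scale = vol$scale)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @param geom Optional [scan_geometry()] to validate the file against; by
#'   default the sidecar geometry is used.
#' @rdname volume_io
#' @export
read_volume <- function(path, geom = NULL) {
  side <- paste0(path, ".yaml")
  if (!file.exists(side))
    stop("missing geometry sidecar '", side, "'", call. = FALSE)
  cfg <- yaml::read_yaml(side)
  scale_factor <- cfg$intensity_scale %||% 1
  scale <- cfg$scale %||% "linear"
  cfg$intensity_scale <- NULL
  cfg$scale <- NULL
  file_geom <- do.call(scan_geometry, cfg)
  if (!is.null(geom)) {
    for (f in c("a_lines_per_bscan", "n_depth_samples", "n_bscans"))
      if (geom[[f]] != file_geom[[f]])
        stop("geometry mismatch for '", f, "': supplied ", geom[[f]],
             ", file has ", file_geom[[f]], call. = FALSE)
    file_geom <- geom
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent TIFF page shapes in '", path, "'", call. = FALSE)
  if (dims[1, 1] != file_geom$a_lines_per_bscan ||
      dims[2, 1] != file_geom$n_depth_samples ||
      length(pages) != file_geom$n_bscans)
    stop("TIFF shape ", length(pages), "x", dims[1, 1], "x", dims[2, 1],
         " does not match geometry ", file_geom$n_bscans, "x",
         file_geom$a_lines_per_bscan, "x", file_geom$n_depth_samples,
         call. = FALSE)
  data <- array(0, dim = c(length(pages), dims[1, 1], dims[2, 1]))
  for (b in seq_along(pages)) data[b, , ] <- pages[[b]] * scale_factor
  oct_volume(data, file_geom, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write wall boundaries as CSV
#'
#' Long format: one row per (bscan, a_line) with 0-based `top` and
#' `bottom` depth indices (`NA` where no wall was found).
#'
#' @param wm A `WallMask`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(wm, path) {
  nb <- nrow(wm$top); na <- ncol(wm$top)
  df <- data.frame(bscan = rep(seq_len(nb) - 1L, na),
                   a_line = rep(seq_len(na) - 1L, each = nb),
                   top = as.vector(wm$top), bottom = as.vector(wm$bottom))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic-study pipeline
#'
#' End-to-end driver: simulate a longitudinal colitis study, quantify
#' thickness and per-layer attenuation per mouse-day, run the group x day
#' ANOVA, and write `quant.csv`, `anova_thickness.csv`, `summary.csv` and
#' a `manifest.json` recording the package version, seed and parameters.
#' Identical config and seed reproduce identical outputs.
#'
#' @param out_dir Output directory (created if missing).
#' @param design A [study_design()].
#' @param phantom A [phantom_spec()].
#' @param effect A [colitis_effect()].
#' @param geom A [scan_geometry()].
#' @param boundaries `"segment"` (image pipeline) or `"truth"` (generator
#'   boundaries; fast statistical path).
#' @param n_locations Pullback bins.
#' @param params [seg_params()] for the segmentation path.
#' @return Invisibly, a list with `quant`, `anova`, `summary` and the
#'   output paths.
#' @export
run_pipeline <- function(out_dir, design = study_design(),
                         phantom = phantom_spec(),
                         effect = colitis_effect(), geom,
                         boundaries = c("segment", "truth"),
                         n_locations = 10L, params = seg_params()) {
  boundaries <- match.arg(boundaries)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  render <- if (boundaries == "segment") "volume" else "truth"
  study <- simulate_study(design, phantom, effect, geom, render = render)
  quant <- quantify_study(study, geom, n_locations, boundaries = boundaries,
                          params = params)
  quant_path <- file.path(out_dir, "quant.csv")
  utils::write.csv(quant, quant_path, row.names = FALSE)

  av <- two_way_anova(quant, response = "thickness_um", layer = "wall")
  anova_path <- file.path(out_dir, "anova_thickness.csv")
  utils::write.csv(av, anova_path, row.names = FALSE)

  thick_sum <- summarize_quant(quant[quant$layer == "wall", ], "thickness_um")
  att <- quant[quant$layer != "wall" & !is.na(quant$mu_A), ]
  summary_df <- thick_sum
  if (nrow(att)) {
    att_sum <- summarize_quant(att, "mu_A")
    thick_sum$response <- "thickness_um"
    att_sum$response <- "mu_A"
    summary_df <- rbind(thick_sum, att_sum)
  }
  summary_path <- file.path(out_dir, "summary.csv")
  utils::write.csv(summary_df, summary_path, row.names = FALSE)

  manifest <- list(
    package = "endoct",
    version = as.character(utils::packageVersion("endoct")),
    seed = design$seed,
    design = unclass(design),
    geometry = unclass(geom),
    boundaries = boundaries,
    n_locations = n_locations,
    effect = lapply(effect$day_schedule, as.list))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(quant = quant, anova = av, summary = summary_df,
                 paths = c(quant = quant_path, anova = anova_path,
                           summary = summary_path)))
}
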