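#' Container for an ordered stack of B-scans
#'
#' Stores the OCT volume as a 3-D numeric array indexed
#' `[bscan, a_line, depth]` together with its acquisition geometry and the
#' intensity scale (`"linear"` detected intensity or `"dB"` after
#' [log_compress()]).
#'
#' @param data 3-D numeric array `[bscan, a_line, depth]`.
#' @param geom A [scan_geometry()]; array dimensions must match its counts.
#' @param scale `"linear"` or `"dB"`.
#' @return An `OCTVolume` list.
#' @export
oct_volume <- function(data, geom, scale = c("linear", "dB")) {
  scale <- match.arg(scale)
  stopifnot(inherits(geom, "ScanGeometry"))
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3-D array [bscan, a_line, depth]",
         call. = FALSE)
  expected <- c(geom$n_bscans, geom$a_lines_per_bscan, geom$n_depth_samples)
  if (!all(dim(data) == expected))
    stop("volume shape ", paste(dim(data), collapse = "x"),
         " does not match geometry ", paste(expected, collapse = "x"),
         call. = FALSE)
  if (scale == "linear" && min(data) < 0)
    stop("linear intensities must be >= 0", call. = FALSE)
  structure(list(data = data, geom = geom, scale = scale),
            class = "OCTVolume")
}

#' @export
print.OCTVolume <- function(x, ...) {
  cat(sprintf("OCTVolume: %d B-scans x %d A-lines x %d depth samples (%s)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$scale))
  invisible(x)
}

#' Frame a raw helical A-scan stream into B-scans
#'
#' The acquisition emits one flat stream of A-scans (depth-fastest order);
#' the number of A-scans per B-scan is fixed by the rotation
#' synchronisation, so framing is a reshape. Any trailing partial frame is
#' discarded and the number of discarded A-lines is reported via
#' [message()].
#'
#' @param stream Numeric vector: concatenated A-scans, each of
#'   `n_depth_samples` samples, `a_lines_per_bscan` A-scans per frame.
#' @param geom A [scan_geometry()]; `n_bscans` is overridden by the number
#'   of complete frames present in the stream.
#' @return An [oct_volume()] in linear scale.
#' @export
frame_bscans <- function(stream, geom) {
  stopifnot(inherits(geom, "ScanGeometry"))
  nd <- geom$n_depth_samples
  na <- geom$a_lines_per_bscan
  frame_len <- nd * na
  n_frames <- length(stream) %/% frame_len
  if (n_frames < 1L)
    stop("stream shorter than one B-scan (", length(stream), " < ",
         frame_len, " samples)", call. = FALSE)
  used <- n_frames * frame_len
  discarded_alines <- (length(stream) - used) %/% nd
  if (length(stream) > used)
    message("frame_bscans: discarded ", discarded_alines,
            " trailing A-line(s) (partial frame)")
  arr <- array(stream[seq_len(used)], dim = c(nd, na, n_frames))
  g <- geom
  g$n_bscans <- n_frames
  oct_volume(aperm(arr, c(3, 2, 1)), g)
}

#' Flatten an OCT volume back to a raw A-scan stream
#'
#' Inverse of [frame_bscans()] for exact-multiple streams.
#'
#' @param vol An [oct_volume()].
#' @return Numeric vector in acquisition order (depth fastest).
#' @export
flatten_stream <- function(vol) {
  stopifnot(inherits(vol, "OCTVolume"))
  as.vector(aperm(vol$data, c(3, 2, 1)))
}

#' Logarithmic compression for display and edge detection
#'
#' Maps linear intensity to decibels above a floor:
#' `out = 20 * log10(max(in, floor) / floor)`. The transform is monotone
#' and non-negative; the floor suppresses log blow-up in the background.
#'
#' @param vol An [oct_volume()] in linear scale.
#' @param floor Positive intensity mapped to 0 dB.
#' @return An [oct_volume()] in dB scale.
#' @export
log_compress <- function(vol, floor = 1e-4) {
  stopifnot(inherits(vol, "OCTVolume"))
  if (!is.numeric(floor) || floor <= 0)
    stop("floor must be a positive intensity", call. = FALSE)
  if (vol$scale != "linear")
    stop("log_compress expects a linear-scale volume", call. = FALSE)
  out <- vol
  out$data <- 20 * log10(pmax(vol$data, floor) / floor)
  out$scale <- "dB"
  out
}

# dB transform of a single B-scan matrix
db_image <- function(img, floor = 1e-4) 20 * log10(pmax(img, floor) / floor)

#' Render a B-scan as a circular (polar) disk image
#'
#' Maps the rectangular `[a_line, depth]` B-scan onto a Cartesian disk
#' resembling the physical colon cross-section. A-line index `i` maps to
#' angle `theta = 2*pi*i / a_lines_per_bscan`, counter-clockwise from the
#' +x (3 o'clock) axis; depth sample `d` maps to radius
#' `r0_mm + d * axial_pixel_pitch / 1000`.
#'
#' @param bscan Numeric matrix `[a_line, depth]`.
#' @param geom A [scan_geometry()].
#' @param out_px Even output image size in pixels (square).
#' @param r0_mm Radius (mm) of depth sample 0; defaults to the package
#'   convention of [simulate_volume()] (just inside the sheath inner wall).
#' @param interp `"bilinear"` (default) or `"nearest"`.
#' @param background Value for pixels inside the minimum radius or beyond
#'   the recorded depth.
#' @return `out_px` x `out_px` numeric matrix; the pixel grid spacing is
#'   one axial pixel pitch.
#' @export
to_polar_disk <- function(bscan, geom, out_px = NULL,
                          r0_mm = depth0_radius(geom),
                          interp = c("bilinear", "nearest"),
                          background = 0) {
  interp <- match.arg(interp)
  stopifnot(is.matrix(bscan), inherits(geom, "ScanGeometry"))
  na <- nrow(bscan)
  nd <- ncol(bscan)
  pitch_mm <- geom$axial_pixel_pitch / 1000
  r_max_px <- r0_mm / pitch_mm + nd          # outermost sampled radius, px
  need <- 2 * ceiling(r_max_px) + 2
  if (is.null(out_px)) out_px <- need + (need %% 2)
  if (out_px %% 2 != 0) stop("out_px must be even", call. = FALSE)
  if (out_px < need)
    stop("out_px = ", out_px, " too small to contain the maximum radius (",
         need, " px required)", call. = FALSE)

  ctr <- (out_px + 1) / 2
  xy <- seq_len(out_px) - ctr                 # pixel offsets, axial-pitch units
  x <- matrix(xy, out_px, out_px)
  y <- matrix(xy, out_px, out_px, byrow = TRUE)
  r_px <- sqrt(x^2 + y^2)
  theta <- atan2(y, x) %% (2 * pi)

  d <- r_px - r0_mm / pitch_mm                # fractional depth sample
  a <- theta / (2 * pi) * na                  # fractional a-line index

  out <- matrix(background, out_px, out_px)
  ok <- d >= 0 & d <= nd - 1
  if (interp == "nearest") {
    ai <- (round(a[ok]) %% na) + 1L
    di <- round(d[ok]) + 1L
    out[ok] <- bscan[cbind(ai, di)]
  } else {
    a0 <- floor(a[ok]); af <- a[ok] - a0
    d0 <- floor(d[ok]); df <- d[ok] - d0
    i00 <- cbind((a0 %% na) + 1L, d0 + 1L)
    i10 <- cbind(((a0 + 1) %% na) + 1L, d0 + 1L)
    d1 <- pmin(d0 + 1, nd - 1)                # clamp last depth row
    i01 <- cbind((a0 %% na) + 1L, d1 + 1L)
    i11 <- cbind(((a0 + 1) %% na) + 1L, d1 + 1L)
    out[ok] <- bscan[i00] * (1 - af) * (1 - df) +
      bscan[i10] * af * (1 - df) +
      bscan[i01] * (1 - af) * df +
      bscan[i11] * af * df
  }
  out
}

#' Extract an enface slice at a fixed depth below the wall surface
#'
#' Requires a flattened volume (surface aligned to row 0, see
#' [flatten_volume()]); the slice at `depth_offset` samples below the
#' surface is returned as a `[bscan, a_line]` image. A-lines whose wall is
#' thinner than the offset, or with no detected wall, get the background
#' value.
#'
#' @param flat A `FlattenedVolume` (from [flatten_volume()]).
#' @param depth_offset Non-negative depth offset in samples below the
#'   surface.
#' @param slab Number of consecutive depth samples averaged (slab
#'   projection); 1 gives a single-sample slice. Averaging over a thin
#'   slab is the usual way to beat single-sample speckle in enface views.
#' @param background Fill value outside the recorded wall.
#' @return Numeric matrix `[bscan, a_line]`.
#' @export
extract_enface <- function(flat, depth_offset = 0, slab = 1L,
                           background = 0) {
  stopifnot(inherits(flat, "FlattenedVolume"), slab >= 1)
  if (depth_offset < 0) stop("depth_offset must be >= 0", call. = FALSE)
  nb <- dim(flat$data)[1]
  na <- dim(flat$data)[2]
  acc <- matrix(0, nb, na)
  cnt <- matrix(0L, nb, na)
  for (j in depth_offset + seq_len(slab) - 1L) {
    if (j >= flat$crop_depth) break
    valid <- !is.na(flat$height) & flat$height > j
    acc[valid] <- acc[valid] + flat$data[, , j + 1L][valid]
    cnt[valid] <- cnt[valid] + 1L
  }
  out <- matrix(background, nb, na)
  out[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
  out
}
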