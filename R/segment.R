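#' Segmentation parameters
#'
#' Tunable parameters of the colon-wall segmentation pipeline. Edge
#' detection operates on log-compressed (dB) images, where multiplicative
#' speckle becomes additive and gradient statistics are comparable across
#' depth.
#'
#' @param sigma Gaussian smoothing scale for Canny, in pixels.
#' @param low,high Hysteresis thresholds, relative to the maximum gradient
#'   magnitude after non-maximum suppression; `0 <= low < high <= 1`.
#' @param se_radius Disk radius (px) of the structuring element for
#'   morphological closing.
#' @param sheath_margin Extra margin (px) around the sheath ring depths
#'   removed before component selection.
#' @param max_gap_deg Angular width (degrees) up to which missing-boundary
#'   gaps are bridged by linear interpolation; wider gaps stay missing.
#' @param db_floor Intensity floor of the dB transform used for edge
#'   detection; `NULL` (default) estimates it per frame from the deepest
#'   image rows (see [estimate_noise_floor()]), which suppresses
#'   background-speckle edges.
#' @param min_component_px Connected components smaller than this are
#'   ignored when selecting the wall.
#' @param rel_component Components smaller than this fraction of the
#'   largest one are also ignored.
#' @return A `SegParams` list.
#' @export
seg_params <- function(sigma = 2, low = 0.1, high = 0.3, se_radius = 6,
                       sheath_margin = 3, max_gap_deg = 15,
                       db_floor = NULL, min_component_px = 3,
                       rel_component = 0) {
  if (!(low >= 0 && low < high && high <= 1))
    stop("hysteresis thresholds must satisfy 0 <= low < high <= 1",
         call. = FALSE)
  stopifnot(sigma > 0, se_radius >= 1)
  structure(list(sigma = sigma, low = low, high = high,
                 se_radius = se_radius, sheath_margin = sheath_margin,
                 max_gap_deg = max_gap_deg, db_floor = db_floor,
                 min_component_px = min_component_px,
                 rel_component = rel_component),
            class = "SegParams")
}

#' Estimate the background intensity floor of a B-scan
#'
#' Takes the median linear intensity of the deepest `frac` of depth rows
#' (assumed to lie beyond the tissue) times a safety `factor`. Used as the
#' dB floor for edge detection so background speckle clips to 0 dB
#' instead of generating spurious edges.
#'
#' @param bscan Linear-intensity matrix `[a_line, depth]`.
#' @param frac Fraction of deepest depth samples treated as background.
#' @param factor Multiplier above the background median.
#' @return Positive scalar intensity.
#' @export
estimate_noise_floor <- function(bscan, frac = 0.1, factor = 4) {
  nd <- ncol(bscan)
  tail_cols <- max(1L, floor(nd * (1 - frac))):nd
  max(factor * stats::median(bscan[, tail_cols]), 1e-12)
}

# separable Gaussian convolution with replicated edges
gauss_blur <- function(img, sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(m, along) {
    out <- matrix(0, nrow(m), ncol(m))
    n <- if (along == 1) nrow(m) else ncol(m)
    for (j in -h:h) {
      idx <- pmin(pmax(seq_len(n) + j, 1L), n)
      out <- out + k[j + h + 1L] *
        (if (along == 1) m[idx, , drop = FALSE] else m[, idx, drop = FALSE])
    }
    out
  }
  conv1(conv1(img, 1), 2)
}

shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

#' Canny edge detection
#'
#' Standard Canny pipeline: Gaussian smoothing, central-difference
#' gradients, non-maximum suppression along the quantised gradient
#' direction, and hysteresis thresholding (weak-edge pixels are kept only
#' if 8-connected to a strong pixel). Thresholds are relative to the
#' maximum suppressed gradient magnitude.
#'
#' @param img Numeric matrix (typically a dB B-scan `[a_line, depth]`).
#' @param sigma Gaussian smoothing scale in pixels.
#' @param low,high Relative hysteresis thresholds, `0 <= low < high <= 1`.
#' @return Logical matrix of edge pixels.
#' @export
detect_edges <- function(img, sigma = 2, low = 0.1, high = 0.3) {
  stopifnot(is.matrix(img))
  if (!(low >= 0 && low < high && high <= 1))
    stop("hysteresis thresholds must satisfy 0 <= low < high <= 1",
         call. = FALSE)
  s <- gauss_blur(img, sigma)
  gx <- (shift_mat(s, -1, 0, fill = NA) - shift_mat(s, 1, 0, fill = NA)) / 2
  gy <- (shift_mat(s, 0, -1, fill = NA) - shift_mat(s, 0, 1, fill = NA)) / 2
  gx[is.na(gx)] <- 0; gy[is.na(gy)] <- 0
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi          # direction modulo 180 degrees

  # quantise direction into 4 sectors and suppress non-maxima
  sector <- findInterval(ang, c(pi / 8, 3 * pi / 8, 5 * pi / 8, 7 * pi / 8)) %% 4
  nms <- matrix(FALSE, nrow(img), ncol(img))
  offs <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))  # row/col step per sector
  for (sct in 0:3) {
    o <- offs[[sct + 1L]]
    n1 <- shift_mat(mag, o[1], o[2], fill = 0)
    n2 <- shift_mat(mag, -o[1], -o[2], fill = 0)
    sel <- sector == sct & mag >= n1 & mag >= n2
    nms[sel] <- TRUE
  }
  supp <- mag * nms
  mx <- max(supp)
  if (mx == 0) return(matrix(FALSE, nrow(img), ncol(img)))
  strong <- supp >= high * mx
  weak <- supp >= low * mx
  if (!any(strong)) return(matrix(FALSE, nrow(img), ncol(img)))
  # hysteresis: keep weak components that contain a strong pixel
  lab <- EBImage::bwlabel(weak)
  keep <- unique(lab[strong])
  matrix(lab %in% keep[keep > 0], nrow(img), ncol(img))
}

#' Fill enclosed holes in a binary image
#'
#' Background regions not reachable from the image border are set to
#' foreground (flood-fill from the border, complemented).
#'
#' @param binary Logical or 0/1 matrix.
#' @return Logical matrix.
#' @export
fill_holes <- function(binary) {
  stopifnot(is.matrix(binary))
  m <- EBImage::fillHull(matrix(as.numeric(binary), nrow(binary), ncol(binary)))
  matrix(as.logical(m > 0), nrow(binary), ncol(binary))
}

#' Morphological refinement (closing)
#'
#' Dilation followed by erosion with a disk structuring element: bridges
#' gaps narrower than the disk diameter and smooths ragged boundaries
#' without eroding isolated foreground.
#'
#' @param binary Logical or 0/1 matrix.
#' @param se_radius Disk radius in pixels (>= 1).
#' @return Logical matrix.
#' @export
morph_refine <- function(binary, se_radius = 6) {
  stopifnot(is.matrix(binary), se_radius >= 1)
  kern <- EBImage::makeBrush(2 * as.integer(se_radius) + 1, shape = "disc")
  m <- matrix(as.numeric(binary), nrow(binary), ncol(binary))
  # pad so closing behaves as on an infinite canvas at the image edges
  p <- as.integer(se_radius) + 1L
  pm <- matrix(0, nrow(m) + 2 * p, ncol(m) + 2 * p)
  pm[p + seq_len(nrow(m)), p + seq_len(ncol(m))] <- m
  cl <- EBImage::erode(EBImage::dilate(pm, kern), kern)
  matrix(as.logical(cl[p + seq_len(nrow(m)), p + seq_len(ncol(m))] > 0),
         nrow(m), ncol(m))
}

# Refine Canny band boundaries on the linear image. The gradient maximum of
# a smoothed flank sits about sigma/2 outside the physical interface, so the
# raw band is systematically one to two samples too wide. The top boundary is
# snapped to the specular interface spike (local intensity maximum); the
# bottom to the half-level crossing of the exit step. Speckle is tamed by a
# circular boxcar across neighbouring A-lines.
refine_boundaries <- function(lin, top, bottom, halo = 5L, search = 3L) {
  na_lines <- nrow(lin)
  nd <- ncol(lin)
  sm <- matrix(0, na_lines, nd)
  for (j in -(halo %/% 2):(halo %/% 2))
    sm <- sm + lin[((seq_len(na_lines) - 1 + j) %% na_lines) + 1L, ]
  sm <- sm / halo
  for (a in seq_len(na_lines)) {
    if (is.na(top[a])) next
    w <- max(0L, top[a] - search):min(nd - 1L, top[a] + search + 1L)
    top[a] <- w[which.max(sm[a, w + 1L])]
    b <- bottom[a]
    lvl <- mean(sm[a, (max(1L, b - 6L)):(max(1L, b - 2L))])
    w <- max(1L, b - search):min(nd - 1L, b + search)
    above <- which(sm[a, w + 1L] >= lvl / 2)
    if (length(above)) bottom[a] <- w[above[length(above)]] + 1L
    if (bottom[a] <= top[a]) bottom[a] <- top[a] + 1L
  }
  list(top = top, bottom = bottom)
}

# depth-sample index range (0-based, inclusive) occupied by the sheath rings
sheath_depth_range <- function(geom, margin = 3, r0_mm = depth0_radius(geom)) {
  lo <- floor(radius_to_depth(geom$sheath_inner_radius, geom, r0_mm)) - margin
  hi <- ceiling(radius_to_depth(geom$sheath_outer_radius, geom, r0_mm)) + margin
  c(max(0, lo), hi)
}

#' Build the wall mask of one B-scan from a refined edge image
#'
#' Removes foreground at the known sheath-ring depths, keeps the wall
#' components (the largest remaining 8-connected component together with
#' every component of comparable size: the Canny map of a layered,
#' speckled B-scan yields one curve per optical interface, and the wall is
#' their union), and extracts per-A-line top and bottom boundaries as the
#' first and last foreground sample of the kept set. A-lines with no
#' foreground are bridged by linear interpolation across angular gaps up
#' to `max_gap_deg`, otherwise left missing. The returned mask is the
#' contiguous band `[top, bottom)` per A-line.
#'
#' @param refined Logical matrix `[a_line, depth]` after [morph_refine()].
#' @param geom A [scan_geometry()].
#' @param params A [seg_params()].
#' @param r0_mm Radius (mm) of depth sample 0.
#' @return List with `top`, `bottom` (0-based depth indices, `NA` where
#'   missing), `mask` (logical band matrix) and `empty` flag.
#' @export
build_wall_mask <- function(refined, geom, params = seg_params(),
                            r0_mm = depth0_radius(geom)) {
  stopifnot(is.matrix(refined))
  na_lines <- nrow(refined)
  nd <- ncol(refined)
  work <- refined
  sr <- sheath_depth_range(geom, params$sheath_margin, r0_mm)
  cols <- (sr[1]:min(sr[2], nd - 1)) + 1L
  work[, cols] <- FALSE

  lab <- EBImage::bwlabel(matrix(as.numeric(work), na_lines, nd))
  sizes <- tabulate(lab[lab > 0])
  sizes[sizes < params$min_component_px] <- 0L
  if (!length(sizes) || !any(sizes > 0))
    return(list(top = rep(NA_integer_, na_lines),
                bottom = rep(NA_integer_, na_lines),
                mask = matrix(FALSE, na_lines, nd), empty = TRUE))
  keep <- which(sizes >= max(sizes) * params$rel_component & sizes > 0)
  comp <- matrix(lab %in% keep, na_lines, nd)

  top <- rep(NA_integer_, na_lines)
  bottom <- rep(NA_integer_, na_lines)
  hit <- which(rowSums(comp) > 0)
  for (a in hit) {
    w <- which(comp[a, ])
    top[a] <- w[1L] - 1L
    bottom[a] <- w[length(w)]          # half-open: one past last foreground
  }
  filled <- bridge_gaps(top, bottom, na_lines, geom, params$max_gap_deg)
  top <- filled$top; bottom <- filled$bottom

  didx <- matrix(rep(seq_len(nd) - 1, each = na_lines), na_lines, nd)
  mask <- !is.na(top) & didx >= top & didx < bottom
  mask[is.na(mask)] <- FALSE
  list(top = top, bottom = bottom,
       mask = matrix(mask, na_lines, nd), empty = FALSE)
}

# Linearly interpolate NA runs in circular per-A-line boundaries when the
# run is at most max_gap_deg wide; longer runs stay NA.
bridge_gaps <- function(top, bottom, na_lines, geom, max_gap_deg) {
  miss <- is.na(top)
  if (!any(miss) || all(miss)) return(list(top = top, bottom = bottom))
  max_gap <- ceiling(max_gap_deg / 360 * na_lines)
  runs <- rle(miss)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  interp_circ <- function(v) {
    # pad one wrap on each side so circular gaps interpolate across 0
    idx <- which(!is.na(v))
    xi <- c(idx - na_lines, idx, idx + na_lines)
    yi <- rep(v[idx], 3L)
    round(stats::approx(xi, yi, xout = seq_len(na_lines))$y)
  }
  ti <- interp_circ(top); bi <- interp_circ(bottom)
  for (r in which(runs$values)) {
    len <- runs$lengths[r]
    # a run touching the vector ends may wrap; merge with the opposite end run
    wrap_len <- len
    if (starts[r] == 1L && runs$values[length(runs$values)] &&
        length(runs$values) > 1L)
      wrap_len <- len + runs$lengths[length(runs$lengths)]
    if (ends[r] == na_lines && runs$values[1L] && length(runs$values) > 1L)
      wrap_len <- len + runs$lengths[1L]
    if (wrap_len <= max_gap) {
      sel <- starts[r]:ends[r]
      top[sel] <- ti[sel]
      bottom[sel] <- bi[sel]
    }
  }
  list(top = top, bottom = bottom)
}

#' Multiply a B-scan by its binary wall mask
#'
#' @param bscan Numeric matrix.
#' @param mask Logical/0-1 matrix of the same shape.
#' @return Numeric matrix with zeros outside the wall.
#' @export
apply_mask <- function(bscan, mask) {
  if (!all(dim(bscan) == dim(mask)))
    stop("bscan and mask shapes differ", call. = FALSE)
  bscan * (mask != 0)
}

#' Segment the colon wall in every B-scan of a volume
#'
#' Runs the full per-frame pipeline: log compression, Canny edge
#' detection, hole filling, morphological closing, sheath removal and
#' band extraction.
#'
#' @param vol An [oct_volume()] in linear scale.
#' @param params A [seg_params()].
#' @param r0_mm Radius (mm) of depth sample 0.
#' @return A `WallMask` list with matrices `top` and `bottom`
#'   (`[bscan, a_line]`, 0-based depth indices, `NA` where no wall was
#'   found) and the geometry.
#' @export
segment_volume <- function(vol, params = seg_params(),
                           r0_mm = depth0_radius(vol$geom)) {
  stopifnot(inherits(vol, "OCTVolume"))
  nb <- dim(vol$data)[1]
  na <- dim(vol$data)[2]
  top <- matrix(NA_integer_, nb, na)
  bottom <- matrix(NA_integer_, nb, na)
  sr <- sheath_depth_range(vol$geom, params$sheath_margin, r0_mm)
  nd <- dim(vol$data)[3]
  sheath_cols <- (sr[1]:min(sr[2], nd - 1)) + 1L
  for (b in seq_len(nb)) {
    lin <- vol$data[b, , ]
    floor_b <- params$db_floor %||% estimate_noise_floor(lin)
    # suppress the sheath rings (known hardware geometry) ahead of edge
    # detection so gradient thresholds adapt to tissue contrast
    lin[, sheath_cols] <- floor_b
    img <- db_image(lin, floor_b)
    edges <- detect_edges(img, params$sigma, params$low, params$high)
    filled <- fill_holes(edges)
    refined <- morph_refine(filled, params$se_radius)
    wm <- build_wall_mask(refined, vol$geom, params, r0_mm)
    rf <- refine_boundaries(vol$data[b, , ], wm$top, wm$bottom)
    top[b, ] <- rf$top
    bottom[b, ] <- rf$bottom
  }
  structure(list(top = top, bottom = bottom, geom = vol$geom),
            class = "WallMask")
}

#' Binary wall-mask volume from per-A-line boundaries
#'
#' @param wm A `WallMask` (from [segment_volume()]) or `GroundTruth`.
#' @return Logical array `[bscan, a_line, depth]`: the band
#'   `[top, bottom)` per A-line.
#' @export
mask_array <- function(wm) {
  geom <- wm$geom
  nb <- nrow(wm$top); na <- ncol(wm$top); nd <- geom$n_depth_samples
  arr <- array(FALSE, dim = c(nb, na, nd))
  didx <- matrix(rep(seq_len(nd) - 1, each = na), na, nd)
  for (b in seq_len(nb)) {
    m <- !is.na(wm$top[b, ]) & didx >= wm$top[b, ] & didx < wm$bottom[b, ]
    m[is.na(m)] <- FALSE
    arr[b, , ] <- m
  }
  arr
}

#' Dice overlap coefficient between two binary masks
#'
#' `2 |A & B| / (|A| + |B|)`; 1 for identical non-empty masks.
#'
#' @param a,b Logical arrays of identical shape.
#' @return Numeric scalar in `[0, 1]` (`NaN` if both masks are empty).
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Flatten a B-scan on its top boundary
#'
#' Shifts each A-line up by its detected surface depth so the wall surface
#' sits at row 0, then crops to `crop_depth` samples. The shifts are stored
#' so the operation is invertible on in-wall pixels ([unflatten_bscan()]).
#'
#' @param bscan Numeric matrix `[a_line, depth]`.
#' @param top,bottom Per-A-line 0-based boundary indices (`NA` allowed).
#' @param crop_depth Number of depth samples to retain; defaults to the
#'   maximum wall height.
#' @param background Fill value for A-lines without a detected wall.
#' @return A `FlattenedBScan` list with `image`, `shifts`, `height`,
#'   `crop_depth`.
#' @export
flatten_bscan <- function(bscan, top, bottom, crop_depth = NULL,
                          background = 0) {
  stopifnot(is.matrix(bscan), length(top) == nrow(bscan))
  nd <- ncol(bscan)
  height <- bottom - top
  if (is.null(crop_depth)) crop_depth <- max(height, na.rm = TRUE)
  if (crop_depth > nd) {
    warning("crop_depth ", crop_depth, " exceeds depth range ", nd,
            "; clipping")
    crop_depth <- nd
  }
  img <- matrix(background, nrow(bscan), crop_depth)
  for (a in seq_len(nrow(bscan))) {
    if (is.na(top[a])) next
    src <- (top[a] + 1L):min(nd, top[a] + crop_depth)
    img[a, seq_along(src)] <- bscan[a, src]
  }
  structure(list(image = img, shifts = top, height = height,
                 crop_depth = as.integer(crop_depth)),
            class = "FlattenedBScan")
}

#' Undo the flattening of a B-scan
#'
#' @param flat A `FlattenedBScan`.
#' @param n_depth Depth-sample count of the original B-scan.
#' @param background Fill value outside restored pixels.
#' @return Numeric matrix `[a_line, n_depth]`; all pixels that survived
#'   the crop are restored exactly.
#' @export
unflatten_bscan <- function(flat, n_depth, background = 0) {
  stopifnot(inherits(flat, "FlattenedBScan"))
  na_lines <- nrow(flat$image)
  out <- matrix(background, na_lines, n_depth)
  for (a in seq_len(na_lines)) {
    if (is.na(flat$shifts[a])) next
    dst <- (flat$shifts[a] + 1L):min(n_depth, flat$shifts[a] + flat$crop_depth)
    out[a, dst] <- flat$image[a, seq_along(dst)]
  }
  out
}

#' Flatten every B-scan of a volume
#'
#' @param vol An [oct_volume()].
#' @param wm A `WallMask` (or `GroundTruth`) with `top`/`bottom` matrices.
#' @param crop_depth Depth samples retained below the surface; defaults to
#'   the maximum wall height over the volume.
#' @param mask_first If `TRUE` (default), pixels outside the wall band are
#'   zeroed before flattening (mask multiplication).
#' @return A `FlattenedVolume` list with `data` `[bscan, a_line,
#'   crop_depth]`, `shifts`, `height`, `crop_depth`, `geom`.
#' @export
flatten_volume <- function(vol, wm, crop_depth = NULL, mask_first = TRUE) {
  stopifnot(inherits(vol, "OCTVolume"))
  nb <- dim(vol$data)[1]
  height <- wm$bottom - wm$top
  if (is.null(crop_depth)) crop_depth <- max(height, na.rm = TRUE)
  crop_depth <- min(crop_depth, dim(vol$data)[3])
  data <- array(0, dim = c(nb, dim(vol$data)[2], crop_depth))
  for (b in seq_len(nb)) {
    img <- vol$data[b, , ]
    if (mask_first) {
      nd <- ncol(img)
      didx <- matrix(rep(seq_len(nd) - 1, each = nrow(img)), nrow(img), nd)
      m <- !is.na(wm$top[b, ]) & didx >= wm$top[b, ] & didx < wm$bottom[b, ]
      m[is.na(m)] <- FALSE
      img <- apply_mask(img, matrix(m, nrow(img), nd))
    }
    fb <- flatten_bscan(img, wm$top[b, ], wm$bottom[b, ], crop_depth)
    data[b, , ] <- fb$image
  }
  structure(list(data = data, shifts = wm$top, height = height,
                 crop_depth = as.integer(crop_depth), geom = vol$geom),
            class = "FlattenedVolume")
}
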