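test_that("Canny finds a sharp step as a thin edge and ignores flats", {
  img <- matrix(0, 40, 60)
  img[, 31:60] <- 10
  e <- detect_edges(img, sigma = 1, low = 0.2, high = 0.5)
  hit <- which(e, arr.ind = TRUE)
  expect_true(nrow(hit) >= 40)                 # edge on every row
  expect_true(all(abs(hit[, 2] - 30.5) <= 1))  # within 1 px of the step
  expect_true(all(tabulate(hit[, 1], 40) <= 2))# at most 2 px thick per row

  expect_false(any(detect_edges(matrix(5, 30, 30))))
  expect_error(detect_edges(img, low = 0.5, high = 0.2), "thresholds")
})

test_that("Canny localises the phantom surface on nearly all A-lines", {
  g <- small_geom(a_lines = 240, n_bscans = 1)
  sim <- simulate_volume(phantom_spec(seed = 12), g)
  lin <- sim$volume$data[1, , ]
  fl <- estimate_noise_floor(lin)
  sr <- endoct:::sheath_depth_range(g, 3)
  lin[, (sr[1]:sr[2]) + 1] <- fl
  e <- detect_edges(20 * log10(pmax(lin, fl) / fl), 2, 0.1, 0.3)
  tt <- sim$truth$top[1, ]
  near <- vapply(seq_len(240), function(a)
    any(e[a, (tt[a] - 1):(tt[a] + 3)]), logical(1))
  expect_gte(mean(near), 0.95)
})

test_that("hole filling matches a border flood-fill oracle", {
  # oracle: BFS flood fill of background from the border; unreached
  # background pixels are holes
  flood_fill_holes <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    reach <- matrix(FALSE, nr, nc)
    queue <- which((row(m) == 1 | row(m) == nr | col(m) == 1 |
                      col(m) == nc) & !m)
    reach[queue] <- TRUE
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      r <- (i - 1) %% nr + 1; c <- (i - 1) %/% nr + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          j <- rr + (cc - 1) * nr
          if (!m[j] && !reach[j]) { reach[j] <- TRUE; queue <- c(queue, j) }
        }
      }
    }
    m | !reach
  }

  hollow <- matrix(FALSE, 12, 12)
  hollow[3:9, 3:9] <- TRUE
  hollow[5:7, 5:7] <- FALSE
  expect_identical(fill_holes(hollow), flood_fill_holes(hollow))
  expect_true(all(fill_holes(hollow)[5:7, 5:7]))

  # idempotence on an already-solid shape
  solid <- matrix(FALSE, 10, 10); solid[2:8, 2:8] <- TRUE
  expect_identical(fill_holes(solid), solid)

  # random blobs against the oracle
  set.seed(5)
  for (k in 1:5) {
    m <- matrix(runif(400) < 0.4, 20, 20)
    expect_identical(fill_holes(m), flood_fill_holes(m))
  }
})

test_that("morphological closing matches a brute-force oracle", {
  disk_offsets <- function(r) {
    o <- expand.grid(dr = -r:r, dc = -r:r)
    # EBImage disc brush includes offsets within radius r (its discrete disc)
    kern <- EBImage::makeBrush(2 * r + 1, "disc")
    o[kern[cbind(o$dr + r + 1, o$dc + r + 1)] > 0, ]
  }
  brute_close <- function(m, r) {
    off <- disk_offsets(r)
    p <- r + 1                        # pad: outside the image is background
    pm <- matrix(FALSE, nrow(m) + 2 * p, ncol(m) + 2 * p)
    pm[p + seq_len(nrow(m)), p + seq_len(ncol(m))] <- m
    nr <- nrow(pm); nc <- ncol(pm)
    sweep_se <- function(x, combine, fill) {
      out <- matrix(fill == "none", nr, nc)  # TRUE for AND, FALSE for OR
      for (i in seq_len(nrow(off))) {
        sh <- matrix(FALSE, nr, nc)
        rs <- seq_len(nr) - off$dr[i]; cs <- seq_len(nc) - off$dc[i]
        rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
        sh[rok, cok] <- x[rs[rok], cs[cok]]
        out <- combine(out, sh)
      }
      out
    }
    dil <- sweep_se(pm, `|`, fill = "bg")
    ero <- sweep_se(dil, `&`, fill = "none")
    ero[p + seq_len(nrow(m)), p + seq_len(ncol(m))]
  }

  set.seed(11)
  for (r in c(1, 2, 3)) {
    m <- matrix(runif(400) < 0.25, 20, 20)
    expect_identical(morph_refine(m, r), brute_close(m, r))
  }

  # two blobs closer than the disk diameter are merged
  m <- matrix(FALSE, 20, 20)
  m[8:12, 3:7] <- TRUE
  m[8:12, 12:16] <- TRUE                # gap of 4 columns
  cl <- morph_refine(m, 3)
  expect_equal(max(EBImage::bwlabel(matrix(as.numeric(cl), 20, 20))), 1)

  # a solid block and an isolated pixel survive closing unchanged
  blk <- matrix(FALSE, 15, 15); blk[4:10, 4:10] <- TRUE
  expect_identical(morph_refine(blk, 2), blk)
  px <- matrix(FALSE, 9, 9); px[5, 5] <- TRUE
  expect_true(morph_refine(px, 2)[5, 5])
})

test_that("a constant-depth band is recovered exactly", {
  g <- small_geom(a_lines = 80, n_bscans = 1, n_depth = 200)
  band <- matrix(FALSE, 80, 200)
  band[, 101:140] <- TRUE               # depth samples 100..139
  wm <- build_wall_mask(band, g)
  expect_false(wm$empty)
  expect_equal(unique(wm$top), 100)
  expect_equal(unique(wm$bottom), 140)
  expect_identical(wm$mask, band)
})

test_that("angular gaps are bridged only up to the configured width", {
  g <- small_geom(a_lines = 360, n_bscans = 1, n_depth = 200)
  band <- matrix(FALSE, 360, 200)
  band[, 101:140] <- TRUE
  band[30:39, ] <- FALSE                # 10 degree gap -> bridged
  band[100:170, ] <- FALSE              # 71 degree gap -> left missing
  wm <- build_wall_mask(band, g, seg_params(max_gap_deg = 15,
                                            min_component_px = 3))
  expect_equal(wm$top[30:39], rep(100L, 10))
  expect_true(all(is.na(wm$top[110:160])))
})

test_that("an empty frame is flagged, not an exception", {
  g <- small_geom(a_lines = 40, n_bscans = 1, n_depth = 100)
  wm <- build_wall_mask(matrix(FALSE, 40, 100), g)
  expect_true(wm$empty)
  expect_true(all(is.na(wm$top)))
})

test_that("mask multiplication behaves as elementwise gating", {
  img <- matrix(runif(100), 10, 10)
  expect_identical(apply_mask(img, matrix(TRUE, 10, 10)), img)
  expect_true(all(apply_mask(img, matrix(FALSE, 10, 10)) == 0))
  checker <- (row(img) + col(img)) %% 2 == 0
  expect_equal(sum(apply_mask(matrix(1, 10, 10), checker)), 50)
  expect_lte(sum(apply_mask(img, checker)), sum(img))
  expect_error(apply_mask(img, matrix(TRUE, 5, 5)), "shapes differ")
})

test_that("flattening is a per-A-line shift and inverts exactly", {
  g <- small_geom(a_lines = 60, n_bscans = 1, n_depth = 120)
  img <- matrix(runif(60 * 120), 60, 120)
  # constant top boundary: pure translation
  top <- rep(20L, 60); bottom <- rep(80L, 60)
  fb <- flatten_bscan(img, top, bottom, crop_depth = 60)
  expect_equal(fb$image[, 1:60], img[, 21:80])

  # varying boundary: round trip restores every in-wall pixel
  top2 <- 20L + as.integer(round(5 * sin(seq_len(60) / 8)))
  bottom2 <- top2 + 50L
  fb2 <- flatten_bscan(img, top2, bottom2)
  back <- unflatten_bscan(fb2, 120)
  for (a in 1:60)
    expect_identical(back[a, (top2[a] + 1):(bottom2[a])],
                     img[a, (top2[a] + 1):(bottom2[a])])

  expect_warning(flatten_bscan(img, top, bottom, crop_depth = 500),
                 "clipping")
})

test_that("segmentation recovers the phantom wall with high overlap", {
  g <- small_geom(a_lines = 240, n_bscans = 4)
  sim <- simulate_volume(phantom_spec(seed = 21), g)
  wm <- segment_volume(sim$volume)
  expect_gte(dice_coefficient(mask_array(wm), sim$truth$wall_mask), 0.95)
  # determinism of the pipeline
  wm2 <- segment_volume(sim$volume)
  expect_identical(wm$top, wm2$top)
  expect_identical(wm$bottom, wm2$bottom)
  # band contiguity by construction
  arr <- mask_array(wm)
  runs <- apply(arr[1, , ], 1, function(v) sum(diff(v) != 0))
  expect_true(all(runs <= 2))
  # flattening on the detected surface puts tissue at row 0 everywhere
  flat <- flatten_volume(sim$volume, wm)
  expect_true(all(flat$data[, , 1][!is.na(flat$height)] > 0))
})

test_that("overlap degrades as speckle contrast is pushed up", {
  # sanity direction check: heavier-tailed noise (squared exponential
  # speckle) must not segment better than the default
  g <- small_geom(a_lines = 180, n_bscans = 2)
  sim <- simulate_volume(phantom_spec(seed = 31), g)
  d_default <- dice_coefficient(mask_array(segment_volume(sim$volume)),
                                sim$truth$wall_mask)
  harsh <- sim
  set.seed(31)
  extra <- array(rexp(length(harsh$volume$data)),
                 dim = dim(harsh$volume$data))
  harsh$volume$data <- harsh$volume$data * extra
  d_harsh <- dice_coefficient(mask_array(segment_volume(harsh$volume)),
                              sim$truth$wall_mask)
  expect_lte(d_harsh, d_default + 0.005)
})
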