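test_that("thickness converts boundary bands to physical micrometres", {
  g <- scan_geometry(axial_pixel_pitch = 5, refractive_index = 1,
                     a_lines_per_bscan = 3, n_bscans = 2,
                     n_depth_samples = 200)
  wm <- list(top = matrix(10, 2, 3), bottom = matrix(110, 2, 3), geom = g)
  expect_true(all(thickness_map(wm) == 500))

  # missing A-lines stay missing and are excluded from summaries
  wm$top[1, 2] <- NA
  tm <- thickness_map(wm)
  expect_true(is.na(tm[1, 2]))
  prof <- sample_thickness(tm, g, n_locations = 1)
  expect_equal(prof$thickness_um, 500)
})

test_that("the location profile bins the pullback and tracks gradients", {
  g <- small_geom(n_bscans = 40)
  # uniform map: every bin equals the true thickness
  tmap <- matrix(380, 40, 10)
  prof <- sample_thickness(tmap, g, 10)
  expect_equal(nrow(prof), 10)
  expect_true(all(prof$thickness_um == 380))
  expect_equal(prof$position_mm, seq(0.6, 11.4, by = 1.2))

  # n_locations = 1 reduces to the global median
  expect_equal(sample_thickness(tmap, g, 1)$thickness_um, median(tmap))

  # a linear thickness gradient along the pullback gives a monotone profile
  grad <- matrix(rep(seq(200, 600, length.out = 40), 10), 40, 10)
  expect_true(all(diff(sample_thickness(grad, g, 10)$thickness_um) > 0))

  # empty bins warn and stay missing
  sparse <- matrix(NA_real_, 40, 10)
  sparse[1:4, ] <- 300
  expect_warning(p2 <- sample_thickness(sparse, g, 10), "no measurable")
  expect_true(is.na(p2$thickness_um[10]))
})

test_that("Beer-Lambert fits are exact on noiseless exponentials", {
  g <- small_geom(n_depth = 400)
  for (mu in c(0.5, 1, 2, 4)) {
    a <- simulate_ascan(c(10, 350), mu, g, reflectivity = 0.3)
    fit <- fit_attenuation(a, 12, 300, g)
    expect_lt(abs(fit$mu_A - mu) / mu, 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  }
  # constant profile: zero attenuation
  flat_prof <- rep(0.2, 400)
  expect_equal(fit_attenuation(flat_prof, 0, 100, g)$mu_A, 0)
  expect_error(fit_attenuation(flat_prof, 0, 3, g), "at least 4")
  expect_error(fit_attenuation(rep(-1, 400), 0, 100, g, noise_floor = -1),
               "non-finite")
})

test_that("averaging more A-lines tightens the attenuation estimate", {
  g <- small_geom(n_depth = 400)
  mu <- 2
  err_for_n <- function(n, seed) {
    set.seed(seed)
    prof <- rowMeans(replicate(n, simulate_ascan(
      c(10, 350), mu, g, reflectivity = 0.3, speckle = "exponential")))
    abs(fit_attenuation(prof, 13, 200, g, noise_floor = 1e-9)$mu_A - mu) / mu
  }
  errs <- vapply(c(10, 100, 1000), function(n)
    median(vapply(1:5, function(s) err_for_n(n, 100 + s), numeric(1))),
    numeric(1))
  # monotone decrease within Monte-Carlo slack
  expect_lt(errs[2], errs[1] * 1.5)
  expect_lt(errs[3], errs[2] * 1.5)
  expect_lt(errs[3], errs[1])
})

test_that("per-layer fits recover generator attenuations within 10%", {
  g <- small_geom(a_lines = 240, n_bscans = 30, n_depth = 400)
  mus <- c(3, 1, 2, 1.5)
  ph <- phantom_spec(layers = make_layers(c(200, 100, 100, 150), mus),
                     seed = 11)
  sim <- simulate_volume(ph, g)
  flat <- flatten_volume(sim$volume, sim$truth)
  la <- suppressWarnings(
    layer_attenuation(flat, truth_layer_offsets(sim$truth), g, n_bins = 10))
  agg <- aggregate(mu_A ~ layer, la, median)
  truth <- sim$truth$layer_attenuation
  for (i in seq_len(nrow(agg))) {
    mu_true <- truth[[agg$layer[i]]]
    expect_lt(abs(agg$mu_A[i] - mu_true) / mu_true, 0.10)
  }
})

test_that("identical layers give indistinguishable per-layer estimates", {
  g <- small_geom(a_lines = 240, n_bscans = 20, n_depth = 400)
  ph <- phantom_spec(layers = make_layers(c(150, 120, 120, 150),
                                          rep(2, 4), rep(0.2, 4)),
                     seed = 14)
  sim <- simulate_volume(ph, g)
  flat <- flatten_volume(sim$volume, sim$truth)
  la <- suppressWarnings(
    layer_attenuation(flat, truth_layer_offsets(sim$truth), g, n_bins = 5))
  agg <- aggregate(mu_A ~ layer, la, median)
  expect_lt(max(abs(agg$mu_A - 2)) / 2, 0.12)
})

test_that("an inflamed phantom shows the attenuation drop it was given", {
  g <- small_geom(a_lines = 240, n_bscans = 30, n_depth = 400)
  s0 <- simulate_volume(phantom_spec(seed = 3), g)
  s9 <- simulate_volume(phantom_spec(seed = 4), g, attenuation_scale = 0.7)
  mu_of <- function(sim) {
    flat <- flatten_volume(sim$volume, sim$truth)
    la <- suppressWarnings(layer_attenuation(
      flat, truth_layer_offsets(sim$truth), sim$truth$geom))
    median(la$mu_A[la$layer == "colonic_mucosa"], na.rm = TRUE)
  }
  expect_equal(mu_of(s9) / mu_of(s0), 0.7, tolerance = 0.05 / 0.7)
})

test_that("baseline normalisation maps multiples to percent change", {
  df <- data.frame(mouse = rep(c("m1", "m2"), each = 3),
                   day = rep(c(0, 9, 24), 2),
                   thickness_um = c(400, 600, 400, 300, 210, 450))
  out <- normalize_to_baseline(df, "thickness_um")
  expect_equal(out$pct_change, c(0, 50, 0, 0, -30, 50))

  df2 <- rbind(df, data.frame(mouse = "m3", day = 9, thickness_um = 500))
  expect_warning(out2 <- normalize_to_baseline(df2, "thickness_um"),
                 "no baseline")
  expect_false("m3" %in% out2$mouse)
})

test_that("measured thickness scales with the phantom multiplier", {
  g <- small_geom(a_lines = 120, n_bscans = 3)
  base <- quiet_phantom(seed = 6)
  med <- function(scale) {
    sim <- simulate_volume(base, g, thickness_scale = scale)
    median(thickness_map(sim$truth))
  }
  vals <- vapply(c(1, 1.2, 1.5), med, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_equal(vals[3] / vals[1], 1.5, tolerance = 0.01)
})
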