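test_that("noise-free A-scan follows the round-trip Beer-Lambert model", {
  g <- small_geom(n_depth = 500)

  # zero attenuation: constant backscatter below the surface
  a0 <- simulate_ascan(c(10, 400), 0, g, reflectivity = 0.3)
  expect_equal(unique(a0[12:400]), 0.3)
  expect_equal(unique(a0[1:10]), 0)

  # 1/mm at 0.5 mm below the surface: I/I0 = exp(-1)
  px_half_mm <- 0.5 * 1000 * g$refractive_index / g$axial_pixel_pitch # 138
  a1 <- simulate_ascan(c(0, 400), 1, g, reflectivity = 1)
  expect_equal(a1[1 + px_half_mm] / a1[1], exp(-1), tolerance = 1e-12)

  # two layers: level at the second interface carries the full first-layer
  # round-trip decay
  mus <- c(2, 0.5)
  b <- c(10, 150, 300)
  a2 <- simulate_ascan(b, mus, g, reflectivity = c(0.3, 0.4))
  t1_mm <- (b[2] - b[1]) * g$axial_pixel_pitch / g$refractive_index / 1000
  expect_equal(a2[1 + b[2]], 0.4 * exp(-2 * mus[1] * t1_mm),
               tolerance = 1e-12)

  expect_error(simulate_ascan(c(100, 50), 1, g), "increasing")
  expect_error(simulate_ascan(c(10, 100), -1, g), ">= 0")
})

test_that("log A-scan intensity is piecewise linear with slope -2 muA", {
  g <- small_geom(n_depth = 500)
  mus <- c(3, 1, 2, 1.5)
  b <- c(20, 120, 220, 320, 450)
  a <- simulate_ascan(b, mus, g, reflectivity = c(0.3, 0.2, 0.25, 0.15))
  mmps <- g$axial_pixel_pitch / g$refractive_index / 1000
  for (l in 1:4) {
    idx <- (b[l] + 1):(b[l + 1] - 1)     # 0-based samples within layer
    z <- idx * mmps
    fit <- lm(log(a[idx + 1]) ~ z)
    expect_lt(max(abs(residuals(fit))), 1e-9)
    expect_equal(unname(coef(fit)[2]), -2 * mus[l], tolerance = 1e-9)
  }
})

test_that("speckle is unit-mean: averaged A-scans converge to the profile", {
  g <- scan_geometry(a_lines_per_bscan = 8, n_bscans = 1,
                     n_depth_samples = 200)
  clean <- simulate_ascan(c(5, 180), 1.5, g, reflectivity = 0.5)
  set.seed(101)
  n <- 10000
  acc <- rowMeans(replicate(n, simulate_ascan(c(5, 180), 1.5, g,
                                              reflectivity = 0.5,
                                              speckle = "exponential")))
  probe <- c(10, 50, 100, 150)   # depth samples well inside the layer
  rel <- abs(acc[probe] - clean[probe]) / clean[probe]
  expect_true(all(rel < 3 / sqrt(n)))
})

test_that("volume simulation is bit-reproducible under a fixed seed", {
  g <- small_geom(a_lines = 90, n_bscans = 3)
  ph <- phantom_spec(seed = 33)
  s1 <- simulate_volume(ph, g)
  s2 <- simulate_volume(ph, g)
  expect_identical(s1$volume$data, s2$volume$data)
  expect_identical(s1$truth$top, s2$truth$top)
  s3 <- simulate_volume(phantom_spec(seed = 34), g)
  expect_false(identical(s1$volume$data, s3$volume$data))
})

test_that("ground truth is consistent with the rendered volume", {
  g <- small_geom(a_lines = 120, n_bscans = 3)
  sim <- simulate_volume(phantom_spec(seed = 2), g)
  tr <- sim$truth
  # mask voxel count equals the summed band heights
  expect_equal(sum(tr$wall_mask), sum(tr$bottom - tr$top))
  # boundaries ordered and inside the depth range
  expect_true(all(tr$top < tr$bottom))
  expect_true(all(tr$bottom <= g$n_depth_samples))
  for (l in seq_along(tr$layer_bounds)[-1])
    expect_true(all(tr$layer_bounds[[l]] >= tr$layer_bounds[[l - 1]]))
  # linear intensities are non-negative
  expect_gte(min(sim$volume$data), 0)
})

test_that("a circularly symmetric phantom has a constant top boundary", {
  g <- small_geom(a_lines = 90, n_bscans = 2)
  sim <- simulate_volume(quiet_phantom(seed = 5), g)
  expect_equal(length(unique(as.vector(sim$truth$top))), 1L)
})

test_that("an oversized wall raises an explicit depth-range error", {
  g <- small_geom(n_depth = 120)
  ph <- phantom_spec(layers = make_layers(c(600, 100, 100, 300),
                                          c(2, 1, 1, 2)), seed = 1)
  expect_error(simulate_volume(ph, g), "n_depth_samples")
})

test_that("detachment gaps displace the top boundary outward", {
  g <- small_geom(a_lines = 240, n_bscans = 2)
  ph <- quiet_phantom(seed = 9)
  ph$detachment <- list(n_gaps = 1L, angular_width = 40,
                        max_radial_offset = 120)
  sim <- simulate_volume(ph, g)
  tr <- sim$truth
  expect_true(any(tr$detached))
  expect_gt(mean(tr$top[tr$detached]), mean(tr$top[!tr$detached]))
  # gap width matches the configured angular span
  expect_equal(mean(tr$detached), 40 / 360, tolerance = 0.25)
})

test_that("a study yields one volume per mouse per day with scaled truth", {
  g <- small_geom(a_lines = 60, n_bscans = 2)
  des <- study_design(n_per_group = 3, seed = 7)
  st <- simulate_study(des, phantom_spec(), colitis_effect(), g,
                       render = "truth", session_sd = 0)
  expect_length(st, 18)
  expect_equal(sort(unique(vapply(st, `[[`, numeric(1), "day"))),
               c(0, 9, 24))

  mean_th <- function(grp, day) {
    sel <- Filter(function(m) m$group == grp && m$day == day, st)
    mean(vapply(sel, function(m) mean(m$truth$thickness_um), numeric(1)))
  }
  # challenged day 9 is 1.5x its own baseline; controls are flat
  expect_equal(mean_th("challenged", 9) / mean_th("challenged", 0), 1.5,
               tolerance = 0.02)
  expect_equal(mean_th("unchallenged", 9) / mean_th("unchallenged", 0), 1,
               tolerance = 0.02)
})

test_that("adding a mouse does not perturb existing mice's draws", {
  g <- small_geom(a_lines = 60, n_bscans = 2)
  des3 <- study_design(n_per_group = 3, seed = 7)
  des4 <- study_design(n_per_group = 4, seed = 7)
  st3 <- simulate_study(des3, phantom_spec(), colitis_effect(), g, "truth")
  st4 <- simulate_study(des4, phantom_spec(), colitis_effect(), g, "truth")
  key <- function(m) paste(m$mouse, m$group, m$day)
  k3 <- vapply(st3, key, character(1))
  k4 <- vapply(st4, key, character(1))
  for (k in k3) {
    i3 <- match(k, k3); i4 <- match(k, k4)
    expect_identical(st3[[i3]]$truth$top, st4[[i4]]$truth$top)
  }
})

test_that("effect schedules validate the baseline", {
  expect_error(colitis_effect(list("0" = c(thickness = 1.2,
                                           attenuation = 1))), "baseline")
  expect_error(colitis_effect(list("0" = c(thickness = 1, attenuation = 1),
                                   "9" = c(thickness = -1,
                                           attenuation = 0.5))), "> 0")
})
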