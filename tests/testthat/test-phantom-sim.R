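test_that("vessel scenes are deterministic in the seed and differ across seeds", {
  s1 <- make_vessel_scene(0, n_vessels = 5, fov = c(1.1, 1.0))
  s2 <- make_vessel_scene(0, n_vessels = 5, fov = c(1.1, 1.0))
  s3 <- make_vessel_scene(1, n_vessels = 5, fov = c(1.1, 1.0))
  expect_identical(s1, s2)
  expect_false(identical(s1$vessels[[1]]$points, s3$vessels[[1]]$points))
  expect_error(make_vessel_scene(0, fov = c(-1, 1)), "invalid geometry")
})

test_that("rendered scenes keep vessel coverage between 1% and 60%", {
  for (seed in c(0, 7, 19)) {
    sc <- make_vessel_scene(seed, n_vessels = 6)
    r <- render_scene(sc, scale_um = 2)
    frac <- mean(r$amplitude > sc$background_level + 0.05)  # brute-force count
    expect_gte(frac, 0.01)
    expect_lte(frac, 0.60)
    expect_true(all(r$amplitude >= 0 & r$amplitude <= 1))
  }
})

test_that("line trajectories: zero jitter, pure lag, determinism, fold-over", {
  geo <- scan_geometry()
  grid <- seq(0, geo$fov_x_mm, length.out = geo$n_fast)
  expect_identical(line_trajectory(geo, zero_jitter(), 3, "forward"), grid)
  expect_equal(line_trajectory(geo, zero_jitter(), 3, "backward"), rev(grid),
               tolerance = 1e-15)
  # constant lag: reversed grid shifted by lag * fov_x
  jc <- jitter_model(phase_lag_mean = 0.004, phase_lag_sd = 0,
                     distortion_coeffs = 0, drift_amplitude = 0)
  bk <- line_trajectory(geo, jc, 5, "backward")
  expect_equal(abs(bk - rev(grid)), rep(0.004 * geo$fov_x_mm, geo$n_fast),
               tolerance = 1e-12)
  # same seed, same line -> identical realization
  jr <- jitter_model(seed = 42)
  expect_identical(line_trajectory(geo, jr, 9, "backward"),
                   line_trajectory(geo, jr, 9, "backward"))
  # an excessive warp coefficient folds the trajectory
  jbad <- jitter_model(phase_lag_sd = 0, distortion_coeffs = 0.5)
  expect_error(line_trajectory(geo, jbad, 1, "backward"), "invalid jitter")
  expect_error(line_trajectory(geo, jr, geo$n_lines, "backward"), "outside")
})

test_that("zero-jitter bidirectional scan equals row-matched unidirectional scan", {
  sc <- fixture_scene()
  geo_b <- scan_geometry(y_step_um = 4, mode = "bidirectional")
  geo_u <- scan_geometry(y_step_um = 2, mode = "unidirectional")
  ref <- render_scene(sc, 1, blur_fwhm_um = geo_b$psf_lateral_fwhm_um)
  b <- simulate_acquisition(sc, geo_b, zero_jitter(), noise_sd = 0, reference = ref)
  u <- simulate_acquisition(sc, geo_u, zero_jitter(), noise_sd = 0, reference = ref)
  expect_identical(dim(b), dim(u))
  expect_lt(max(abs(b - u)), 1e-9)
})

test_that("doubling the slow-axis step halves the number of lines", {
  g4 <- scan_geometry(y_step_um = 4)
  g8 <- scan_geometry(y_step_um = 8)
  expect_identical(g4$n_lines, 2L * g8$n_lines)
  sc <- fixture_scene()
  ref <- render_scene(sc, 1, blur_fwhm_um = g4$psf_lateral_fwhm_um)
  i4 <- simulate_acquisition(sc, g4, zero_jitter(), noise_sd = 0, reference = ref)
  i8 <- simulate_acquisition(sc, g8, zero_jitter(), noise_sd = 0, reference = ref)
  expect_identical(nrow(i4), 2L * nrow(i8))
})

test_that("cross-correlation oracle recovers a constant injected lag within 1 px", {
  sc <- fixture_scene()
  geo <- scan_geometry()
  jit <- jitter_model(phase_lag_mean = 0.008, phase_lag_sd = 0,
                      distortion_coeffs = 0, drift_amplitude = 0)
  ref <- render_scene(sc, 1, blur_fwhm_um = geo$psf_lateral_fwhm_um)
  img <- simulate_acquisition(sc, geo, jit, noise_sd = 0, reference = ref)
  clean <- simulate_acquisition(sc, geo, zero_jitter(), noise_sd = 0, reference = ref)
  px <- geo$fov_x_mm / (geo$n_fast - 1)
  lag_px <- 0.008 * geo$fov_x_mm / px                 # ~2 px
  back_rows <- which(attr(img, "jitter_record")$direction == "backward")
  for (r in back_rows[seq(1, length(back_rows), by = 25)]) {
    a <- img[r, ]; b <- clean[r, ]
    if (sd(a) < 1e-3) next                            # featureless line
    cors <- vapply(-6:6, function(sh) {
      ia <- max(1, 1 + sh):min(length(a), length(a) + sh)
      suppressWarnings(cor(a[ia], b[ia - sh]))
    }, numeric(1))
    expect_lte(abs((-6:6)[which.max(cors)] - lag_px), 1)
  }
})

test_that("paired datasets are byte-identical under a fixed seed", {
  geo <- scan_geometry()
  d1 <- generate_paired_dataset(3, geo, jitter_model(), seed = 7, crop_size = 64)
  d2 <- generate_paired_dataset(3, geo, jitter_model(), seed = 7, crop_size = 64)
  expect_identical(d1, d2)
  d3 <- generate_paired_dataset(3, geo, jitter_model(), seed = 8, crop_size = 64)
  expect_false(identical(d1$pairs[[1]]$input_img, d3$pairs[[1]]$input_img))
})

test_that("zero jitter gives SSIM 1 pairs; default jitter is detectable", {
  z <- fixture_zero_dataset()
  sz <- vapply(z$pairs, function(p) ssim(p$input_img, p$target_img), numeric(1))
  expect_equal(mean(sz), 1, tolerance = 1e-6)
  d <- fixture_dataset()
  sd_ <- vapply(d$pairs, function(p) ssim(p$input_img, p$target_img), numeric(1))
  expect_lt(mean(sd_), 0.99)
})

test_that("image similarity degrades monotonically with the mean phase lag", {
  geo <- scan_geometry()
  lags <- c(0, 0.002, 0.005, 0.01)
  mean_ssim <- vapply(lags, function(lg) {
    jit <- jitter_model(phase_lag_mean = lg, phase_lag_sd = 0,
                        distortion_coeffs = 0, drift_amplitude = 0)
    ds <- generate_paired_dataset(4, geo, jit, seed = 55, crop_size = 64,
                                  noise_sd = 0)
    mean(vapply(ds$pairs, function(p) ssim(p$input_img, p$target_img), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_ssim) <= 1e-9))
})

test_that("theoretical resolution formulas: identities and scaling", {
  expect_equal(theoretical_lateral_resolution(0.51, 510), 0.51, tolerance = 1e-12)
  expect_equal(theoretical_lateral_resolution(0.016, 532),
               2 * theoretical_lateral_resolution(0.032, 532), tolerance = 1e-12)
  expect_equal(theoretical_axial_resolution(40, 0.60),
               theoretical_axial_resolution(20, 0.60) / 2, tolerance = 1e-12)
  expect_equal(theoretical_axial_resolution(20, 1.20),
               theoretical_axial_resolution(20, 0.60) / 2, tolerance = 1e-12)
  expect_error(theoretical_lateral_resolution(-0.1, 532))
  expect_error(theoretical_lateral_resolution(0.03, -5))
  expect_error(theoretical_axial_resolution(20, 3))
})
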