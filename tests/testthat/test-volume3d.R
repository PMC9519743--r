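make_toy_volume <- function(seed = 51, nz = 5, nx = 6, ny = 7) {
  set.seed(seed)
  as_ascan_volume(array(runif(nz * nx * ny), c(nz, nx, ny)), c(20, 4, 4))
}

test_that("slice-wise correction conserves shape and is plane-independent", {
  ck <- fixture_identity_generator()
  sc <- fixture_scene()
  geo <- scan_geometry(n_depth = 8L)
  vol <- simulate_acquisition(sc, geo, jitter_model(), noise_sd = 0)
  out <- correct_volume(vol, ck)
  expect_identical(dim(out$amplitudes), dim(vol$amplitudes))
  expect_identical(out$spacing_um, vol$spacing_um)
  # z-planes are processed independently: permuting planes commutes with
  # correction
  perm <- c(3, 1, 2, 5, 4, 6, 8, 7)
  vperm <- as_ascan_volume(vol$amplitudes[perm, , ], vol$spacing_um)
  operm <- correct_volume(vperm, ck)
  expect_equal(operm$amplitudes, out$amplitudes[perm, , ], tolerance = 1e-12)
  expect_error(correct_volume(as_ascan_volume(array(0, c(0, 2, 2)), c(1, 1, 1)), ck))
})

test_that("an identity-calibrated generator leaves volumes nearly unchanged", {
  ck <- fixture_identity_generator()
  sc <- fixture_scene()
  geo <- scan_geometry(n_depth = 6L)
  vol <- simulate_acquisition(sc, geo, zero_jitter(), noise_sd = 0)
  out <- correct_volume(vol, ck)
  expect_lt(mean(abs(out$amplitudes - vol$amplitudes)), 0.02)
})

test_that("depth encoding: argmax oracle, tie-breaking, endpoint hues", {
  vol <- make_toy_volume()
  enc <- depth_encode(vol)
  d <- dim(vol$amplitudes)
  for (x in seq_len(d[2])) for (y in seq_len(d[3]))
    expect_identical(enc$depth_index[y, x], which.max(vol$amplitudes[, x, y]))
  # ties break toward the shallowest depth
  vt <- array(0, c(3, 2, 2)); vt[1, , ] <- 0.5; vt[3, , ] <- 0.5
  enc_t <- depth_encode(as_ascan_volume(vt, c(1, 1, 1)))
  expect_true(all(enc_t$depth_index == 1L))
  # single bright plane -> uniform hue where amplitude > 0
  vk <- array(0, c(4, 3, 3)); vk[2, , ] <- matrix(runif(9, 0.5, 1), 3)
  enc_k <- depth_encode(as_ascan_volume(vk, c(1, 1, 1)))
  expect_true(all(enc_k$depth_index == 2L))
  # two-point toy volume: maxima at the first and last plane map to the
  # colormap endpoints
  v2 <- array(0, c(5, 1, 2)); v2[1, 1, 1] <- 1; v2[5, 1, 2] <- 1
  enc2 <- depth_encode(as_ascan_volume(v2, c(1, 1, 1)), hue_range = c(0.66, 0))
  expect_identical(enc2$depth_index[1, 1], 1L)
  expect_identical(enc2$depth_index[2, 1], 5L)
  expect_error(depth_encode(as_ascan_volume(array(0.1, c(1, 2, 2)), c(1, 1, 1))),
               "n_depth")
})

test_that("depth-encoded brightness equals the normalized MAP", {
  vol <- make_toy_volume(52)
  enc <- depth_encode(vol)
  m <- map_project(vol)
  mn <- (m - min(m)) / (max(m) - min(m))
  expect_equal(enc$map, mn, tolerance = 1e-12)
  v <- apply(enc$rgb, c(1, 2), max)   # HSV value channel
  expect_equal(v, mn, tolerance = 2 / 255)
})

test_that("stitching: identity, constant blend, disjoint copy, gap report", {
  set.seed(53)
  img <- matrix(runif(30 * 40), 30)
  m1 <- stitch_segments(list(list(image = img, offset = c(0, 0))))
  expect_equal(unclass(m1)[, ], img, ignore_attr = TRUE)
  # overlapping constant segments blend to the same constant
  cseg <- matrix(0.6, 20, 20)
  m2 <- stitch_segments(list(list(image = cseg, offset = c(0, 0)),
                             list(image = cseg, offset = c(0, 10))))
  expect_true(all(abs(m2 - 0.6) < 1e-12))
  expect_identical(attr(m2, "n_gap_pixels"), 0L)
  # non-overlapping layout is an exact copy
  a <- matrix(runif(100), 10); b <- matrix(runif(100), 10)
  m3 <- suppressMessages(stitch_segments(list(list(image = a, offset = c(0, 0)),
                                              list(image = b, offset = c(10, 10)))))
  expect_equal(m3[1:10, 1:10], a, ignore_attr = TRUE)
  expect_equal(m3[11:20, 11:20], b, ignore_attr = TRUE)
  expect_identical(attr(m3, "n_gap_pixels"), 200L)
  expect_true(all(m3[1:10, 11:20] == 0))
})
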