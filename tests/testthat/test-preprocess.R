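test_that("MAP projection matches a triple-loop oracle and handles edge cases", {
  set.seed(11)
  vol <- as_ascan_volume(array(runif(4 * 5 * 6), c(4, 5, 6)), c(10, 4, 4))
  img <- map_project(vol)
  expect_identical(dim(img), c(6L, 5L))
  for (x in 1:5) for (y in 1:6) {
    mx <- -Inf
    for (z in 1:4) mx <- max(mx, vol$amplitudes[z, x, y])
    expect_identical(img[y, x], mx)
  }
  # single nonzero voxel
  v2 <- array(0, c(3, 4, 5)); v2[2, 3, 4] <- 0.7
  m2 <- map_project(as_ascan_volume(v2, c(1, 1, 1)))
  expect_identical(m2[4, 3], 0.7)
  expect_identical(sum(m2), 0.7)
  # constant volume
  m3 <- map_project(as_ascan_volume(array(0.3, c(2, 3, 3)), c(1, 1, 1)))
  expect_true(all(m3 == 0.3))
})

test_that("angular correction: small-angle identity, round trip, constants", {
  geo_small <- scan_geometry(galvo_amplitude_deg = 1e-4 * 180 / pi)
  img <- matrix(0, 6, 250)
  for (r in 1:6) img[r, ] <- 0.5 + 0.3 * sin(seq(0, 6, length.out = 250) + r)
  expect_lt(max(abs(angular_correction(img, geo_small) - img)), 1e-6)
  # forward-distort then correct recovers the original
  geo <- scan_geometry(galvo_amplitude_deg = 12)
  rt <- angular_correction(angular_distort(img, geo), geo)
  expect_lt(max(abs(rt - img)), 1e-3)
  cst <- matrix(0.42, 3, 250)
  expect_equal(angular_correction(cst, geo), cst, tolerance = 1e-12)
  expect_error(angular_correction(matrix(0, 3, 100), geo), "n_fast")
})

test_that("normalization: minmax mapping, constants, percentile clipping", {
  expect_equal(normalize_image(matrix(c(0, 5, 10), 1)), matrix(c(0, 0.5, 1), 1),
               tolerance = 1e-12)
  expect_true(all(normalize_image(matrix(0.7, 4, 4)) == 0))
  set.seed(12)
  img <- matrix(runif(400), 20)
  img[7, 7] <- 50                      # hot outlier
  out <- normalize_image(img, "percentile")
  expect_identical(out[7, 7], 1)
  # brute-force percentile oracle on the sorted values
  q <- quantile(img, c(0.001, 0.999), names = FALSE, type = 7)
  clipped <- pmin(pmax(img, q[1]), q[2])
  oracle <- (clipped - min(clipped)) / (max(clipped) - min(clipped))
  expect_equal(out, oracle, tolerance = 1e-12)
  bad <- img; bad[1, 1] <- NaN
  expect_error(normalize_image(bad), "finite")
})

test_that("tiling: counts, offsets and exact reassembly", {
  set.seed(13)
  img <- matrix(runif(250 * 250), 250)
  t1 <- crop_tiles(img, 192)
  expect_length(t1, 1L)
  expect_identical(t1[[1]]$offset, c(0L, 0L))
  img2 <- matrix(runif(384 * 384), 384)
  t4 <- crop_tiles(img2, 192)
  expect_length(t4, 4L)
  canvas <- matrix(NA_real_, 384, 384)
  for (tl in t4)
    canvas[tl$offset[1] + 1:192, tl$offset[2] + 1:192] <- tl$tile
  expect_identical(canvas, img2)
  expect_error(crop_tiles(matrix(0, 100, 100), 192), "smaller")
})

test_that("dataset splits obey the ceiling rule and partition the indices", {
  sp <- split_dataset(1154, seed = 1)
  expect_length(sp$test, 231L)
  expect_length(sp$validation, 93L)
  expect_length(sp$train, 830L)
  sp10 <- split_dataset(10, seed = 2)
  expect_identical(lengths(sp10[c("test", "validation", "train")]),
                   c(test = 2L, validation = 1L, train = 7L))
  expect_identical(split_dataset(57, seed = 9), split_dataset(57, seed = 9))
  for (n in c(10, 37, 200)) {
    sp_n <- split_dataset(n, seed = n)
    all_idx <- c(sp_n$train, sp_n$validation, sp_n$test)
    expect_identical(sort(all_idx), seq_len(n))   # disjoint and covering
    expect_identical(length(sp_n$test), as.integer(ceiling(0.2 * n)))
    expect_identical(length(sp_n$validation),
                     as.integer(ceiling(0.1 * (n - length(sp_n$test)))))
  }
  expect_error(split_dataset(5), ">= 10")
  expect_error(split_dataset(20, test_frac = 1.2), "fractions")
})
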