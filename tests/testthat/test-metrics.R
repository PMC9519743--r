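test_that("SSIM matches a naive sliding-window oracle on random pairs", {
  set.seed(1)
  for (i in 1:4) {
    a <- matrix(runif(32 * 32), 32)
    b <- if (i %% 2 == 0) matrix(runif(32 * 32), 32)
         else pmin(pmax(a + rnorm(1024, 0, 0.1), 0), 1)
    expect_equal(ssim(a, b), naive_ssim(a, b), tolerance = 1e-6)
  }
})

test_that("SSIM is 1 on identical images and negative for inverted checkerboards", {
  set.seed(2)
  x <- matrix(runif(24 * 24), 24)
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  chk <- outer(1:32, 1:32, function(i, j) (i + j) %% 2)
  expect_lt(ssim(chk, 1 - chk), 0)
  expect_equal(ssim(chk, 1 - chk), naive_ssim(chk, 1 - chk), tolerance = 1e-6)
  expect_error(ssim(x, matrix(0, 3, 3)), "mismatch")
})

smooth_fixture <- function() {
  outer(seq(0, 1, length.out = 192), seq(0, 1, length.out = 192),
        function(u, v) 0.5 + 0.4 * sin(4 * u) * cos(3 * v))
}

test_that("MS-SSIM: self-similarity, degenerate single scale, noise behavior", {
  set.seed(3)
  x <- matrix(runif(192 * 192), 192)
  expect_equal(ms_ssim(x, x), 1, tolerance = 1e-9)
  a <- matrix(runif(64 * 64), 64)
  b <- pmin(pmax(a + rnorm(64 * 64, 0, 0.15), 0), 1)
  expect_equal(ms_ssim(a, b, n_scales = 1L), ssim(a, b), tolerance = 1e-12)
  # smooth image + high-frequency noise: coarse scales forgive the noise
  base <- smooth_fixture()
  noisy <- pmin(pmax(base + matrix(rnorm(192 * 192, 0, 0.05), 192), 0), 1)
  expect_gte(ms_ssim(base, noisy), ssim(base, noisy))
})

test_that("PSNR closed forms, symmetry and infinite sentinel", {
  a <- matrix(0.5, 20, 20)
  expect_equal(psnr(a, a + 0.1), 20, tolerance = 1e-9)
  expect_equal(psnr(a, a + 0.01), 40, tolerance = 1e-9)
  set.seed(4)
  x <- matrix(runif(100), 10); y <- matrix(runif(100), 10)
  expect_identical(psnr(x, y), psnr(y, x))
  expect_identical(psnr(x, x), Inf)
})

test_that("MAE and MSE match direct loops and constant-offset identities", {
  set.seed(5)
  a <- matrix(runif(9), 3); b <- matrix(runif(9), 3)
  m1 <- 0; m2 <- 0
  for (i in 1:3) for (j in 1:3) {
    m1 <- m1 + abs(a[i, j] - b[i, j]); m2 <- m2 + (a[i, j] - b[i, j])^2
  }
  expect_equal(mae(a, b), m1 / 9, tolerance = 1e-12)
  expect_equal(mse(a, b), m2 / 9, tolerance = 1e-12)
  expect_equal(mae(a, a + 0.3), 0.3, tolerance = 1e-12)
  expect_equal(mse(a, a + 0.3), 0.09, tolerance = 1e-12)
  expect_identical(c(mae(a, a), mse(a, a)), c(0, 0))
})

test_that("blur score rises under smoothing, is transpose-symmetric, flat -> 0", {
  chk <- outer(1:48, 1:48, function(i, j) (i %/% 3 + j %/% 3) %% 2)
  blurred <- biraster:::blur_axis(biraster:::blur_axis(chk, "x"), "y")   # 9x9 mean filter
  expect_lt(blur_score(chk), blur_score(blurred))
  set.seed(6)
  x <- matrix(runif(30 * 30), 30)
  expect_equal(blur_score(x), blur_score(t(x)), tolerance = 1e-12)
  expect_warning(v <- blur_score(matrix(0.4, 20, 20)), "flat")
  expect_identical(v, 0)
})

test_that("BAD is the absolute blur difference: zero on identity, symmetric", {
  set.seed(7)
  sharp <- matrix(runif(40 * 40), 40)
  soft <- biraster:::blur_axis(biraster:::blur_axis(sharp, "x"), "y")
  expect_identical(bad(sharp, sharp), 0)
  expect_equal(bad(sharp, soft), bad(soft, sharp), tolerance = 1e-15)
  expect_equal(bad(sharp, soft), abs(blur_score(sharp) - blur_score(soft)),
               tolerance = 1e-15)
})

test_that("baseline filters: median impulse removal, constants, range, errors", {
  flat <- matrix(0.2, 16, 16)
  expect_equal(baseline_filter(flat, "median"), flat, tolerance = 1e-9)
  imp <- flat; imp[8, 8] <- 1
  out <- baseline_filter(imp, "median", window = 3)
  # oracle: median of the 3x3 window around the impulse is the background
  expect_equal(out[8, 8], median(imp[7:9, 7:9]), tolerance = 1e-9)
  expect_equal(out[8, 8], 0.2, tolerance = 1e-9)
  set.seed(8)
  x <- matrix(runif(32 * 32), 32)
  for (m in c("bicubic", "bilateral", "median")) {
    y <- baseline_filter(x, m)
    expect_identical(dim(y), dim(x))
    expect_true(all(y >= 0 & y <= 1))
  }
  expect_error(baseline_filter(x, "sharpen"))
})

test_that("evaluate_set: perfect pairs, single-pair SD, brute-force mean/sd", {
  ds <- fixture_zero_dataset()
  # noiseless background-only crops are flat: blur warns and returns 0
  rep0 <- suppressWarnings(evaluate_set(ds$pairs[1:3]))
  s <- rep0$summary
  expect_equal(s$mean[s$metric == "ssim"], 1, tolerance = 1e-9)
  expect_equal(s$mean[s$metric == "mae"], 0, tolerance = 1e-12)
  expect_true(all(!is.finite(rep0$per_image$psnr)))  # identical pairs
  expect_identical(rep0$n_psnr_excluded, 3L)

  ds2 <- fixture_dataset()
  rep1 <- evaluate_set(ds2$pairs[1], list(median = function(x) baseline_filter(x, "median")))
  expect_true(all(rep1$summary$sd == 0))
  rep2 <- evaluate_set(ds2$pairs[1:4])
  pi_ssim <- rep2$per_image$ssim
  expect_equal(rep2$summary$mean[rep2$summary$metric == "ssim"], mean(pi_ssim),
               tolerance = 1e-12)
  expect_equal(rep2$summary$sd[rep2$summary$metric == "ssim"], sd(pi_ssim),
               tolerance = 1e-12)
  expect_setequal(unique(rep2$summary$metric),
                  c("ssim", "ms_ssim", "psnr", "mae", "mse", "bad"))
})
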