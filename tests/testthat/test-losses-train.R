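test_that("generator loss reproduces its closed-form worked examples", {
  img <- matrix(runif(64), 8)
  # perfect reconstruction, no adversarial term
  expect_equal(generator_loss(0.7, img, img, loss_weights(lambda = 0, nu = 0.6)),
               0, tolerance = 1e-12)
  # pure adversarial term at D = 0.5
  expect_equal(generator_loss(matrix(0.5, 4, 4), img, img,
                              loss_weights(lambda = 1, nu = 0)),
               -log(0.5), tolerance = 1e-9)
  # pure MAE on constant images
  a <- matrix(0.2, 8, 8); b <- matrix(0.5, 8, 8)
  expect_equal(generator_loss(0.5, a, b, loss_weights(lambda = 0, nu = 1)),
               0.3, tolerance = 1e-12)
  expect_error(loss_weights(lambda = 0.6, nu = 0.6), "exceed")
  expect_error(loss_weights(lambda = -0.1, nu = 0.5), "non-negative")
  # the three coefficients partition unity
  w <- loss_weights(0.05, 0.6)
  expect_equal(w$lambda + w$nu + w$ssim, 1, tolerance = 1e-15)
})

test_that("discriminator loss: symmetric case, perfect-D limit, identity", {
  expect_equal(discriminator_loss(0.5, 0.5), 2 * log(2), tolerance = 1e-9)
  expect_lt(discriminator_loss(1 - 1e-7, 1e-7), 1e-5)
  set.seed(31)
  dr <- runif(10, 0.2, 0.8); df <- runif(10, 0.2, 0.8)
  expect_equal(discriminator_loss(dr, df), discriminator_loss(1 - df, 1 - dr),
               tolerance = 1e-12)
})

test_that("the SSIM loss gradient agrees with numerical differentiation", {
  set.seed(32)
  y <- matrix(runif(20 * 20), 20)
  p <- matrix(runif(20 * 20), 20)
  sg <- biraster:::ssim_with_grad(y, p)
  expect_equal(sg$value, ssim(p, y), tolerance = 1e-12)
  eps <- 1e-6
  for (j in sample(length(p), 6)) {
    p2 <- p; p2[j] <- p2[j] + eps
    p3 <- p; p3[j] <- p3[j] - eps
    num <- (ssim(p2, y) - ssim(p3, y)) / (2 * eps)
    expect_equal(sg$grad[j], num, tolerance = 1e-4)
  }
})

test_that("training is reproducible and checkpoints the best validation SSIM", {
  ds <- fixture_dataset()
  sp <- list(train = 1:6, validation = 7:8)
  run_once <- function() {
    gen <- tiny_generator(seed = 41)
    disc <- tiny_discriminator(seed = 42)
    train_gan(gen, disc, ds, sp, train_config(epochs_max = 3, batch_size = 3,
                                              seed = 43))
  }
  ck1 <- run_once()
  ck2 <- run_once()
  expect_equal(ck1$log$g_loss[1], ck2$log$g_loss[1], tolerance = 1e-6)
  expect_equal(ck1$log$d_loss[1], ck2$log$d_loss[1], tolerance = 1e-6)
  # best-so-far is monotone and the checkpoint is the argmax of the log
  expect_gte(ck1$best_val_ssim, ck1$log$val_ssim[1])
  expect_equal(ck1$best_val_ssim, max(ck1$log$val_ssim), tolerance = 1e-12)
  expect_identical(ck1$best_epoch, which.max(ck1$log$val_ssim))
  expect_error(train_gan(tiny_generator(), tiny_discriminator(), ds,
                         list(train = integer(), validation = 7:8),
                         train_config(epochs_max = 1)),
               "empty")
})

test_that("identity calibration: training on zero-jitter pairs approximates identity", {
  ck <- fixture_identity_generator()
  held_out <- generate_paired_dataset(4, scan_geometry(), zero_jitter(),
                                      seed = 91, crop_size = 32, noise_sd = 0)
  mad <- mean(vapply(held_out$pairs, function(p)
    mean(abs(infer(ck, p$input_img) - p$input_img)), numeric(1)))
  expect_lt(mad, 0.02)
})

test_that("inference pads transparently and batches equal single calls", {
  gen <- tiny_generator()
  set.seed(33)
  x <- matrix(runif(250 * 250), 250)   # not a multiple of 8
  y <- infer(gen, x)
  expect_identical(dim(y), dim(x))
  expect_true(all(y >= 0 & y <= 1))
  imgs <- lapply(1:3, function(i) matrix(runif(64 * 64), 64))
  batch <- infer(gen, imgs)
  singles <- lapply(imgs, function(im) infer(gen, im))
  for (i in 1:3) expect_equal(batch[[i]], singles[[i]], tolerance = 1e-6)
})
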