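# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

fixture_scene <- function() memo("scene", make_vessel_scene(3, n_vessels = 5))

fixture_geometry <- function() scan_geometry()

# small paired dataset with default jitter, 64 px crops
fixture_dataset <- function() memo("dataset",
  generate_paired_dataset(8, scan_geometry(), jitter_model(), seed = 21,
                          crop_size = 64))

# noiseless zero-jitter dataset
fixture_zero_dataset <- function() memo("zero_dataset",
  generate_paired_dataset(6, scan_geometry(), zero_jitter(), seed = 22,
                          crop_size = 64, noise_sd = 0))

tiny_generator <- function(seed = 7)
  build_generator(generator_config(base_channels = 6, growth_rate = 4,
                                   dense_layers_per_block = 2, init_seed = seed))

tiny_discriminator <- function(seed = 8)
  build_discriminator(discriminator_config(base_width = 8, init_seed = seed))

# a generator trained briefly on zero-jitter (input == target) pairs so its
# output approximates the identity; reused by the model and volume tests
fixture_identity_generator <- function() memo("identity_gen", {
  ds <- generate_paired_dataset(24, scan_geometry(), zero_jitter(), seed = 31,
                                crop_size = 32, noise_sd = 0)
  sp <- split_dataset(24, seed = 32)
  gen <- tiny_generator(seed = 33)
  tc <- train_config(epochs_max = 40, batch_size = 8, lambda = 0, nu = 0.7,
                     lr_g = 2e-3, seed = 34)
  train_gan(gen, NULL, ds, sp, tc)
})

# naive sliding-window SSIM used as an independent oracle (direct loops,
# symmetric padding, Gaussian weights)
naive_ssim <- function(a, b, data_range = 1, sd = 1.5, radius = 5L) {
  k1 <- exp(-(-radius:radius)^2 / (2 * sd^2))
  w <- outer(k1, k1); w <- w / sum(w)
  C1 <- (0.01 * data_range)^2; C2 <- (0.03 * data_range)^2
  H <- nrow(a); W <- ncol(a)
  sym <- function(i, n) { i[i < 1] <- 1 - i[i < 1]; i[i > n] <- 2 * n + 1 - i[i > n]; i }
  total <- 0
  for (y in seq_len(H)) for (x in seq_len(W)) {
    ri <- sym(y + (-radius:radius), H)
    ci <- sym(x + (-radius:radius), W)
    pa <- a[ri, ci]; pb <- b[ri, ci]
    ma <- sum(w * pa); mb <- sum(w * pb)
    va <- sum(w * pa^2) - ma^2; vb <- sum(w * pb^2) - mb^2
    vab <- sum(w * pa * pb) - ma * mb
    total <- total + ((2 * ma * mb + C1) * (2 * vab + C2)) /
      ((ma^2 + mb^2 + C1) * (va + vb + C2))
  }
  total / (H * W)
}
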