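test_that("median pooling matches a blockwise sort oracle", {
  expect_true(all(median_pool(matrix(0.4, 8, 8), 2) == 0.4))
  blk <- matrix(c(1, 3, 2, 100), 2)      # column-major: [1,2;3,100]
  expect_identical(median_pool(blk, 2), matrix(2.5, 1, 1))
  set.seed(21)
  x <- matrix(runif(64), 8)
  p <- median_pool(x, 2)
  for (i in 1:4) for (j in 1:4) {
    v <- sort(as.vector(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]))
    expect_identical(p[i, j], (v[2] + v[3]) / 2)
  }
  p4 <- median_pool(x, 4)
  for (i in 1:2) for (j in 1:2) {
    v <- sort(as.vector(x[(4 * i - 3):(4 * i), (4 * j - 3):(4 * j)]))
    expect_identical(p4[i, j], (v[8] + v[9]) / 2)
  }
  expect_error(median_pool(matrix(0, 7, 8), 2), "divisible")
})

test_that("pixel shuffle: defining rearrangement, bijection, conservation", {
  x <- array(c(1, 2, 3, 4), c(1, 1, 4))       # channels a,b,c,d
  y <- pixel_shuffle(x, 2)
  expect_identical(dim(y), c(2L, 2L, 1L))
  expect_identical(y[, , 1], matrix(c(1, 3, 2, 4), 2))  # [[a,b],[c,d]]
  set.seed(22)
  z <- array(rnorm(6 * 5 * 8 * 2), c(6, 5, 8, 2))
  expect_identical(pixel_unshuffle(pixel_shuffle(z, 2), 2), z)
  expect_identical(length(pixel_shuffle(z, 2)), length(z))
  expect_error(pixel_shuffle(array(0, c(2, 2, 3)), 2), "divisible")
})

test_that("reference configurations hit the target parameter budgets", {
  g <- build_generator(generator_config(init_seed = 1))
  d <- build_discriminator(discriminator_config(init_seed = 1))
  ng <- count_parameters(g)
  nd <- count_parameters(d)
  expect_identical(ng, expected_parameters(generator_config()))
  expect_identical(nd, expected_parameters(discriminator_config()))
  expect_lt(abs(ng - 7.6e6) / 7.6e6, 0.02)
  expect_lt(abs(nd - 1.6e6) / 1.6e6, 0.02)
})

test_that("count_parameters sums single convolutions correctly", {
  net <- biraster:::nn_new()
  xin <- biraster:::nn_input(net)
  net$out <- biraster:::nn_conv(net, xin, 3L, 1L, 8L)     # 3*3*1*8 + 8
  wrap <- structure(list(graph = net, type = "custom"), class = "biraster_net")
  expect_identical(count_parameters(wrap), 80L)
  net2 <- biraster:::nn_new()
  xin2 <- biraster:::nn_input(net2)
  net2$out <- biraster:::nn_conv(net2, xin2, 1L, 16L, 4L) # 16*4 + 4
  wrap2 <- structure(list(graph = net2, type = "custom"), class = "biraster_net")
  expect_identical(count_parameters(wrap2), 68L)
})

test_that("generator is fully convolutional with in-range sigmoid output", {
  gen <- tiny_generator()
  set.seed(23)
  x <- matrix(runif(192 * 192), 192)
  y <- infer(gen, x)
  expect_identical(dim(y), dim(x))
  expect_true(all(y > 0 & y < 1))
  x2 <- matrix(runif(64 * 96), 64)     # non-square multiple of 8
  y2 <- infer(gen, x2)
  expect_identical(dim(y2), dim(x2))
})

test_that("pixel-shuffle decoder leaves constant inputs spatially constant", {
  # constant-initialized weights + constant input must give a constant
  # output: the sub-pixel path introduces no periodic (checkerboard) pattern
  gen <- tiny_generator()
  net <- gen$graph
  for (i in seq_along(net$nodes))
    if (net$nodes[[i]]$op == "conv") {
      net$nodes[[i]]$W[] <- 0.01
      net$nodes[[i]]$b[] <- 0.005
    }
  out <- infer(gen, matrix(0.5, 64, 64))
  expect_lt(diff(range(out)), 1e-12)
})

test_that("discriminator yields a deterministic patch map of (0,1) scores", {
  d <- tiny_discriminator()
  set.seed(24)
  x <- matrix(runif(64 * 64), 64)
  s1 <- biraster:::nn_forward(d$graph, x, keep = FALSE)$out
  s2 <- biraster:::nn_forward(d$graph, x, keep = FALSE)$out
  expect_identical(s1, s2)
  expect_true(all(s1 > 0 & s1 < 1))
  expect_lt(dim(s1)[1], 64)            # strided layers shrink the map
  expect_identical(d$config$n_layers, 5L)
  expect_identical(sum(vapply(d$graph$nodes, function(nd) nd$op == "conv",
                              logical(1))), 5L)
})
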