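# Composite GAN losses. The generator minimizes
#   lambda * (-log D(G(x))) + nu * MAE(y, G(x)) + (1-lambda-nu) * (1 - SSIM(y, G(x)))
# with the three coefficients partitioning unity; the discriminator
# minimizes -[log D(y) + log(1 - D(G(x)))]. Patch-map scores are reduced by
# their mean before the logarithms; scores are clamped at eps = 1e-7.

LOSS_EPS <- 1e-7

#' Generator loss weights
#'
#' `lambda` weights the adversarial term, `nu` the MAE term; the SSIM term
#' receives the remainder `1 - lambda - nu`, which must be non-negative.
#' The defaults (0.05 / 0.60, SSIM 0.35) let the reconstruction terms
#' dominate early training.
#'
#' @param lambda adversarial weight (>= 0).
#' @param nu MAE weight (>= 0), with `lambda + nu <= 1`.
#' @return a `loss_weights` list including the implied `ssim` weight.
#' @export
loss_weights <- function(lambda = 0.05, nu = 0.60) {
  if (lambda < 0 || nu < 0) stop("loss weights must be non-negative")
  if (lambda + nu > 1 + 1e-12)
    stop("lambda + nu must not exceed 1 (the SSIM weight is 1 - lambda - nu)")
  structure(list(lambda = lambda, nu = nu, ssim = 1 - lambda - nu),
            class = "loss_weights")
}

clamp_scores <- function(s) {
  n_bad <- sum(s < LOSS_EPS | s > 1 - LOSS_EPS)
  if (n_bad > 0) message(n_bad, " discriminator score(s) clamped at eps")
  pmin(pmax(s, LOSS_EPS), 1 - LOSS_EPS)
}

#' Composite generator loss
#'
#' @param d_fake discriminator patch scores for the generated image(s),
#'   values in (0, 1); any numeric array.
#' @param pred,target generated image and ground truth, same shape, in
#'   `[0, 1]`.
#' @param weights a [loss_weights()].
#' @return scalar loss.
#' @examples
#' img <- matrix(runif(64), 8)
#' generator_loss(0.5, img, img, loss_weights(lambda = 1, nu = 0))  # -log 0.5
#' @export
generator_loss <- function(d_fake, pred, target, weights = loss_weights()) {
  if (!inherits(weights, "loss_weights")) weights <- do.call(loss_weights, weights)
  adv <- if (weights$lambda > 0) -log(max(mean(clamp_scores(d_fake)), LOSS_EPS)) else 0
  rec <- mean(abs(target - pred))
  ss <- if (weights$ssim > 0) 1 - mean_ssim_any(target, pred) else 0
  weights$lambda * adv + weights$nu * rec + weights$ssim * ss
}

# SSIM averaged over batch samples for matrices or (H,W,C,N) arrays
mean_ssim_any <- function(y, p) {
  if (is.matrix(y)) return(ssim(y, p))
  yb <- as_batch(y); pb <- as_batch(p)
  n <- dim(yb)[4]
  mean(vapply(seq_len(n), function(i) ssim(yb[, , 1, i], pb[, , 1, i]), numeric(1)))
}

#' Discriminator loss
#'
#' Negated value of the adversarial objective so the discriminator is
#' trained by minimization: `-[log mean(d_real) + log(1 - mean(d_fake))]`.
#'
#' @param d_real,d_fake patch scores in (0, 1) for real and generated
#'   images.
#' @return scalar loss.
#' @examples
#' discriminator_loss(0.5, 0.5)  # 2 log 2
#' @export
discriminator_loss <- function(d_real, d_fake) {
  mr <- max(mean(clamp_scores(d_real)), LOSS_EPS)
  mf <- min(mean(clamp_scores(d_fake)), 1 - LOSS_EPS)
  -(log(mr) + log(1 - mf))
}

# SSIM of (y, p) and its exact gradient with respect to p, including the
# adjoint of the symmetric-padded Gaussian window filtering. Verified
# against numerical differentiation in the test suite.
ssim_with_grad <- function(y, p, data_range = 1, sd = 1.5, radius = 5L) {
  k <- gauss_kernel(sd, radius)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  F <- function(m) cpp_sep_filter(m, k)
  Ft <- function(m) cpp_sep_filter_adjoint(m, k)
  mu_p <- F(p); mu_y <- F(y)
  vp <- F(p * p) - mu_p^2
  vy <- F(y * y) - mu_y^2
  vpy <- F(p * y) - mu_p * mu_y
  A1 <- 2 * mu_p * mu_y + C1; B1 <- mu_p^2 + mu_y^2 + C1
  A2 <- 2 * vpy + C2;         B2 <- vp + vy + C2
  S <- (A1 * A2) / (B1 * B2)
  dS_dmu <- 2 * A2 * (mu_y * B1 - mu_p * A1) / (B1^2 * B2)
  dS_dvp <- -S / B2
  dS_dvpy <- 2 * A1 / (B1 * B2)
  N <- length(p)
  grad <- (Ft(dS_dmu) + 2 * p * Ft(dS_dvp) - 2 * Ft(mu_p * dS_dvp) +
             y * Ft(dS_dvpy) - Ft(mu_y * dS_dvpy)) / N
  list(value = mean(S), grad = grad)
}

# value + gradient wrt pred of the full generator loss, given the gradient
# of the adversarial term wrt pred (backpropagated through D separately)
generator_loss_grad <- function(pred, target, weights) {
  d <- dim(pred)
  n_img <- d[4]
  rec_g <- weights$nu * sign(pred - target) / length(pred)
  ss_val <- 0
  ss_g <- array(0, d)
  if (weights$ssim > 0) {
    for (i in seq_len(n_img)) {
      sg <- ssim_with_grad(target[, , 1, i], pred[, , 1, i])
      ss_val <- ss_val + (1 - sg$value) / n_img
      ss_g[, , 1, i] <- -sg$grad / n_img
    }
  }
  list(rec = mean(abs(target - pred)), ssim_term = ss_val,
       grad = rec_g + weights$ssim * ss_g)
}
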