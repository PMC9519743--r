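# Adversarial training: alternating discriminator/generator steps per
# batch, Adam with L2 weight decay, He initialization, and SSIM-based
# checkpointing (the retained generator weights are those of the epoch with
# the best mean validation SSIM). Fully deterministic under the config
# seed on a single CPU.

#' Training configuration
#'
#' Adam settings follow stable pix2pix-style practice (learning rate 2e-4,
#' moments 0.5/0.999) for both networks; training runs for at most
#' `epochs_max` epochs (default cap 200) with one discriminator step per
#' generator step.
#'
#' @param epochs_max maximum number of epochs (<= 200 by default).
#' @param batch_size images per batch.
#' @param lr_g,lr_d Adam learning rates of generator and discriminator.
#' @param beta1,beta2 Adam moment coefficients.
#' @param weight_decay L2 regularization strength.
#' @param lambda,nu generator [loss_weights()].
#' @param seed master seed for initialization and batch shuffling.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs_max = 200L, batch_size = 8L,
                         lr_g = 2e-4, lr_d = 2e-4,
                         beta1 = 0.5, beta2 = 0.999, weight_decay = 1e-5,
                         lambda = 0.05, nu = 0.60, seed = 1L) {
  if (epochs_max < 1L) stop("epochs_max must be >= 1")
  if (lr_g <= 0 || lr_d <= 0) stop("learning rates must be positive")
  structure(list(epochs_max = as.integer(epochs_max),
                 batch_size = as.integer(batch_size),
                 lr_g = lr_g, lr_d = lr_d, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay,
                 weights = loss_weights(lambda, nu), seed = as.integer(seed)),
            class = "train_config")
}

#' Train the MS-FD-U-Net GAN
#'
#' @param generator,discriminator networks from [build_generator()] /
#'   [build_discriminator()]. If `config$weights$lambda == 0` the
#'   discriminator may be `NULL` and only the reconstruction terms are
#'   trained.
#' @param dataset a `paired_dataset` (or plain list of `paired_sample`s).
#' @param split a [split_dataset()] result; training uses `split$train`,
#'   checkpoint selection uses `split$validation`.
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return a `biraster_checkpoint`: the generator with its best-validation
#'   weights, the final discriminator, the per-epoch `log` (g_loss, d_loss,
#'   val_ssim) and `best_epoch`.
#' @export
train_gan <- function(generator, discriminator, dataset, split, config,
                      verbose = FALSE) {
  pairs <- if (inherits(dataset, "paired_dataset")) dataset$pairs else dataset
  if (!length(split$train) || !length(split$validation))
    stop("empty train or validation split")
  w <- config$weights
  use_d <- w$lambda > 0
  if (use_d && is.null(discriminator))
    stop("a discriminator is required when lambda > 0")
  G <- generator$graph
  D <- if (use_d) discriminator$graph else NULL
  opt_g <- adam_new(G, config$lr_g, config$beta1, config$beta2, config$weight_decay)
  opt_d <- if (use_d) adam_new(D, config$lr_d, config$beta1, config$beta2,
                               config$weight_decay)
  val_in <- batch_from_images(lapply(pairs[split$validation], `[[`, "input_img"))
  val_gt <- lapply(pairs[split$validation], `[[`, "target_img")
  log <- data.frame(epoch = integer(), g_loss = numeric(), d_loss = numeric(),
                    val_ssim = numeric())
  best <- list(ssim = -Inf, epoch = NA_integer_, weights = NULL)
  set.seed(config$seed)
  for (epoch in seq_len(config$epochs_max)) {
    idx <- sample(split$train)
    g_tot <- 0; d_tot <- 0; n_batches <- 0L
    for (b0 in seq(1, length(idx), by = config$batch_size)) {
      bi <- idx[b0:min(b0 + config$batch_size - 1L, length(idx))]
      X <- batch_from_images(lapply(pairs[bi], `[[`, "input_img"))
      Y <- batch_from_images(lapply(pairs[bi], `[[`, "target_img"))
      # one generator forward serves both the (detached) D step and the G
      # step: D's update does not change G's weights
      fw <- nn_forward(G, X)
      pred <- fw$out
      d_loss <- 0
      if (use_d) {
        # --- discriminator step (generator detached) ---
        fr <- nn_forward(D, Y)
        ff <- nn_forward(D, pred)
        mr <- max(mean(fr$out), LOSS_EPS)
        mf <- min(mean(ff$out), 1 - LOSS_EPS)
        d_loss <- -(log(mr) + log(1 - mf))
        P <- length(fr$out)
        gd_r <- array(-1 / (mr * P), dim(fr$out))
        gd_f <- array(1 / ((1 - mf) * P), dim(ff$out))
        pg_r <- nn_backward(D, fr$acts, gd_r)$pgrads
        pg_f <- nn_backward(D, ff$acts, gd_f)$pgrads
        pg <- merge_pgrads(pg_r, pg_f)
        adam_step(D, pg, opt_d)
      }
      # --- generator step ---
      lg <- generator_loss_grad(pred, Y, w)
      dpred <- lg$grad
      adv_val <- 0
      if (use_d) {
        fd <- nn_forward(D, pred)
        mf <- max(mean(fd$out), LOSS_EPS)
        adv_val <- -log(mf)
        P <- length(fd$out)
        gadv <- array(-w$lambda / (mf * P), dim(fd$out))
        dpred <- dpred + nn_backward(D, fd$acts, gadv)$dinput
      }
      g_loss <- w$lambda * adv_val + w$nu * lg$rec + w$ssim * lg$ssim_term
      if (!is.finite(g_loss) || (use_d && !is.finite(d_loss)))
        stop(sprintf("non-finite loss at epoch %d (g=%.4g, d=%.4g); aborting",
                     epoch, g_loss, d_loss))
      pg_g <- nn_backward(G, fw$acts, dpred)$pgrads
      adam_step(G, pg_g, opt_g)
      g_tot <- g_tot + g_loss; d_tot <- d_tot + d_loss
      n_batches <- n_batches + 1L
    }
    vs <- validation_ssim(G, val_in, val_gt)
    log <- rbind(log, data.frame(epoch = epoch, g_loss = g_tot / n_batches,
                                 d_loss = d_tot / n_batches, val_ssim = vs))
    if (vs > best$ssim)
      best <- list(ssim = vs, epoch = epoch, weights = nn_get_weights(G))
    if (verbose)
      message(sprintf("epoch %3d  g_loss %.4f  d_loss %.4f  val_ssim %.4f%s",
                      epoch, g_tot / n_batches, d_tot / n_batches, vs,
                      if (best$epoch == epoch) " *" else ""))
  }
  nn_set_weights(G, best$weights)
  structure(list(generator = generator, discriminator = discriminator,
                 config = config, log = log, best_epoch = best$epoch,
                 best_val_ssim = best$ssim),
            class = "biraster_checkpoint")
}

merge_pgrads <- function(a, b) {
  for (i in seq_along(a)) {
    if (is.null(b[[i]])) next
    if (is.null(a[[i]])) a[i] <- b[i]
    else {
      a[[i]]$dW <- a[[i]]$dW + b[[i]]$dW
      a[[i]]$db <- a[[i]]$db + b[[i]]$db
    }
  }
  a
}

validation_ssim <- function(G, val_in, val_gt) {
  out <- nn_forward(G, val_in, keep = FALSE)$out
  mean(vapply(seq_along(val_gt), function(i) ssim(val_gt[[i]], out[, , 1, i]),
              numeric(1)))
}

#' @export
print.biraster_checkpoint <- function(x, ...) {
  cat(sprintf("<biraster_checkpoint: best epoch %d / %d, val SSIM %.4f>\n",
              x$best_epoch, nrow(x$log), x$best_val_ssim))
  invisible(x)
}

#' Correct an image with a trained generator
#'
#' Runs a single forward pass. Images whose sides are not multiples of
#' `2^n_scales` are transparently reflect-padded and unpadded.
#'
#' @param model a `biraster_checkpoint` or `biraster_net` generator.
#' @param image numeric matrix in `[0, 1]`, or a list of such matrices
#'   (processed as one batch; equal shapes required).
#' @return corrected matrix (or list of matrices) in `[0, 1]`, same shape.
#' @export
infer <- function(model, image) {
  net <- if (inherits(model, "biraster_checkpoint")) model$generator else model
  if (!inherits(net, "biraster_net") || net$type != "generator")
    stop("model must be a generator network or checkpoint")
  mult <- 2L^net$config$n_scales
  imgs <- if (is.matrix(image)) list(image) else image
  d <- dim(imgs[[1]])
  Hp <- as.integer(ceiling(d[1] / mult) * mult)
  Wp <- as.integer(ceiling(d[2] / mult) * mult)
  padded <- lapply(imgs, function(im) pad_reflect(im, Hp, Wp))
  out <- nn_forward(net$graph, batch_from_images(padded), keep = FALSE)$out
  res <- lapply(seq_along(imgs), function(i)
    out[seq_len(d[1]), seq_len(d[2]), 1, i])
  if (is.matrix(image)) res[[1]] else res
}

# reflect-101 pad at the bottom/right to reach (Hp, Wp)
pad_reflect <- function(im, Hp, Wp) {
  H <- nrow(im); W <- ncol(im)
  if (H == Hp && W == Wp) return(im)
  ridx <- c(seq_len(H), H - seq_len(Hp - H))
  cidx <- c(seq_len(W), W - seq_len(Wp - W))
  im[ridx, cidx, drop = FALSE]
}
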