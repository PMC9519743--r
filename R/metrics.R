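# Full-reference image quality metrics: SSIM (11x11 Gaussian window,
# sigma 1.5), MS-SSIM (5 scales, canonical weights), PSNR, MAE, MSE, the
# no-reference perceptual blur score, and BAD (blur absolute difference
# against the ground truth). Metrics operate on [0, data_range] grayscale
# matrices; window filtering uses symmetric padding at borders.

ssim_maps <- function(a, b, data_range = 1, sd = 1.5, radius = 5L) {
  k <- gauss_kernel(sd, radius)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  mu_a <- cpp_sep_filter(a, k)
  mu_b <- cpp_sep_filter(b, k)
  va <- cpp_sep_filter(a * a, k) - mu_a^2
  vb <- cpp_sep_filter(b * b, k) - mu_b^2
  vab <- cpp_sep_filter(a * b, k) - mu_a * mu_b
  l <- (2 * mu_a * mu_b + C1) / (mu_a^2 + mu_b^2 + C1)
  cs <- (2 * vab + C2) / (va + vb + C2)
  list(l = l, cs = cs)
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with an 11x11 Gaussian window (sigma 1.5) and the
#' standard stabilizers `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`.
#'
#' @param a,b same-shape numeric matrices in `[0, data_range]`.
#' @param data_range dynamic range `L` (default 1).
#' @return scalar SSIM in `[-1, 1]`.
#' @export
ssim <- function(a, b, data_range = 1) {
  stopifnot_image(a, b)
  m <- ssim_maps(a, b, data_range)
  mean(m$l * m$cs)
}

#' Multiscale SSIM
#'
#' Five-scale MS-SSIM with the canonical exponents (0.0448, 0.2856, 0.3001,
#' 0.2363, 0.1333) and dyadic 2x2 average-pool downsampling; contrast/
#' structure terms are taken at every scale and luminance only at the
#' coarsest. When the image is too small for five scales (min side < 176),
#' the number of scales is reduced and the weights renormalized.
#'
#' @inheritParams ssim
#' @param n_scales maximum number of scales (default 5).
#' @return scalar MS-SSIM.
#' @export
ms_ssim <- function(a, b, data_range = 1, n_scales = 5L) {
  stopifnot_image(a, b)
  w <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  # each scale needs at least the 11-px window after downsampling
  feasible <- max(1L, floor(log2(min(dim(a)) / 11)) + 1L)
  lev <- min(n_scales, 5L, feasible)
  w <- w[seq_len(lev)] / sum(w[seq_len(lev)])
  val <- 1
  for (i in seq_len(lev)) {
    m <- ssim_maps(a, b, data_range)
    term <- if (i == lev) mean(m$l * m$cs) else mean(m$cs)
    val <- val * max(term, 1e-6)^w[i]
    if (i < lev) {
      a <- avg_pool2(a)
      b <- avg_pool2(b)
    }
  }
  val
}

avg_pool2 <- function(x) {
  H <- 2L * (nrow(x) %/% 2L); W <- 2L * (ncol(x) %/% 2L)
  x <- x[seq_len(H), seq_len(W), drop = FALSE]
  0.25 * (x[seq(1, H, 2), seq(1, W, 2), drop = FALSE] +
          x[seq(2, H, 2), seq(1, W, 2), drop = FALSE] +
          x[seq(1, H, 2), seq(2, W, 2), drop = FALSE] +
          x[seq(2, H, 2), seq(2, W, 2), drop = FALSE])
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(max_val^2 / MSE)` in dB; identical images return `Inf`
#' (excluded, with a count, from [evaluate_set()] means).
#'
#' @inheritParams ssim
#' @param max_val peak signal value (default 1).
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, max_val = 1) {
  stopifnot_image(a, b)
  m <- mean((a - b)^2)
  if (m == 0) return(Inf)
  10 * log10(max_val^2 / m)
}

#' Mean absolute / squared error
#'
#' @inheritParams ssim
#' @return scalar mean absolute (squared) pixel difference.
#' @export
mae <- function(a, b) {
  stopifnot_image(a, b)
  mean(abs(a - b))
}

#' @rdname mae
#' @export
mse <- function(a, b) {
  stopifnot_image(a, b)
  mean((a - b)^2)
}

# 9-tap axis-aligned moving average with symmetric padding
blur_axis <- function(img, along = c("x", "y"), k = 9L) {
  along <- match.arg(along)
  r <- (k - 1L) %/% 2L
  n <- if (along == "x") ncol(img) else nrow(img)
  acc <- img * 0
  for (j in -r:r) {
    idx <- seq_len(n) + j
    idx[idx < 1] <- 1 - idx[idx < 1]           # symmetric reflection
    idx[idx > n] <- 2 * n + 1 - idx[idx > n]
    acc <- acc + if (along == "x") img[, idx, drop = FALSE]
                 else img[idx, , drop = FALSE]
  }
  acc / k
}

#' No-reference perceptual blur score
#'
#' Crete-Roffet style blur estimation: the image is strongly low-passed with
#' 9-tap averaging kernels along each axis; the variation of neighbor
#' differences lost by that blurring, relative to the original variation,
#' indicates how sharp the image was. Scores lie in `[0, 1]` (0 = sharp,
#' 1 = maximally blurred); the final score is the maximum over the two axes.
#'
#' @param image grayscale matrix in `[0, 1]`, minimum side >= 16.
#' @return scalar blur score in `[0, 1]`.
#' @export
blur_score <- function(image) {
  stopifnot_image(image)
  if (min(dim(image)) < 16L) stop("image too small for the blur metric (min side 16)")
  score_axis <- function(axis) {
    B <- blur_axis(image, axis)
    if (axis == "y") {
      dF <- abs(image[-1, , drop = FALSE] - image[-nrow(image), , drop = FALSE])
      dB <- abs(B[-1, , drop = FALSE] - B[-nrow(B), , drop = FALSE])
    } else {
      dF <- abs(image[, -1, drop = FALSE] - image[, -ncol(image), drop = FALSE])
      dB <- abs(B[, -1, drop = FALSE] - B[, -ncol(B), drop = FALSE])
    }
    sF <- sum(dF)
    if (sF == 0) return(NA_real_)
    sV <- sum(pmax(dF - dB, 0))
    (sF - sV) / sF
  }
  sy <- score_axis("y")
  sx <- score_axis("x")
  if (is.na(sy) && is.na(sx)) {
    warning("flat image: blur score undefined, returning 0")
    return(0)
  }
  max(sy, sx, na.rm = TRUE)
}

#' Blur absolute difference (BAD)
#'
#' Absolute difference of the no-reference [blur_score()] of two images;
#' measures how closely a corrected image matches the ground truth's
#' sharpness, independent of alignment.
#'
#' @inheritParams ssim
#' @return scalar `|blur_score(a) - blur_score(b)|`.
#' @export
bad <- function(a, b) {
  stopifnot_image(a, b)
  abs(blur_score(a) - blur_score(b))
}

#' Classical baseline filters
#'
#' The conventional enhancement baselines: `bicubic` (downsample x0.5 then
#' upsample x2 with Keys bicubic interpolation), `bilateral` (5x5 window,
#' sigma_color 0.1, sigma_space 2) and `median` (5x5).
#'
#' @param image matrix in `[0, 1]`.
#' @param method one of `"bicubic"`, `"bilateral"`, `"median"`.
#' @param window square window side for bilateral/median (odd, default 5).
#' @param sigma_color,sigma_space bilateral range / spatial sigmas.
#' @return filtered matrix in `[0, 1]`.
#' @export
baseline_filter <- function(image, method = c("bicubic", "bilateral", "median"),
                            window = 5L, sigma_color = 0.1, sigma_space = 2) {
  method <- match.arg(method)
  stopifnot_image(image)
  r <- (as.integer(window) - 1L) %/% 2L
  out <- switch(method,
    bicubic = {
      small <- cpp_bicubic_resize(image, max(1L, nrow(image) %/% 2L),
                                  max(1L, ncol(image) %/% 2L))
      cpp_bicubic_resize(small, nrow(image), ncol(image))
    },
    bilateral = cpp_bilateral(image, r, sigma_color, sigma_space),
    median = as.matrix(EBImage::medianFilter(image, size = r)))
  clamp01(out)
}

#' Evaluate correction methods on paired images
#'
#' Computes all six metrics (SSIM, MS-SSIM, PSNR, MAE, MSE, BAD) of each
#' method's output against the unidirectional ground truth, for every pair,
#' and summarizes mean +/- SD per method in a benchmark-style table
#' (methods as columns, one row per metric). The uncorrected input is always included as the first
#' column. Infinite PSNR values (identical images) are excluded from the
#' mean with a recorded count.
#'
#' @param pairs a `paired_dataset` or list of `paired_sample`s.
#' @param methods named list of functions `image -> image` (e.g. baselines
#'   or `function(x) infer(ckpt, x)`).
#' @return a `metric_report`: list with `per_image` and `summary` data
#'   frames and `n_psnr_excluded`.
#' @export
evaluate_set <- function(pairs, methods = list()) {
  if (inherits(pairs, "paired_dataset")) pairs <- pairs$pairs
  if (!length(pairs)) stop("empty pair list")
  cols <- c(list(input = identity), methods)
  metric_fns <- list(ssim = ssim, ms_ssim = ms_ssim, psnr = psnr,
                     mae = mae, mse = mse, bad = bad)
  rows <- list()
  for (mname in names(cols)) {
    fn <- cols[[mname]]
    for (i in seq_along(pairs)) {
      out <- fn(pairs[[i]]$input_img)
      gt <- pairs[[i]]$target_img
      vals <- vapply(metric_fns, function(f) f(out, gt), numeric(1))
      rows[[length(rows) + 1L]] <-
        data.frame(method = mname, pair = i, t(vals))
    }
  }
  per_image <- do.call(rbind, rows)
  n_excl <- sum(!is.finite(per_image$psnr))
  summ <- do.call(rbind, lapply(split(per_image, per_image$method), function(d) {
    data.frame(method = d$method[1],
               metric = names(metric_fns),
               mean = vapply(names(metric_fns), function(m) {
                 v <- d[[m]][is.finite(d[[m]])]
                 if (length(v)) mean(v) else NA_real_
               }, numeric(1)),
               sd = vapply(names(metric_fns), function(m) {
                 v <- d[[m]][is.finite(d[[m]])]
                 if (length(v) > 1) sd(v) else 0
               }, numeric(1)),
               row.names = NULL)
  }))
  summ <- summ[order(match(summ$method, names(cols))), ]
  rownames(summ) <- NULL
  structure(list(per_image = per_image, summary = summ,
                 n_psnr_excluded = n_excl),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  wide <- format_report_table(x)
  print(wide, row.names = FALSE)
  if (x$n_psnr_excluded > 0)
    cat(sprintf("(%d infinite PSNR value(s) excluded from means)\n",
                x$n_psnr_excluded))
  invisible(x)
}

format_report_table <- function(report) {
  s <- report$summary
  metrics <- unique(s$metric)
  methods <- unique(s$method)
  wide <- data.frame(metric = metrics)
  for (m in methods) {
    sm <- s[s$method == m, ]
    wide[[m]] <- sprintf("%.4f ± %.4f",
                         sm$mean[match(metrics, sm$metric)],
                         sm$sd[match(metrics, sm$metric)])
  }
  wide
}

#' Write a metric report to disk
#'
#' @param report a [evaluate_set()] result.
#' @param csv_path output CSV (metrics as rows, methods as columns,
#'   cells "mean +/- sd").
#' @param json_path optional JSON with all per-image values.
#' @return `report`, invisibly.
#' @export
write_metric_report <- function(report, csv_path, json_path = NULL) {
  write.csv(format_report_table(report), csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(per_image = report$per_image,
                              summary = report$summary,
                              n_psnr_excluded = report$n_psnr_excluded),
                         json_path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE)
  invisible(report)
}
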