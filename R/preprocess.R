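# Conversion of raw acquisitions into network-ready images: MAP projection,
# deterministic angular-distortion correction, normalization, tiling and
# dataset splitting. Images are row-major: rows = slow axis (y), columns =
# fast axis (x); offsets and indices in manifests are 0-based.

#' Maximum amplitude projection
#'
#' Per-pixel maximum over the depth axis of an A-scan volume, yielding the
#' 2-D vascular image (rows = slow axis, columns = fast axis).
#'
#' @param volume an [as_ascan_volume()] object.
#' @return numeric matrix (`n_lines` x `n_fast`).
#' @export
map_project <- function(volume) {
  if (!inherits(volume, "ascan_volume")) stop("expected an ascan_volume")
  d <- dim(volume$amplitudes)
  if (d[1] < 1L || any(d == 0L)) stop("empty volume")
  t(apply(volume$amplitudes, c(2, 3), max))
}

# nominal sinusoidal galvo sampling positions for one line, in the uniform-
# grid coordinate [-L/2, L/2]
galvo_positions <- function(geometry) {
  th_max <- geometry$galvo_amplitude_deg * pi / 180
  th <- seq(-th_max, th_max, length.out = geometry$n_fast)
  (geometry$fov_x_mm / 2) * sin(th) / sin(th_max)
}

#' Correct angular-scanning distortion
#'
#' A galvanometer sweeping sinusoidally samples non-uniform spatial
#' positions at uniform laser pulse times. This resamples each line from the
#' nominal sinusoidal positions onto a uniform grid by linear interpolation.
#' It is deterministic and leaves stochastic timing jitter untouched (that
#' residual misalignment is what the network corrects).
#'
#' @param image matrix with `n_fast` columns.
#' @param geometry a [scan_geometry()] providing `galvo_amplitude_deg`.
#' @return corrected matrix of the same size.
#' @export
angular_correction <- function(image, geometry) {
  stopifnot_image(image)
  if (ncol(image) != geometry$n_fast)
    stop("image width does not match geometry n_fast")
  xk <- galvo_positions(geometry)
  u <- seq(-geometry$fov_x_mm / 2, geometry$fov_x_mm / 2,
           length.out = geometry$n_fast)
  out <- image
  for (r in seq_len(nrow(image)))
    out[r, ] <- approx(xk, image[r, ], xout = u, rule = 2)$y
  out
}

#' @describeIn angular_correction forward model: distort a uniform-grid
#'   image onto the sinusoidal sampling positions (used for round-trip
#'   validation and simulation).
#' @export
angular_distort <- function(image, geometry) {
  stopifnot_image(image)
  if (ncol(image) != geometry$n_fast)
    stop("image width does not match geometry n_fast")
  xk <- galvo_positions(geometry)
  u <- seq(-geometry$fov_x_mm / 2, geometry$fov_x_mm / 2,
           length.out = geometry$n_fast)
  out <- image
  for (r in seq_len(nrow(image)))
    out[r, ] <- approx(u, image[r, ], xout = xk, rule = 2)$y
  out
}

#' Normalize an image to [0, 1]
#'
#' `minmax` maps the observed range to `[0, 1]`; `percentile` first clips at
#' the given percentiles (robust to hot pixels). Constant images map to all
#' zeros.
#'
#' @param image finite numeric matrix.
#' @param mode `"minmax"` or `"percentile"`.
#' @param p_low,p_high clipping percentiles (in percent) for percentile mode.
#' @return matrix with values in `[0, 1]`.
#' @export
normalize_image <- function(image, mode = c("minmax", "percentile"),
                            p_low = 0.1, p_high = 99.9) {
  mode <- match.arg(mode)
  stopifnot_image(image)
  if (any(!is.finite(image))) stop("image contains non-finite values")
  if (mode == "percentile") {
    q <- quantile(image, c(p_low, p_high) / 100, names = FALSE, type = 7)
    image <- pmin(pmax(image, q[1]), q[2])
  }
  rng <- range(image)
  if (rng[2] <= rng[1]) return(image * 0)
  (image - rng[1]) / (rng[2] - rng[1])
}

#' Cut an image into square tiles
#'
#' Tiles lie on a regular grid from the top-left corner with the given
#' stride (default non-overlapping); any remainder is discarded. Offsets
#' are 0-based `(row, col)` and allow exact reassembly of the covered
#' region.
#'
#' @param image matrix with both sides >= `size`.
#' @param size tile side (default 192, the network's training crop).
#' @param stride grid stride (default `size`).
#' @return list of `list(tile, offset)` with attribute `image_dim`.
#' @export
crop_tiles <- function(image, size = 192L, stride = size) {
  stopifnot_image(image)
  size <- as.integer(size); stride <- as.integer(stride)
  if (any(dim(image) < size)) stop("image smaller than tile size")
  ys <- seq(0L, nrow(image) - size, by = stride)
  xs <- seq(0L, ncol(image) - size, by = stride)
  tiles <- list()
  for (y in ys) for (x in xs)
    tiles[[length(tiles) + 1L]] <-
      list(tile = image[y + seq_len(size), x + seq_len(size)],
           offset = c(y, x))
  attr(tiles, "image_dim") <- dim(image)
  tiles
}

#' Split sample indices into train / validation / test sets
#'
#' Held-out sizes use ceiling rounding: `test = ceiling(test_frac * n)`,
#' then `validation = ceiling(val_frac * (n - test))`, remainder train --
#' the rule that reproduces a 231-image test set and 93-image validation
#' set from 1154 pairs at the 8:2 and 9:1 ratios. Assignment is by seeded
#' permutation.
#'
#' @param n number of samples (>= 10).
#' @param test_frac,val_frac held-out fractions in (0, 1).
#' @param seed permutation seed.
#' @return a `split_indices` object with sorted, disjoint 1-based index
#'   vectors `train`, `validation`, `test` covering `1:n`.
#' @export
split_dataset <- function(n, test_frac = 0.2, val_frac = 0.1, seed = 1L) {
  if (n < 10) stop("n must be >= 10")
  if (test_frac <= 0 || test_frac >= 1 || val_frac <= 0 || val_frac >= 1)
    stop("fractions must lie in (0, 1)")
  perm <- local_seed(seed, sample.int(n))
  n_test <- ceiling(test_frac * n)
  n_val <- ceiling(val_frac * (n - n_test))
  structure(list(test = sort(perm[seq_len(n_test)]),
                 validation = sort(perm[n_test + seq_len(n_val)]),
                 train = sort(perm[-seq_len(n_test + n_val)])),
            class = "split_indices")
}

#' @export
print.split_indices <- function(x, ...) {
  cat(sprintf("<split_indices: %d train / %d validation / %d test>\n",
              length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}
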