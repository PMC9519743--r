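# Slice-wise extension of the 2-D correction to 3-D volumes: each en-face
# (x, y) plane at fixed depth z is corrected independently by the trained
# generator, then the planes are reassembled. Includes depth-encoded
# rendering and mosaic stitching of segmented acquisitions.

#' Correct a 3-D volume slice by slice
#'
#' For each depth index, the en-face plane is min-max normalized, reflect-
#' padded to multiples of `2^n_scales`, passed through the generator,
#' unpadded, and rescaled back to its original amplitude range, so global
#' amplitude relations between planes are preserved.
#'
#' @param volume an [as_ascan_volume()] object (axes z, x, y).
#' @param model a trained `biraster_checkpoint` or generator network.
#' @param normalize_planes normalize each plane before inference (default
#'   TRUE; planes with zero dynamic range bypass the network).
#' @return corrected `ascan_volume`, same shape and metadata.
#' @export
correct_volume <- function(volume, model, normalize_planes = TRUE) {
  if (!inherits(volume, "ascan_volume")) stop("expected an ascan_volume")
  d <- dim(volume$amplitudes)
  if (any(d == 0L)) stop("empty volume")
  out <- volume$amplitudes
  for (z in seq_len(d[1])) {
    plane <- t(volume$amplitudes[z, , ])       # rows = y, cols = x
    rng <- range(plane)
    if (normalize_planes) {
      if (rng[2] <= rng[1]) next               # flat plane: leave unchanged
      p <- (plane - rng[1]) / (rng[2] - rng[1])
    } else p <- plane
    cor <- infer(model, p)
    if (normalize_planes) cor <- cor * (rng[2] - rng[1]) + rng[1]
    out[z, , ] <- t(cor)
  }
  as_ascan_volume(out, volume$spacing_um, mode = paste0(volume$mode, "+corrected"),
                  jitter_record = volume$jitter_record)
}

#' Depth-encoded rendering of a volume
#'
#' Per (x, y) position, the depth of the maximum-amplitude voxel (ties
#' broken toward the shallowest) selects a hue along a monotone colormap,
#' and the MAP amplitude sets the brightness.
#'
#' @param volume an [as_ascan_volume()] with `n_depth >= 2`.
#' @param hue_range hue endpoints (shallow, deep) of the HSV colormap.
#' @return a `depth_encoded_image`: list with `rgb` (H x W x 3 in `[0,1]`),
#'   `depth_index` (1-based argmax plane, rows = y), `map` (normalized MAP),
#'   `depth_range_mm` and a colormap descriptor.
#' @export
depth_encode <- function(volume, hue_range = c(0.66, 0)) {
  if (!inherits(volume, "ascan_volume")) stop("expected an ascan_volume")
  d <- dim(volume$amplitudes)
  if (d[1] < 2L) stop("depth encoding needs n_depth >= 2")
  zidx <- t(apply(volume$amplitudes, c(2, 3), which.max))  # rows = y
  amp <- map_project(volume)
  rng <- range(amp)
  v <- if (rng[2] > rng[1]) (amp - rng[1]) / (rng[2] - rng[1]) else amp * 0
  frac <- (zidx - 1) / (d[1] - 1)
  hue <- hue_range[1] + (hue_range[2] - hue_range[1]) * frac
  cols <- col2rgb(hsv(h = as.vector(hue), s = 1, v = as.vector(v))) / 255
  rgb <- array(0, c(nrow(amp), ncol(amp), 3))
  for (ch in 1:3) rgb[, , ch] <- matrix(cols[ch, ], nrow(amp))
  structure(list(rgb = rgb, depth_index = zidx, map = v,
                 depth_range_mm = c(0, (d[1] - 1) * volume$spacing_um[1] / 1000),
                 colormap = sprintf("hsv %.2f->%.2f, value = MAP amplitude",
                                    hue_range[1], hue_range[2])),
            class = "depth_encoded_image")
}

#' @export
print.depth_encoded_image <- function(x, ...) {
  cat(sprintf("<depth_encoded_image %d x %d, depth %.2f-%.2f mm, %s>\n",
              nrow(x$map), ncol(x$map), x$depth_range_mm[1],
              x$depth_range_mm[2], x$colormap))
  invisible(x)
}

#' Stitch image segments into a mosaic
#'
#' Places each segment at its 0-based `(row, col)` offset on a canvas sized
#' to the joint extent. Overlapping regions are blended with linear
#' feathering (weights fall off toward each segment's border); uncovered
#' pixels are filled with 0 and reported.
#'
#' @param segments list of `list(image, offset)`.
#' @param feather feather width in pixels.
#' @return mosaic matrix with attribute `n_gap_pixels`.
#' @export
stitch_segments <- function(segments, feather = 16L) {
  if (!length(segments)) stop("no segments to stitch")
  offs <- t(vapply(segments, function(s) as.numeric(s$offset), numeric(2)))
  if (any(offs < 0)) stop("offsets must be non-negative")
  dims <- t(vapply(segments, function(s) dim(s$image), numeric(2)))
  H <- max(offs[, 1] + dims[, 1]); W <- max(offs[, 2] + dims[, 2])
  acc <- matrix(0, H, W); wsum <- matrix(0, H, W)
  for (s in segments) {
    h <- nrow(s$image); w <- ncol(s$image)
    wy <- pmin(seq_len(h), h + 1 - seq_len(h), feather)
    wx <- pmin(seq_len(w), w + 1 - seq_len(w), feather)
    wmap <- outer(wy, wx, pmin)
    ri <- s$offset[1] + seq_len(h); ci <- s$offset[2] + seq_len(w)
    acc[ri, ci] <- acc[ri, ci] + wmap * s$image
    wsum[ri, ci] <- wsum[ri, ci] + wmap
  }
  covered <- wsum > 0
  out <- matrix(0, H, W)
  out[covered] <- acc[covered] / wsum[covered]
  n_gap <- sum(!covered)
  if (n_gap > 0)
    message(n_gap, " uncovered pixel(s) filled with 0")
  attr(out, "n_gap_pixels") <- n_gap
  out
}
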