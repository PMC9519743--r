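# Raster-scan acquisition simulation. The scene is rendered once on a 1 um
# reference grid, blurred with the lateral PSF, and sampled bilinearly along
# each line's trajectory. Bidirectional scans alternate forward/backward
# lines; unidirectional scans simulate both sweeps but retain only the
# forward lines, halving the effective line rate.

#' Simulate one raster-scan acquisition
#'
#' @param scene a [make_vessel_scene()] scene.
#' @param geometry a [scan_geometry()]; its field of view must match the
#'   scene's.
#' @param jitter a [jitter_model()] applied to backward lines.
#' @param noise_sd additive Gaussian noise SD; the default corresponds to a
#'   peak SNR of ~47 dB on unit-amplitude vessels.
#' @param noise_seed seed of the noise draw (defaults to a stream derived
#'   from the jitter seed, so repeated calls are identical).
#' @param reference optional precomputed [render_scene()] output (with PSF
#'   blur) to avoid re-rasterizing the scene.
#' @return with `n_depth = 0`, a numeric matrix (`n_lines_kept` x `n_fast`,
#'   rows = slow axis) with attributes `jitter_record` (data.frame: line,
#'   direction, lag) and `y_positions_um`; with `n_depth > 0`, an
#'   `ascan_volume` object (see [as_ascan_volume()]).
#' @export
simulate_acquisition <- function(scene, geometry, jitter = zero_jitter(),
                                 noise_sd = 0.0045,
                                 noise_seed = sub_seed(jitter$seed, 1L, 5L),
                                 reference = NULL) {
  if (any(abs(c(geometry$fov_x_mm, geometry$fov_y_mm) - scene$fov) > 1e-9))
    stop("geometry field of view inconsistent with scene")
  ref <- reference %||%
    render_scene(scene, scale_um = 1, blur_fwhm_um = geometry$psf_lateral_fwhm_um)
  scale <- ref$scale_um
  n_lines <- geometry$n_lines
  dirs <- ifelse(seq_len(n_lines) %% 2L == 1L, "forward", "backward") # line 0 fwd
  keep <- if (geometry$mode == "unidirectional") which(dirs == "forward")
          else seq_len(n_lines)
  y_um <- (seq_len(n_lines) - 1L) * geometry$y_step_um
  img <- matrix(0, length(keep), geometry$n_fast)
  depth_img <- matrix(NA_real_, length(keep), geometry$n_fast)
  lags <- rep(0, n_lines)
  want_depth <- geometry$n_depth > 0L
  for (r in seq_along(keep)) {
    li <- keep[r]
    dr <- dirs[li]
    pos <- line_trajectory(geometry, jitter, li - 1L, dr)
    if (dr == "backward")
      lags[li] <- realized_lag(jitter, li - 1L, n_lines)
    xs <- matrix(pos * 1000 / scale, 1)
    ys <- matrix(rep(y_um[li] / scale, length(pos)), 1)
    vals <- as.numeric(cpp_bilinear_sample(ref$amplitude, xs, ys))
    if (dr == "backward") vals <- rev(vals)   # store in ascending-x order
    img[r, ] <- vals
    if (want_depth) {
      dref <- ref$depth
      dref[is.na(dref)] <- geometry$z_extent_mm / 2
      dv <- as.numeric(cpp_bilinear_sample(dref, xs, ys))
      if (dr == "backward") dv <- rev(dv)
      depth_img[r, ] <- dv
    }
  }
  rec <- data.frame(line = seq_len(n_lines) - 1L, direction = dirs, lag = lags)
  if (!want_depth) {
    if (noise_sd > 0)
      img <- img + local_seed(noise_seed, matrix(rnorm(length(img), 0, noise_sd), nrow(img)))
    img <- clamp01(img)
    attr(img, "jitter_record") <- rec[keep, , drop = FALSE]
    attr(img, "y_positions_um") <- y_um[keep]
    return(img)
  }
  # 3-D path: spread each surface pixel along z with the axial Gaussian PSF
  nz <- geometry$n_depth
  z <- seq(0, geometry$z_extent_mm, length.out = nz)
  fa <- geometry$psf_axial_fwhm_um / 1000
  vol <- array(0, c(nz, geometry$n_fast, length(keep)))
  for (r in seq_along(keep))
    for (x in seq_len(geometry$n_fast))
      vol[, x, r] <- img[r, x] * exp(-4 * log(2) * (z - depth_img[r, x])^2 / fa^2)
  if (noise_sd > 0)
    vol <- vol + local_seed(noise_seed, array(rnorm(length(vol), 0, noise_sd), dim(vol)))
  vol <- clamp01(vol)
  as_ascan_volume(vol,
                  spacing_um = c(geometry$z_extent_mm * 1000 / (nz - 1),
                                 geometry$fov_x_mm * 1000 / (geometry$n_fast - 1),
                                 geometry$y_step_um *
                                   (if (geometry$mode == "unidirectional") 2 else 1)),
                  mode = geometry$mode, jitter_record = rec[keep, , drop = FALSE])
}

#' A-scan volume container
#'
#' A 3-D photoacoustic amplitude array with axis metadata. Axis order is
#' (z = depth, x = fast axis, y = slow axis).
#'
#' @param amplitudes non-negative 3-D array `(n_depth, n_fast, n_lines)`.
#' @param spacing_um per-axis sample spacing `c(dz, dx, dy)` in micrometres.
#' @param mode acquisition mode string.
#' @param jitter_record optional per-line lag record.
#' @return an `ascan_volume` object.
#' @export
as_ascan_volume <- function(amplitudes, spacing_um, mode = "unknown",
                            jitter_record = NULL) {
  if (length(dim(amplitudes)) != 3L) stop("amplitudes must be a 3-d array")
  if (any(spacing_um <= 0)) stop("axis spacings must be positive")
  structure(list(amplitudes = amplitudes, spacing_um = as.numeric(spacing_um),
                 mode = mode, jitter_record = jitter_record),
            class = "ascan_volume")
}

#' @export
print.ascan_volume <- function(x, ...) {
  d <- dim(x$amplitudes)
  cat(sprintf("<ascan_volume %d x %d x %d (z,x,y), spacing %s um, %s>\n",
              d[1], d[2], d[3], paste(signif(x$spacing_um, 4), collapse = "/"),
              x$mode))
  invisible(x)
}

#' Generate a paired bidirectional/unidirectional dataset
#'
#' Each pair shares one vessel scene: the input is a bidirectional scan at
#' `geometry$y_step_um` (default 4 um) with the configured jitter, the
#' target a unidirectional scan at half the step with forward lines
#' retained, so both land on the same row grid. Both images receive
#' independent noise draws and are cropped to `crop_size` at a common
#' seeded offset. Fully deterministic in `seed`.
#'
#' @param n_pairs number of pairs (>= 1).
#' @param geometry bidirectional [scan_geometry()].
#' @param jitter a [jitter_model()]; its per-pair realization seed is derived
#'   from `seed`.
#' @param seed integer master seed.
#' @param crop_size side of the square crops (default 192).
#' @param n_vessels vessels per scene.
#' @param noise_sd additive noise SD for both acquisitions.
#' @return a `paired_dataset`: list with `pairs` (each a `paired_sample`
#'   holding `input_img`, `target_img`, `jitter_record`, `scene_seed`,
#'   `crop_offset`) and a `manifest`.
#' @export
generate_paired_dataset <- function(n_pairs, geometry = scan_geometry(),
                                    jitter = jitter_model(), seed = 1L,
                                    crop_size = 192L, n_vessels = 6L,
                                    noise_sd = 0.0045) {
  if (n_pairs < 1L) stop("n_pairs must be >= 1")
  if (geometry$mode != "bidirectional")
    stop("geometry must be bidirectional; the unidirectional target geometry is derived")
  geo_uni <- geometry
  geo_uni$y_step_um <- geometry$y_step_um / 2
  geo_uni$mode <- "unidirectional"
  geo_uni$n_lines <- as.integer(floor(geometry$fov_y_mm * 1000 / geo_uni$y_step_um))
  pairs <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    scene_seed <- sub_seed(seed, i, 1L)
    scene <- make_vessel_scene(scene_seed, n_vessels,
                               fov = c(geometry$fov_x_mm, geometry$fov_y_mm))
    ref <- render_scene(scene, 1, blur_fwhm_um = geometry$psf_lateral_fwhm_um)
    jit <- jitter
    jit$seed <- sub_seed(seed, i, 2L)
    input <- simulate_acquisition(scene, geometry, jit, noise_sd = noise_sd,
                                  noise_seed = sub_seed(seed, i, 6L),
                                  reference = ref)
    target <- simulate_acquisition(scene, geo_uni, jit, noise_sd = noise_sd,
                                   noise_seed = sub_seed(seed, i, 7L),
                                   reference = ref)
    if (!identical(dim(input), dim(target)))
      stop("internal error: paired scans have mismatched grids")
    H <- nrow(input); W <- ncol(input)
    if (crop_size > min(H, W)) stop("crop_size larger than the scanned image")
    off <- local_seed(sub_seed(seed, i, 8L),
                      c(sample.int(H - crop_size + 1L, 1L),
                        sample.int(W - crop_size + 1L, 1L))) - 1L
    rows <- off[1] + seq_len(crop_size)
    cols <- off[2] + seq_len(crop_size)
    pairs[[i]] <- structure(
      list(input_img = unclass(input[rows, cols]),
           target_img = unclass(target[rows, cols]),
           jitter_record = attr(input, "jitter_record"),
           scene_seed = scene_seed, crop_offset = off),
      class = "paired_sample")
  }
  manifest <- list(seed = as.integer(seed), n_pairs = as.integer(n_pairs),
                   crop_size = as.integer(crop_size), n_vessels = as.integer(n_vessels),
                   noise_sd = noise_sd,
                   geometry = unclass(geometry), jitter = unclass(jitter),
                   scene_seeds = vapply(pairs, function(p) p$scene_seed, numeric(1)),
                   crop_offsets = t(vapply(pairs, function(p) p$crop_offset, numeric(2))))
  structure(list(pairs = pairs, manifest = manifest), class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("<paired_dataset: %d pairs of %d x %d images (seed %d)>\n",
              length(x$pairs), x$manifest$crop_size, x$manifest$crop_size,
              x$manifest$seed))
  invisible(x)
}

#' @export
length.paired_dataset <- function(x) length(x$pairs)
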