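# Synthetic vascular scenes: smooth, branching, tapering vessel curves with
# Gaussian cross-sections, standing in for the microvasculature imaged in
# OR-PAM. Scenes are rasterized onto a 1 um reference grid so that sub-pixel
# differences between scan trajectories matter.

#' Generate a synthetic vessel scene
#'
#' Draws `n_vessels` smooth centreline curves (random-walk control points
#' interpolated with cubic splines), each with linearly tapering radius, a
#' per-vessel amplitude and depth, plus side branches. A rejection loop
#' regenerates the scene until vessels cover between 1% and 60% of the field
#' when rendered at 2 um/px, keeping phantoms in a realistic density range.
#'
#' @param seed integer seed; scenes are deterministic in `seed`.
#' @param n_vessels number of primary vessels (>= 1).
#' @param fov field of view `c(x_mm, y_mm)`.
#' @param background_level background amplitude in `[0, 1]`.
#' @param max_radius_um maximum vessel radius.
#' @return a `vessel_scene` object.
#' @export
make_vessel_scene <- function(seed, n_vessels = 6L, fov = c(1.1, 1.0),
                              background_level = 0.05, max_radius_um = 18) {
  if (any(fov <= 0)) stop("invalid geometry: fov must be positive")
  if (n_vessels < 1L) stop("n_vessels must be >= 1")
  for (attempt in 0:24) {
    sc <- local_seed(sub_seed(seed, attempt, 11L),
                     gen_scene_once(n_vessels, fov, background_level, max_radius_um))
    sc$seed <- as.integer(seed)
    cov <- scene_coverage(sc)
    if (cov >= 0.01 && cov <= 0.60) return(sc)
  }
  stop("could not generate a scene with vessel coverage in [1%, 60%]")
}

gen_scene_once <- function(n_vessels, fov, background_level, max_radius_um) {
  rmax_mm <- max_radius_um / 1000
  lo <- -rmax_mm
  hi <- fov + rmax_mm
  one_walk <- function(start, dir0, n_ctrl, step_mm) {
    pts <- matrix(0, n_ctrl, 2)
    pts[1, ] <- start
    dir <- dir0
    for (i in 2:n_ctrl) {
      dir <- dir + rnorm(1, 0, 0.5)
      pts[i, ] <- pts[i - 1, ] + step_mm * c(cos(dir), sin(dir))
    }
    pts[, 1] <- pmin(pmax(pts[, 1], lo[1]), hi[1])
    pts[, 2] <- pmin(pmax(pts[, 2], lo[1]), hi[2])
    pts
  }
  vessels <- list()
  for (v in seq_len(n_vessels)) {
    n_ctrl <- sample(4:7, 1)
    start <- c(runif(1, 0, fov[1]), runif(1, 0, fov[2]))
    pts <- one_walk(start, runif(1, 0, 2 * pi), n_ctrl, runif(1, 0.15, 0.35))
    r0 <- runif(1, 6, max_radius_um)
    radius <- r0 * seq(1, runif(1, 0.35, 0.6), length.out = n_ctrl) *
      exp(rnorm(n_ctrl, 0, 0.05))
    vessels[[length(vessels) + 1L]] <-
      list(points = pts, radius_um = pmax(radius, 1.5),
           amplitude = runif(1, 0.55, 1), depth_mm = runif(1, 0.2, 0.6))
    if (runif(1) < 0.6) {        # one side branch
      at <- sample(2:(n_ctrl - 1), 1)
      n_b <- sample(3:5, 1)
      bpts <- one_walk(pts[at, ], runif(1, 0, 2 * pi), n_b, runif(1, 0.1, 0.25))
      br0 <- radius[at] * 0.8
      bradius <- br0 * seq(1, runif(1, 0.35, 0.6), length.out = n_b)
      vessels[[length(vessels) + 1L]] <-
        list(points = bpts, radius_um = pmax(bradius, 1.5),
             amplitude = vessels[[length(vessels)]]$amplitude * runif(1, 0.8, 1),
             depth_mm = vessels[[length(vessels)]]$depth_mm + rnorm(1, 0, 0.02))
    }
  }
  structure(list(vessels = vessels, fov = fov,
                 background_level = background_level, seed = NA_integer_),
            class = "vessel_scene")
}

scene_coverage <- function(scene) {
  r <- render_scene(scene, scale_um = 2)
  mean(r$amplitude > scene$background_level + 0.05)
}

# densely resample one vessel's control polygon with cubic splines;
# returns x/y (mm) and interpolated radius (um) at ~spacing_mm intervals
vessel_samples <- function(vessel, spacing_mm) {
  pts <- vessel$points
  n <- nrow(pts)
  if (n < 2) return(NULL)
  tt <- seq_len(n)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  len <- sum(seg)
  m <- max(8L, ceiling(len / spacing_mm))
  to <- seq(1, n, length.out = m)
  xs <- spline(tt, pts[, 1], xout = to)$y
  ys <- spline(tt, pts[, 2], xout = to)$y
  rs <- approx(tt, vessel$radius_um, xout = to)$y
  cbind(xs, ys, rs)
}

#' Rasterize a vessel scene onto a reference grid
#'
#' Vessels are splatted as Gaussian cross-sections (FWHM = vessel diameter)
#' with the per-pixel maximum over vessels; the result can optionally be
#' blurred with the lateral PSF. Also returns the depth (mm) of the
#' strongest vessel at each pixel (NA outside vessels).
#'
#' @param scene a [make_vessel_scene()] scene.
#' @param scale_um grid spacing in micrometres per pixel.
#' @param blur_fwhm_um optional Gaussian blur FWHM (the lateral PSF).
#' @return list with `amplitude` (rows = y, cols = x, values in `[0, 1]`),
#'   `depth` (mm, NA background) and `scale_um`.
#' @export
render_scene <- function(scene, scale_um = 1, blur_fwhm_um = 0) {
  W <- as.integer(floor(scene$fov[1] * 1000 / scale_um)) + 1L
  H <- as.integer(floor(scene$fov[2] * 1000 / scale_um)) + 1L
  rows <- list()
  for (v in scene$vessels) {
    sm <- vessel_samples(v, spacing_mm = scale_um * 0.6 / 1000)
    if (is.null(sm)) next
    sigma_px <- pmax(sm[, 3] * 0.8493 / scale_um, 0.4)
    rows[[length(rows) + 1L]] <-
      cbind(sm[, 1] * 1000 / scale_um, sm[, 2] * 1000 / scale_um,
            sigma_px, v$amplitude, v$depth_mm)
  }
  pts <- do.call(rbind, rows)
  r <- cpp_splat_render(pts, H, W, scene$background_level)
  amp <- clamp01(r$amplitude)
  if (blur_fwhm_um > 0) {
    sd_px <- blur_fwhm_um / 2.3548 / scale_um
    amp <- cpp_sep_filter(amp, gauss_kernel(sd_px))
  }
  list(amplitude = amp, depth = r$depth, scale_um = scale_um)
}

# normalized 1-D Gaussian kernel, radius 3*sd
gauss_kernel <- function(sd, radius = max(1L, ceiling(3 * sd))) {
  k <- exp(-(-radius:radius)^2 / (2 * sd^2))
  k / sum(k)
}
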