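# Scan geometry and the stochastic timing (jitter) model of the fast-axis
# scanner. Forward lines sample the nominal post-angular-correction uniform
# grid; backward lines are the reversed grid composed with a realized per-
# line lag and a smooth odd warp, reproducing the nonlinear misalignment of
# bidirectional raster scanning.

#' Theoretical diffraction-limited lateral resolution
#'
#' FWHM lateral resolution `0.51 * lambda / NA` of an optical-resolution
#' photoacoustic microscope, in micrometres. Used for the default lateral
#' PSF of the acquisition simulator.
#'
#' @param na optical numerical aperture, in (0, 1).
#' @param wavelength_nm excitation wavelength in nanometres.
#' @return lateral resolution in micrometres.
#' @examples
#' theoretical_lateral_resolution(0.032, 532)  # ~8.5 um
#' @export
theoretical_lateral_resolution <- function(na, wavelength_nm) {
  if (!is.numeric(na) || na <= 0 || na >= 1) stop("na must be in (0, 1)")
  if (!is.numeric(wavelength_nm) || wavelength_nm <= 0)
    stop("wavelength_nm must be positive")
  0.51 * wavelength_nm / na / 1000
}

#' Theoretical axial resolution of the ultrasonic detector
#'
#' FWHM axial resolution `0.88 * c / (f0 * bandwidth)` in micrometres, for a
#' transducer of centre frequency `f0` (MHz) and fractional -6 dB bandwidth.
#'
#' @param center_freq_mhz transducer centre frequency in MHz.
#' @param fractional_bandwidth fractional bandwidth in (0, 2].
#' @param speed_of_sound_m_s speed of sound in m/s (default 1540, soft tissue).
#' @return axial resolution in micrometres.
#' @examples
#' theoretical_axial_resolution(20, 0.60)  # ~113 um
#' @export
theoretical_axial_resolution <- function(center_freq_mhz, fractional_bandwidth,
                                         speed_of_sound_m_s = 1540) {
  if (center_freq_mhz <= 0 || speed_of_sound_m_s <= 0)
    stop("frequency and speed of sound must be positive")
  if (fractional_bandwidth <= 0 || fractional_bandwidth > 2)
    stop("fractional_bandwidth must be in (0, 2]")
  0.88 * speed_of_sound_m_s / (center_freq_mhz * 1e6 * fractional_bandwidth) * 1e6
}

#' Raster-scan geometry
#'
#' Field of view, pixel grid and point-spread function of one acquisition.
#' The defaults reproduce the reference acquisition conditions: a 1.1 mm x 1 mm field, 250
#' fast-axis pixels, 4 um slow-axis steps for bidirectional scans (2 um,
#' forward lines retained, for the unidirectional ground truth).
#'
#' @param fov_x_mm,fov_y_mm field of view in mm.
#' @param n_fast pixels per fast-axis line.
#' @param y_step_um slow-axis step in micrometres.
#' @param mode `"bidirectional"` (all lines kept, alternating direction) or
#'   `"unidirectional"` (both sweeps scanned, forward lines retained).
#' @param galvo_amplitude_deg half-angle of the sinusoidal galvanometer sweep,
#'   degrees; used by [angular_correction()].
#' @param psf_lateral_fwhm_um,psf_axial_fwhm_um Gaussian PSF FWHMs; defaults
#'   derive from [theoretical_lateral_resolution()] (NA 0.032, 532 nm) and
#'   [theoretical_axial_resolution()] (20 MHz, 60% bandwidth).
#' @param n_depth depth samples per A-line; 0 simulates 2-D MAP images
#'   directly.
#' @param z_extent_mm axial extent of the simulated volume.
#' @return a `scan_geometry` list with derived `n_lines`.
#' @export
scan_geometry <- function(fov_x_mm = 1.1, fov_y_mm = 1.0, n_fast = 250L,
                          y_step_um = 4, mode = c("bidirectional", "unidirectional"),
                          galvo_amplitude_deg = 10,
                          psf_lateral_fwhm_um = theoretical_lateral_resolution(0.032, 532),
                          psf_axial_fwhm_um = theoretical_axial_resolution(20, 0.60),
                          n_depth = 0L, z_extent_mm = 0.8) {
  mode <- match.arg(mode)
  if (fov_x_mm <= 0 || fov_y_mm <= 0) stop("invalid geometry: field of view must be positive")
  if (n_fast < 2L) stop("invalid geometry: n_fast must be >= 2")
  if (y_step_um <= 0) stop("invalid geometry: y_step_um must be positive")
  n_lines <- as.integer(floor(fov_y_mm * 1000 / y_step_um))
  if (n_lines < 2L) stop("invalid geometry: fewer than two scan lines")
  structure(list(fov_x_mm = fov_x_mm, fov_y_mm = fov_y_mm,
                 n_fast = as.integer(n_fast), y_step_um = y_step_um,
                 mode = mode, n_lines = n_lines,
                 galvo_amplitude_deg = galvo_amplitude_deg,
                 psf_lateral_fwhm_um = psf_lateral_fwhm_um,
                 psf_axial_fwhm_um = psf_axial_fwhm_um,
                 n_depth = as.integer(n_depth), z_extent_mm = z_extent_mm),
            class = "scan_geometry")
}

#' Scanner timing-jitter model
#'
#' Parameterizes the misalignment of backward lines: a constant phase lag, a
#' slow sinusoidal drift across the slow axis, independent per-line Gaussian
#' jitter (all as fractions of the fast-axis span), and a smooth odd warp
#' `x -> x + sum_k a_k * L * sin(k*pi*x/L)` giving the nonlinear component.
#' With every field zero, forward and backward trajectories coincide exactly.
#' Defaults give roughly one pixel of lag at 250 fast-axis pixels, which
#' visibly doubles vessels without destroying structure.
#'
#' @param phase_lag_mean mean lag of backward lines (fraction of span).
#' @param phase_lag_sd per-line Gaussian jitter SD (fraction of span).
#' @param distortion_coeffs coefficients `a_k` of the odd sinusoidal warp
#'   (fractions of span).
#' @param drift_amplitude amplitude of the sinusoidal lag drift across lines.
#' @param seed integer seed for the per-line jitter realizations.
#' @return a `jitter_model` list.
#' @export
jitter_model <- function(phase_lag_mean = 0.004, phase_lag_sd = 0.002,
                         distortion_coeffs = 0.003, drift_amplitude = 0.002,
                         seed = 0L) {
  structure(list(phase_lag_mean = phase_lag_mean, phase_lag_sd = phase_lag_sd,
                 distortion_coeffs = as.numeric(distortion_coeffs),
                 drift_amplitude = drift_amplitude, seed = as.integer(seed)),
            class = "jitter_model")
}

#' @rdname jitter_model
#' @export
zero_jitter <- function(seed = 0L)
  jitter_model(0, 0, 0, 0, seed = seed)

# realized lag (fraction of span) of one backward line; deterministic in
# (jitter seed, line index)
realized_lag <- function(jitter, line_index, n_lines) {
  lag <- jitter$phase_lag_mean +
    jitter$drift_amplitude * sin(2 * pi * line_index / n_lines)
  if (jitter$phase_lag_sd > 0)
    lag <- lag + local_seed(sub_seed(jitter$seed, line_index, 3L),
                            rnorm(1, 0, jitter$phase_lag_sd))
  lag
}

#' Fast-axis trajectory of one scan line
#'
#' Forward lines return the nominal uniform grid over `[0, fov_x]`. Backward
#' lines return the reversed grid shifted by the realized lag for that line
#' and composed with the odd sinusoidal warp; positions are strictly
#' monotonic in sample (time) index.
#'
#' @param geometry a [scan_geometry()].
#' @param jitter a [jitter_model()].
#' @param line_index 0-based line index within the scan.
#' @param direction `"forward"` or `"backward"`.
#' @return numeric vector of `n_fast` x-positions in mm, in acquisition order.
#' @export
line_trajectory <- function(geometry, jitter, line_index,
                            direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (line_index < 0 || line_index >= geometry$n_lines)
    stop("line_index outside the scan")
  L <- geometry$fov_x_mm
  grid <- seq(0, L, length.out = geometry$n_fast)
  if (direction == "forward") return(grid)
  lag <- realized_lag(jitter, line_index, geometry$n_lines)
  pos <- rev(grid) - lag * L
  a <- jitter$distortion_coeffs
  if (length(a) && any(a != 0)) {
    warp <- 0
    for (k in seq_along(a)) warp <- warp + a[k] * L * sin(k * pi * pos / L)
    pos <- pos + warp
  }
  if (any(diff(pos) >= 0))
    stop("invalid jitter: warp folds the backward trajectory over")
  pos
}
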