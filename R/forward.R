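# Forward vascular model and the GRE signal transform.
#
# The tissue concentration model is
#   c(t) = CBF * integral_0^t Ca(tau) R(t - delay - tau) dtau
#        + K_app * integral_0^t Ca(tau) dtau
# with R(t) = 1 - GammaCDF(t; alpha, beta) the residue function. CBF enters
# in ml/100 ml/min (divided by 6000 to give s^-1) and K_app in 1/min
# (divided by 60), so that concentration shares the relaxation-rate units
# of the AIF. The convolution is evaluated by the trapezoidal rule on a
# grid upsampled by an integer factor relative to the frame grid and then
# decimated back to the frames; the same operator is used by the generator
# and the fitter, so discretisation is a shared, documented approximation
# rather than a source of fitting bias.

# Upsampled-grid machinery shared by generation and fitting. `aif` is
# sampled on `time_grid`; the fine AIF is linear interpolation.
fine_grid <- function(aif, time_grid, upsample) {
  dt_frame <- grid_step(time_grid)
  upsample <- as.integer(upsample)
  if (upsample < 1L) stopf("upsample factor must be >= 1")
  n <- length(time_grid)
  t_fine <- seq(0, time_grid[n], by = dt_frame / upsample)
  a_fine <- if (upsample == 1L) aif else stats::approx(time_grid, aif, xout = t_fine)$y
  list(t = t_fine, a = a_fine, dt = dt_frame / upsample,
       frame_index = seq(1L, length(t_fine), by = upsample),
       cum = cumtrapz_uniform(a_fine, dt_frame / upsample))
}

# Model curve at frame times given a prepared fine grid.
model_curve <- function(fg, cbf, alpha, beta, k_app, delay) {
  f <- cbf / 6000           # ml/100ml/min -> 1/s
  k <- k_app / 60           # 1/min -> 1/s
  r <- 1 - stats::pgamma(fg$t, shape = alpha, scale = beta)
  y <- conv_trapz(fg$a, r, fg$dt)
  lag <- as.integer(round(delay / fg$dt))
  if (lag > 0) y <- c(numeric(lag), y[seq_len(length(y) - lag)])
  (f * y + k * fg$cum)[fg$frame_index]
}

#' Forward tissue concentration curve of the vascular model
#'
#' Generates the noiseless tissue concentration time course implied by a
#' set of ground-truth voxel parameters: the AIF convolved with the gamma
#' residue function, scaled by CBF and shifted by the voxel delay, plus the
#' leakage term `K_app` times the running integral of the AIF.
#'
#' @param aif arterial input concentration sampled on `time_grid`.
#' @param truth a [ground_truth_voxel()].
#' @param acq an [acquisition_params()] object (kappa is applied and, being
#'   1 by default, leaves concentrations unscaled).
#' @param time_grid uniform, strictly increasing frame time grid (seconds).
#' @param upsample integer upsampling factor for the internal convolution
#'   grid (default 4).
#' @return Concentration vector on `time_grid`.
#' @export
forward_tissue_curve <- function(aif, truth, acq, time_grid, upsample = 4) {
  stopifnot(inherits(truth, "ground_truth_voxel"),
            inherits(acq, "acquisition_params"))
  if (length(aif) != length(time_grid))
    stopf("aif and time_grid must have the same length (%d vs %d)",
          length(aif), length(time_grid))
  fg <- fine_grid(aif, time_grid, upsample)
  acq$kappa * model_curve(fg, truth$cbf, truth$alpha, truth$beta,
                          truth$k_app, truth$delay)
}

#' Convert a concentration curve to a GRE signal curve
#'
#' Single-echo gradient-echo transform `S(t) = s0 * exp(-TE * C(t))` with
#' optional additive zero-mean Gaussian noise. With `noise_sigma = 0` the
#' transform is exactly inverted by [signal_to_concentration()].
#'
#' @param conc concentration vector (relaxation-rate units, s^-1).
#' @param s0 baseline signal, positive.
#' @param te echo time, seconds.
#' @param noise_sigma standard deviation of the additive signal noise.
#' @param seed optional seed for the noise draw; when supplied the caller's
#'   RNG state is left untouched.
#' @return Signal vector of the same length as `conc`.
#' @export
concentration_to_signal <- function(conc, s0, te, noise_sigma = 0, seed = NULL) {
  if (s0 <= 0) stopf("s0 must be positive")
  if (te <= 0) stopf("te must be positive")
  if (noise_sigma < 0) stopf("noise_sigma must be non-negative")
  s <- s0 * exp(-te * conc)
  if (noise_sigma > 0) {
    eps <- if (is.null(seed)) stats::rnorm(length(s), 0, noise_sigma)
           else with_seed(seed, stats::rnorm(length(s), 0, noise_sigma))
    s <- s + eps
  }
  s
}

#' Convert DSC signal to contrast concentration
#'
#' Per voxel, the baseline signal S0 is the mean of the pre-bolus frames
#' (frame 1 is excluded when more than one baseline frame is configured)
#' and the concentration is the relaxation-rate change
#' `C(t) = -log(S(t)/S0) / TE`. Voxels whose baseline is not positive
#' (including all-zero voxels) are marked missing (`NA`) rather than
#' raising an error.
#'
#' @param signal a numeric vector (one voxel) or a 4D array (x, y, z, t).
#' @param acq an [acquisition_params()] object.
#' @return An object of the same shape as `signal` holding concentrations,
#'   with the baseline estimate attached as attribute `"s0"` (scalar for a
#'   vector input, 3D array for a 4D input).
#' @export
signal_to_concentration <- function(signal, acq) {
  stopifnot(inherits(acq, "acquisition_params"))
  bl <- baseline_frame_index(acq)
  if (is.null(dim(signal)) || length(dim(signal)) == 1L) {
    if (length(signal) != acq$n_dynamics)
      stopf("signal has %d frames but acquisition declares %d",
            length(signal), acq$n_dynamics)
    s0 <- mean(signal[bl])
    if (!is.finite(s0) || s0 <= 0) {
      conc <- rep(NA_real_, length(signal))
    } else {
      ratio <- signal / s0
      ratio[ratio <= 0] <- NA_real_
      conc <- -log(ratio) / acq$te
    }
    attr(conc, "s0") <- s0
    return(conc)
  }
  dims <- dim(signal)
  if (length(dims) != 4L)
    stopf("signal must be a vector or a 4D array (x, y, z, t)")
  if (dims[4] != acq$n_dynamics)
    stopf("signal has %d frames but acquisition declares %d", dims[4], acq$n_dynamics)
  nvox <- prod(dims[1:3])
  mat <- matrix(signal, nrow = nvox, ncol = dims[4])
  s0 <- rowMeans(mat[, bl, drop = FALSE])
  bad <- !is.finite(s0) | s0 <= 0
  ratio <- mat / s0
  ratio[ratio <= 0] <- NA_real_
  conc <- -log(ratio) / acq$te
  conc[bad, ] <- NA_real_
  out <- array(conc, dims)
  attr(out, "s0") <- array(ifelse(bad, NA_real_, s0), dims[1:3])
  out
}

baseline_frame_index <- function(acq) {
  if (acq$baseline_frames >= 2L) 2:acq$baseline_frames else 1L
}
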