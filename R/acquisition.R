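#' DSC acquisition parameters
#'
#' Container for the gradient-echo EPI acquisition settings that the signal
#' model and the concentration conversion depend on. Defaults follow a
#' typical clinical bolus-tracking protocol: TR 1.5 s, TE 40 ms, 80 dynamic
#' frames, with the proportionality constant kappa (haematocrit and tissue
#' density term of the vascular model) set to unity so that CBF is reported
#' in arbitrary units unless calibrated.
#'
#' @param tr repetition time in seconds.
#' @param te echo time in seconds.
#' @param n_dynamics number of dynamic frames.
#' @param kappa dimensionless proportionality constant of the vascular model.
#' @param baseline_frames number of pre-bolus frames used to estimate the
#'   baseline signal S0. Frame 1 is excluded from the baseline average when
#'   more than one baseline frame is available (signal not yet in steady
#'   state).
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(tr = 1.5, te = 0.040, n_dynamics = 80,
                               kappa = 1, baseline_frames = 8) {
  if (tr <= 0) stopf("tr must be positive")
  if (te <= 0) stopf("te must be positive")
  if (kappa <= 0) stopf("kappa must be positive")
  baseline_frames <- as.integer(baseline_frames)
  n_dynamics <- as.integer(n_dynamics)
  if (baseline_frames < 1L) stopf("baseline_frames must be >= 1")
  if (n_dynamics < baseline_frames) stopf("n_dynamics must be >= baseline_frames")
  structure(list(tr = tr, te = te, n_dynamics = n_dynamics,
                 kappa = kappa, baseline_frames = baseline_frames),
            class = "acquisition_params")
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat(sprintf("DSC acquisition: TR %.3g s, TE %.3g s, %d dynamics (%d baseline), kappa = %g\n",
              x$tr, x$te, x$n_dynamics, x$baseline_frames, x$kappa))
  invisible(x)
}

#' Frame time grid of an acquisition
#'
#' @param acq an [acquisition_params()] object.
#' @return Numeric vector of frame times starting at 0, spaced by TR.
#' @export
frame_times <- function(acq) {
  (seq_len(acq$n_dynamics) - 1) * acq$tr
}

#' Gamma-variate arterial input function model
#'
#' Parametric model of the arterial contrast concentration time course
#' C_a(t): a gamma-variate bolus with peak value `amplitude` at
#' `arrival_time + shape * scale`, plus an optional recirculation bump of
#' the same shape delayed by `recirculation_delay` and scaled by
#' `recirculation_fraction`.
#'
#' @param amplitude peak concentration, arbitrary relaxation-rate units
#'   (s^-1).
#' @param arrival_time bolus arrival time in seconds.
#' @param shape dimensionless gamma-variate shape parameter.
#' @param scale gamma-variate time scale in seconds.
#' @param recirculation_fraction amplitude fraction of the recirculation
#'   bump, in `[0, 1)`.
#' @param recirculation_delay delay of the recirculation bump in seconds.
#' @return An object of class `aif_model`.
#' @export
aif_model <- function(amplitude = 30, arrival_time = 12, shape = 3,
                      scale = 1.5, recirculation_fraction = 0,
                      recirculation_delay = 20) {
  if (amplitude < 0) stopf("amplitude must be non-negative")
  if (arrival_time < 0) stopf("arrival_time must be non-negative")
  if (shape <= 0) stopf("shape must be positive")
  if (scale <= 0) stopf("scale must be positive")
  if (recirculation_fraction < 0 || recirculation_fraction >= 1)
    stopf("recirculation_fraction must lie in [0, 1)")
  structure(list(amplitude = amplitude, arrival_time = arrival_time,
                 shape = shape, scale = scale,
                 recirculation_fraction = recirculation_fraction,
                 recirculation_delay = recirculation_delay),
            class = "aif_model")
}

#' @export
print.aif_model <- function(x, ...) {
  cat(sprintf("Gamma-variate AIF: peak %g at t = %g s (arrival %g s, shape %g, scale %g s)\n",
              x$amplitude, x$arrival_time + x$shape * x$scale,
              x$arrival_time, x$shape, x$scale))
  if (x$recirculation_fraction > 0)
    cat(sprintf("  recirculation: fraction %g, delay %g s\n",
                x$recirculation_fraction, x$recirculation_delay))
  invisible(x)
}

gamma_variate <- function(t, amplitude, arrival, shape, scale) {
  u <- (t - arrival) / scale
  out <- numeric(length(t))
  pos <- u > 0
  # normalised so the peak value equals `amplitude` at u = shape
  out[pos] <- amplitude * (u[pos] / shape)^shape * exp(shape - u[pos])
  out
}

#' Sample an arterial input function on a time grid
#'
#' @param model an [aif_model()] object.
#' @param time_grid strictly increasing time grid starting at 0 (seconds).
#' @return Concentration vector sampled on `time_grid`; zero before the
#'   arrival time, non-negative everywhere.
#' @export
make_aif <- function(model, time_grid) {
  stopifnot(inherits(model, "aif_model"))
  if (length(time_grid) < 2 || is.unsorted(time_grid, strictly = TRUE))
    stopf("time_grid must be strictly increasing")
  if (time_grid[1] != 0) stopf("time_grid must start at 0")
  ca <- gamma_variate(time_grid, model$amplitude, model$arrival_time,
                      model$shape, model$scale)
  if (model$recirculation_fraction > 0) {
    ca <- ca + gamma_variate(time_grid,
                             model$amplitude * model$recirculation_fraction,
                             model$arrival_time + model$recirculation_delay,
                             model$shape, model$scale)
  }
  ca
}

#' Ground-truth voxel parameters
#'
#' The generative parameters of one voxel of a synthetic phantom: the
#' vascular model parameters plus the baseline signal used by the GRE
#' signal transform.
#'
#' @param cbf cerebral blood flow, ml/100 ml/min.
#' @param alpha gamma transit-time shape parameter (dimensionless).
#' @param beta gamma transit-time scale parameter (seconds).
#' @param k_app apparent leakage rate, 1/min (sign-unconstrained).
#' @param delay bolus delay relative to the AIF, seconds.
#' @param s0 baseline signal, arbitrary units.
#' @return An object of class `ground_truth_voxel`.
#' @export
ground_truth_voxel <- function(cbf, alpha, beta, k_app = 0, delay = 0, s0 = 100) {
  if (cbf < 0) stopf("cbf must be non-negative")
  if (alpha <= 0 || beta <= 0) stopf("alpha and beta must be positive")
  if (delay < 0) stopf("delay must be non-negative")
  if (s0 <= 0) stopf("s0 must be positive")
  structure(list(cbf = cbf, alpha = alpha, beta = beta, k_app = k_app,
                 delay = delay, s0 = s0),
            class = "ground_truth_voxel")
}

#' Gamma transit-time distribution
#'
#' The transit-time law of the vascular model: a gamma distribution with
#' shape `alpha` and scale `beta` whose mean is the mean transit time
#' (MTT = alpha * beta) and whose standard deviation is the capillary
#' transit time heterogeneity (CTH = sqrt(alpha) * beta).
#'
#' @param alpha shape parameter, dimensionless, > 0.
#' @param beta scale parameter, seconds, > 0.
#' @return An object of class `transit_distribution`.
#' @export
transit_distribution <- function(alpha, beta) {
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0)
    stopf("alpha and beta must be positive and finite")
  structure(list(alpha = alpha, beta = beta), class = "transit_distribution")
}

#' @export
print.transit_distribution <- function(x, ...) {
  s <- transit_stats(x)
  cat(sprintf("Gamma transit time law: alpha %.4g, beta %.4g s (MTT %.4g s, CTH %.4g s, RTH %.3g)\n",
              x$alpha, x$beta, s$mtt, s$cth, s$rth))
  invisible(x)
}

#' Convert transit-time moments to gamma parameters
#'
#' Inverse of the moment map: `alpha = (mtt/cth)^2`, `beta = cth^2/mtt`.
#'
#' @param mtt mean transit time, seconds.
#' @param cth transit time heterogeneity (SD), seconds.
#' @return A [transit_distribution()].
#' @export
gamma_from_moments <- function(mtt, cth) {
  if (mtt <= 0 || cth <= 0) stopf("mtt and cth must be positive")
  transit_distribution(alpha = (mtt / cth)^2, beta = cth^2 / mtt)
}
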