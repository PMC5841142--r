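# Shared fixtures: all synthetic, built in code at test time.

quick_acq <- function(...) acquisition_params(...)

quick_aif <- function(...) aif_model(...)

# standard frame grid + sampled AIF used across tests
std_setup <- function(acq = quick_acq(), aif = quick_aif()) {
  tg <- frame_times(acq)
  list(acq = acq, aif_model = aif, time = tg, aif = make_aif(aif, tg))
}

# noiseless tissue curve for given truth parameters
noiseless_curve <- function(setup, cbf, alpha, beta, k_app = 0, delay = 0) {
  truth <- ground_truth_voxel(cbf = cbf, alpha = alpha, beta = beta,
                              k_app = k_app, delay = delay)
  forward_tissue_curve(setup$aif, truth, setup$acq, setup$time)
}

# fit options used for phantom studies (no arrival dispersion in the
# generator, so the delay grid is degenerate at zero)
phantom_opts <- function(...) {
  fit_options(n_multistart = 3, delay_grid = 0, ...)
}

# single-region phantom spec with the given region parameters
one_region_spec <- function(rp, dims = c(4, 4, 1), ...) {
  phantom_spec(array(1L, dims), list(`1` = rp), ...)
}

# brute-force ROI accumulation oracle (independent of roi_mean internals)
brute_roi_stats <- function(map, roi) {
  acc <- c()
  dims <- dim(map)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    if (roi[i, j, k] && is.finite(map[i, j, k])) acc <- c(acc, map[i, j, k])
  }
  list(n = length(acc), mean = mean(acc), sd = stats::sd(acc))
}
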