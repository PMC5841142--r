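test_that("noiseless forward curves are inverted to the generating parameters", {
  s <- std_setup()
  conc <- noiseless_curve(s, cbf = 60, alpha = 4, beta = 1)
  fit <- fit_voxel(conc, s$aif, s$time, phantom_opts())
  cf <- coef(fit)
  expect_true(fit$converged)
  expect_lt(abs(cf[["cbf"]] - 60) / 60, 0.01)
  expect_lt(abs(cf[["alpha"]] - 4) / 4, 0.01)
  expect_lt(abs(cf[["beta"]] - 1) / 1, 0.01)
  expect_lt(abs(cf[["k_app"]]), 1e-4)
  st <- transit_stats(fit$transit)
  expect_equal(st$mtt, 4, tolerance = 1e-3)
  expect_equal(st$cth, 2, tolerance = 1e-3)
})

test_that("a leakage-only curve pins K_app with CBF at its floor", {
  s <- std_setup()
  conc <- noiseless_curve(s, cbf = 0, alpha = 4, beta = 1, k_app = 0.05)
  fit <- fit_voxel(conc, s$aif, s$time, phantom_opts())
  cf <- coef(fit)
  expect_lt(abs(cf[["k_app"]] - 0.05) / 0.05, 0.01)
  expect_lt(cf[["cbf"]], 0.5)
})

test_that("an all-zero curve yields a zero-flow converged fit", {
  s <- std_setup()
  fit <- fit_voxel(rep(0, length(s$time)), s$aif, s$time, phantom_opts())
  expect_lt(coef(fit)[["cbf"]], 1e-6)
  expect_lt(fit$rss, 1e-12)
  expect_false(fit$missing)
})

test_that("adding a leakage term moves only K_app (separability)", {
  s <- std_setup()
  base <- noiseless_curve(s, cbf = 60, alpha = 4, beta = 1, k_app = 0)
  k_extra <- 0.3
  cum <- noiseless_curve(s, cbf = 0, alpha = 4, beta = 1, k_app = k_extra)
  f0 <- fit_voxel(base, s$aif, s$time, phantom_opts())
  f1 <- fit_voxel(base + cum, s$aif, s$time, phantom_opts())
  expect_lt(abs(coef(f1)[["k_app"]] - coef(f0)[["k_app"]] - k_extra) / k_extra,
            0.01)
  for (p in c("cbf", "alpha", "beta")) {
    expect_lt(abs(coef(f1)[[p]] - coef(f0)[[p]]) / coef(f0)[[p]], 0.01)
  }
})

test_that("jointly rescaling AIF and tissue curve leaves all parameters fixed", {
  s <- std_setup()
  conc <- noiseless_curve(s, cbf = 45, alpha = 2, beta = 2.2, k_app = 0.02)
  f1 <- fit_voxel(conc, s$aif, s$time, phantom_opts())
  f2 <- fit_voxel(3.7 * conc, 3.7 * s$aif, s$time, phantom_opts())
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
})

test_that("true nonzero delays on the grid are recovered exactly without noise", {
  s <- std_setup()
  conc <- noiseless_curve(s, cbf = 50, alpha = 2, beta = 2, delay = 1.5)
  fit <- fit_voxel(conc, s$aif, s$time,
                   fit_options(n_multistart = 3, delay_grid = c(0, 0.75, 1.5)))
  cf <- coef(fit)
  expect_equal(cf[["delay"]], 1.5)
  expect_lt(abs(cf[["cbf"]] - 50) / 50, 0.01)
  expect_lt(abs(cf[["alpha"]] - 2) / 2, 0.01)
})

test_that("missing and degenerate curves propagate without errors", {
  s <- std_setup()
  fit <- fit_voxel(rep(NA_real_, length(s$time)), s$aif, s$time, phantom_opts())
  expect_true(fit$missing)
  expect_false(fit$converged)
  expect_true(all(is.na(coef(fit))))
  expect_error(fit_voxel(rep(0, 12), s$aif[1:12], s$time[1:12], phantom_opts()),
               "post-bolus")
})

test_that("vascular_fit methods behave like a classical model object", {
  s <- std_setup()
  conc <- noiseless_curve(s, cbf = 60, alpha = 4, beta = 1)
  fit <- fit_voxel(conc, s$aif, s$time, phantom_opts())
  expect_equal(fitted(fit), predict(fit))
  expect_equal(residuals(fit), conc - fitted(fit))
  expect_lt(max(abs(residuals(fit))), 1e-6)
  fine <- predict(fit, time_grid = seq(0, 60, by = 0.75))
  expect_equal(length(fine), 81)
  sims <- simulate(fit, nsim = 3, seed = 5)
  expect_equal(dim(sims), c(length(s$time), 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 5))
  expect_output(print(fit), "Vascular model fit")
  expect_output(print(summary(fit, oxygen = oxygen_params())), "OEC")
})

test_that("volume fitting is order-independent and propagates missingness", {
  s <- std_setup()
  conc <- noiseless_curve(s, cbf = 60, alpha = 4, beta = 1)
  arr <- array(NA_real_, c(3, 1, 1, length(s$time)))
  arr[1, 1, 1, ] <- conc
  arr[2, 1, 1, ] <- conc                    # identical curve
  arr[3, 1, 1, ] <- NA_real_                # missing voxel
  mask <- array(TRUE, c(3, 1, 1))
  res <- fit_volume(arr, s$aif, mask, s$time, phantom_opts())
  for (nm in c("cbf", "mtt", "cth", "k_app")) {
    expect_equal(res$maps[[nm]][1, 1, 1], res$maps[[nm]][2, 1, 1])
    expect_true(is.na(res$maps[[nm]][3, 1, 1]))
  }
  expect_warning(
    empty <- fit_volume(arr, s$aif, array(FALSE, c(3, 1, 1)), s$time,
                        phantom_opts()),
    "empty mask")
  expect_true(all(is.na(empty$maps$cbf)))
})
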