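test_that("single-capillary extraction obeys limits and closed forms", {
  p_exp <- oxygen_params("exponential", rate_k = 0.5)
  expect_equal(capillary_extraction(0, p_exp), 0)
  expect_equal(capillary_extraction(2, p_exp), 1 - exp(-1), tolerance = 1e-12)

  p <- oxygen_params()
  expect_equal(capillary_extraction(0, p), 0)
  taus <- seq(0, 60, by = 0.5)
  q <- capillary_extraction(taus, p)
  expect_true(all(q >= 0 & q <= 1))
  expect_true(all(diff(q) >= -1e-12))            # non-decreasing
  expect_true(all(diff(diff(q)) <= 1e-8))        # concave
  expect_error(capillary_extraction(-1, p), "non-negative")
})

test_that("BKCR extraction matches an independent stiff ODE integration", {
  p <- oxygen_params()
  ode_oracle <- function(tau) {
    f <- function(x, S, parms)
      list(-p$rate_k * tau * (p$p50 * (S / (1 - S))^(1 / p$hill_h) - p$tissue_pt))
    out <- deSolve::ode(y = c(S = p$arterial_saturation), times = c(0, 1),
                        func = f, method = "lsoda", rtol = 1e-11, atol = 1e-13)
    (p$arterial_saturation - out[nrow(out), 2]) / p$arterial_saturation
  }
  for (tau in c(0.5, 2, 4, 10, 40)) {
    expect_lt(abs(capillary_extraction(tau, p) - ode_oracle(tau)), 1e-6)
  }
})

test_that("OEC quadrature reproduces the exponential-mode closed form", {
  p <- oxygen_params("exponential", rate_k = 1)
  expect_equal(oec(transit_distribution(2, 1), p), 0.75, tolerance = 1e-10)
  for (ab in list(c(0.5, 4), c(3, 0.7), c(10, 0.3))) {
    closed <- 1 - (1 + 1 * ab[2])^(-ab[1])
    expect_lt(abs(oec(transit_distribution(ab[1], ab[2]), p) - closed), 1e-10)
  }
})

test_that("vanishing heterogeneity collapses OEC onto Q(MTT)", {
  p <- oxygen_params()
  mtt <- 4
  alpha <- 1e6
  expect_lt(abs(oec(transit_distribution(alpha, mtt / alpha), p) -
                  capillary_extraction(mtt, p)), 1e-4)
})

test_that("full-mode OEC agrees with a large Monte-Carlo average", {
  p <- oxygen_params()
  set.seed(202)
  draws <- stats::rgamma(1e6, shape = 4, scale = 1)
  q <- capillary_extraction(draws, p)
  mc_se <- stats::sd(q) / sqrt(1e6)
  expect_lt(abs(mean(q) - oec(transit_distribution(4, 1), p)), 3 * mc_se)
})

test_that("CMRO2max is the CBF x OEC product with optional O2 content", {
  expect_equal(cmro2max(50, 0.3), 15)
  expect_equal(cmro2max(50, 0), 0)
  expect_equal(cmro2max(50, 0.3, arterial_o2_content = 0.19), 15 * 0.19)
  expect_error(cmro2max(-1, 0.3), "non-negative")
})

test_that("oxygen maps reconstruct the gamma law from moments and propagate NA", {
  p <- oxygen_params()
  dims <- c(2, 2, 1)
  maps <- perfusion_maps(cbf = array(50, dims),
                         mtt = array(4, dims),
                         cth = array(2, dims),
                         k_app = array(0, dims))
  maps$mtt[2, 2, 1] <- NA                # missing voxel
  maps$cth[1, 2, 1] <- 2.5               # different heterogeneity
  out <- oxygen_maps(maps, p)
  # mtt=4, cth=2 is exactly alpha=4, beta=1
  expect_equal(out$oec[1, 1, 1], oec(transit_distribution(4, 1), p),
               tolerance = 1e-9)
  expect_equal(out$cmro2max[1, 1, 1], 50 * out$oec[1, 1, 1])
  expect_true(is.na(out$oec[2, 2, 1]) && is.na(out$cmro2max[2, 2, 1]))
  # uniform voxels give a uniform map
  expect_equal(out$oec[2, 1, 1], out$oec[1, 1, 1])
  # higher CTH at equal MTT lowers OEC
  expect_lt(out$oec[1, 2, 1], out$oec[1, 1, 1])
})

test_that("CBF calibration inverts the oxygen model at committed defaults", {
  p <- oxygen_params()
  cbf <- calibrate_cbf(15.78, 4.5, 3.2, p)
  expect_equal(cbf * oec(gamma_from_moments(4.5, 3.2), p), 15.78,
               tolerance = 1e-9)
})
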