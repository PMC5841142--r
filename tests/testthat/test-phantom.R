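test_that("zero-spread zero-noise phantoms are homogeneous and deterministic", {
  rp <- region_params(cbf = 60, mtt = 4, cth = 2, k_app = 0)
  spec <- one_region_spec(rp, dims = c(2, 2, 1), seed = 5)
  ph1 <- make_region_phantom(spec, with_oxygen = FALSE)
  sig <- matrix(ph1$signal, nrow = 4)
  for (v in 2:4) expect_equal(sig[v, ], sig[1, ])
  expect_equal(unique(as.vector(ph1$truth$cth)), 2)

  ph2 <- make_region_phantom(spec, with_oxygen = FALSE)
  expect_identical(ph1$signal, ph2$signal)

  # different seed with spread/noise gives different draws
  rp2 <- region_params(cbf = 60, mtt = 4, cth = 2, cth_sd = 0.4)
  pha <- make_region_phantom(one_region_spec(rp2, seed = 1, noise_sigma = 0.5),
                             with_oxygen = FALSE)
  phb <- make_region_phantom(one_region_spec(rp2, seed = 2, noise_sigma = 0.5),
                             with_oxygen = FALSE)
  expect_false(identical(pha$signal, phb$signal))
})

test_that("phantom generation is a pure function that restores the caller RNG", {
  set.seed(42)
  before <- .Random.seed
  rp <- region_params(cbf = 60, mtt = 4, cth = 2, cth_sd = 0.3)
  make_region_phantom(one_region_spec(rp, seed = 9, noise_sigma = 1),
                      with_oxygen = FALSE)
  expect_identical(.Random.seed, before)
})

test_that("unparameterised labels are a configuration error", {
  labs <- array(c(1L, 2L), c(2, 1, 1))
  expect_error(phantom_spec(labs, list(`1` = region_params(60, 4, 2))),
               "labels without parameters")
})

test_that("nine-region ground truth follows the lesion-probability ranking", {
  params <- default_region_params("hemizygote")
  # the assigned parameter means decrease along the probability ranking
  cth_means <- vapply(as.character(1:9), function(lb) params[[lb]]$cth, 1)
  expect_true(all(diff(cth_means) < 0))
  expect_equal(cth_means[[1]], 4.00)
  expect_equal(cth_means[[9]], 2.92)

  # through the generator, with spreads silenced, region means rank exactly
  frozen <- lapply(params, function(rp)
    region_params(cbf = rp$cbf, mtt = rp$mtt, cth = rp$cth, k_app = rp$k_app))
  attr(frozen, "region_names") <- attr(params, "region_names")
  labels <- block_labels(10, block = c(3, 3, 1), ncol = 4)
  ph <- make_region_phantom(phantom_spec(labels, frozen, seed = 3),
                            with_oxygen = FALSE)
  means <- vapply(1:9, function(lb) mean(ph$truth$cth[ph$labels == lb]), 1)
  expect_equal(order(means, decreasing = TRUE), 1:9)
  # thalamus reference well below white matter
  expect_lt(mean(ph$truth$cth[ph$labels == 10]), 1.2)
})

test_that("snr specification scales noise to the bolus depth", {
  rp <- region_params(cbf = 60, mtt = 4, cth = 2)
  ph <- make_region_phantom(one_region_spec(rp, dims = c(3, 3, 1), snr = 20,
                                            seed = 4), with_oxygen = FALSE)
  expect_gt(ph$noise_sigma, 0)
  clean <- make_region_phantom(one_region_spec(rp, dims = c(3, 3, 1), seed = 4),
                               with_oxygen = FALSE)
  depth <- mean(apply(matrix(100 - matrix(clean$signal, nrow = 9), nrow = 9),
                      1, max))
  expect_equal(ph$noise_sigma, depth / 20, tolerance = 1e-9)
})

test_that("ground-truth oxygen maps accompany the kinetic truth", {
  rp <- region_params(cbf = 60, mtt = 4, cth = 2)
  ph <- make_region_phantom(one_region_spec(rp, dims = c(2, 1, 1), seed = 1))
  expect_equal(ph$truth$oec[1, 1, 1],
               oec(transit_distribution(4, 1), oxygen_params()),
               tolerance = 1e-9)
  expect_equal(ph$truth$cmro2max[1, 1, 1], 60 * ph$truth$oec[1, 1, 1])
})
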