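test_that("probability atlas counts are exact rational fractions", {
  d <- c(4, 4, 1)
  m1 <- array(FALSE, d); m1[1:2, 1:2, 1] <- TRUE
  m2 <- array(FALSE, d); m2[2, 2, 1] <- TRUE
  atlas <- build_probability_atlas(list(m1, m2))
  expect_equal(atlas$probability[2, 2, 1], 1.0)
  expect_equal(atlas$probability[1, 1, 1], 0.5)
  expect_equal(atlas$probability[4, 4, 1], 0)

  single <- build_probability_atlas(list(m1))
  expect_equal(single$probability, m1 * 1)

  set.seed(31)
  masks <- lapply(1:35, function(i) array(stats::runif(60) < 0.3, c(5, 4, 3)))
  a35 <- build_probability_atlas(masks)
  counts <- a35$probability * 35
  expect_lt(max(abs(counts - round(counts))), 1e-9)
  # brute-force count at every voxel
  brute <- Reduce(`+`, lapply(masks, function(m) m * 1))
  expect_equal(counts, brute, tolerance = 1e-12)

  expect_error(build_probability_atlas(list(m1, array(FALSE, c(2, 2, 1)))),
               "dimensions")
  expect_error(build_probability_atlas(list()), "non-empty")
})

test_that("atlas construction is linear in subject pooling", {
  set.seed(7)
  g1 <- lapply(1:4, function(i) array(stats::runif(24) < 0.4, c(4, 3, 2)))
  g2 <- lapply(1:6, function(i) array(stats::runif(24) < 0.4, c(4, 3, 2)))
  a1 <- build_probability_atlas(g1)
  a2 <- build_probability_atlas(g2)
  pooled <- build_probability_atlas(c(g1, g2))
  expect_equal(pooled$probability,
               (4 * a1$probability + 6 * a2$probability) / 10,
               tolerance = 1e-12)
})

test_that("region probabilities rank a splenium-weighted synthetic atlas first", {
  labels <- block_labels(9, block = c(3, 3, 1), ncol = 3)
  rois <- region_rois(labels, n_voxels = 9)
  # subject masks always cover region 1, progressively less often the rest
  set.seed(11)
  masks <- lapply(1:20, function(i) {
    m <- array(FALSE, dim(labels))
    for (r in 1:9) if (stats::runif(1) < 1.05 - r * 0.11) m[labels == r] <- TRUE
    m
  })
  atlas <- build_probability_atlas(masks)
  probs <- vapply(1:9, function(r) region_probability(atlas, rois[[r]]), 1)
  expect_equal(which.max(probs), 1L)

  zero_roi <- array(FALSE, dim(labels)); zero_roi[1, 1, 1] <- TRUE
  expect_equal(region_probability(atlas, zero_roi), 0)
  expect_error(region_probability(atlas, array(FALSE, dim(labels))), "empty")
})

test_that("toy nested squares segment into zones with hand-computed counts", {
  dims <- c(21, 21, 1)
  lesion <- array(FALSE, dims); lesion[6:16, 6:16, 1] <- TRUE      # 11x11 = 121
  enh <- array(FALSE, dims); enh[9:13, 9:13, 1] <- TRUE            # 5x5 = 25
  enh[10:12, 10:12, 1] <- FALSE                                    # ring of 16
  wm <- array(TRUE, dims)
  z <- segment_lesion_zones(lesion, enh, wm, ring_width = 2, margin = 4)
  expect_equal(sum(z$zone_b), 16)                                  # enhancing ring
  expect_equal(sum(z$zone_a), 9)                                   # enclosed 3x3 core
  expect_equal(sum(z$zone_c), 121 - 16 - 9)
  expect_equal(sum(z$zone_d), 15^2 - 11^2)                         # dilation ring
  expect_equal(sum(z$zone_e), 21^2 - 19^2)                         # beyond margin 4
})

test_that("degenerate zone inputs follow the stated policies", {
  dims <- c(10, 10, 1)
  lesion <- array(FALSE, dims); lesion[4:7, 4:7, 1] <- TRUE
  wm <- array(TRUE, dims)
  z <- segment_lesion_zones(lesion, NULL, wm, ring_width = 0, margin = 2)
  expect_equal(sum(z$zone_a), 0)
  expect_equal(sum(z$zone_b), 0)
  expect_equal(sum(z$zone_c), sum(lesion))
  expect_equal(sum(z$zone_d), 0)                                   # ring width 0

  expect_warning(z0 <- segment_lesion_zones(array(FALSE, dims), NULL, wm),
                 "empty lesion")
  expect_equal(sum(z0$zone_c), 0)

  enh_out <- array(FALSE, dims); enh_out[1, 1, 1] <- TRUE
  expect_warning(segment_lesion_zones(lesion, enh_out, wm), "clipped")
})

test_that("zone partition invariants hold on random geometries", {
  set.seed(17)
  for (rep in 1:5) {
    dims <- c(15, 15, 2)
    lesion <- array(FALSE, dims)
    cx <- sample(5:10, 1); cy <- sample(5:10, 1); h <- sample(2:4, 1)
    lesion[(cx - h):(cx + h), (cy - h):(cy + h), ] <- TRUE
    enh <- lesion & array(stats::runif(prod(dims)) < 0.3, dims)
    wm <- array(TRUE, dims)
    z <- segment_lesion_zones(lesion, enh, wm, ring_width = 2, margin = 4)
    expect_identical(z$zone_a | z$zone_b | z$zone_c, lesion)
    expect_equal(sum((z$zone_d | z$zone_e) & lesion), 0)
    expect_equal(sum(z$zone_d & z$zone_e), 0)
  }
})

test_that("progression partitions are exact set operations", {
  dims <- c(8, 8, 1)
  zone <- array(FALSE, dims); zone[2:5, 2:5, 1] <- TRUE
  fu_all <- array(TRUE, dims)
  p1 <- partition_progression(zone, fu_all)
  expect_identical(p1$converting, zone)
  expect_equal(sum(p1$nonconverting), 0)

  fu_none <- array(FALSE, dims)
  p2 <- partition_progression(zone, fu_none)
  expect_equal(sum(p2$converting), 0)
  expect_identical(p2$nonconverting, zone)

  set.seed(3)
  fu <- array(stats::runif(prod(dims)) < 0.5, dims)
  p3 <- partition_progression(zone, fu)
  expect_identical(p3$converting | p3$nonconverting, zone)
  expect_equal(sum(p3$converting & p3$nonconverting), 0)
})

test_that("lesion phantom progression mirrors the designed CTH contrast", {
  ph <- make_lesion_phantom(geometry = lesion_geometry(dims = c(20, 20, 2),
                                                       core_half = 1,
                                                       lesion_half = 4),
                            seed = 21)
  parts <- partition_progression(ph$zones$zone_d, ph$masks$t2_followup)
  cth <- ph$baseline$truth$cth
  expect_gt(mean(cth[parts$converting]), mean(cth[parts$nonconverting]))
})

test_that("ROI statistics match closed forms and a brute-force oracle", {
  dims <- c(4, 3, 2)
  roi <- array(FALSE, dims); roi[1:2, 1, 1] <- TRUE
  uni <- array(7, dims)
  st <- roi_mean(uni, roi)
  expect_equal(st$mean, 7); expect_equal(st$sd, 0)

  two <- array(NA_real_, dims); two[1, 1, 1] <- 1; two[2, 1, 1] <- 3
  st2 <- roi_mean(two, roi)
  expect_equal(st2$mean, 2)
  expect_equal(st2$sd, sqrt(2))
  expect_equal(st2$n_voxels, 2)

  set.seed(5)
  noisy <- array(stats::rnorm(prod(dims)), dims)
  noisy[sample(prod(dims), 5)] <- NA
  big_roi <- array(stats::runif(prod(dims)) < 0.7, dims)
  if (any(big_roi & is.finite(noisy))) {
    st3 <- roi_mean(noisy, big_roi)
    oracle <- brute_roi_stats(noisy, big_roi)
    expect_equal(st3$mean, oracle$mean, tolerance = 1e-12)
    expect_equal(st3$sd, oracle$sd, tolerance = 1e-12)
    expect_equal(st3$n_voxels, oracle$n)
  }
  expect_error(roi_mean(array(NA_real_, dims), roi), "no non-missing")
})

test_that("reference normalisation behaves like rCTH", {
  dims <- c(4, 2, 1)
  map <- array(2, dims); map[3:4, , 1] <- 4
  roi <- array(FALSE, dims); roi[3:4, , 1] <- TRUE
  ref <- array(FALSE, dims); ref[1:2, , 1] <- TRUE
  expect_equal(relative_value(map, roi, ref), 2)
  expect_equal(relative_value(map, roi, roi), 1)
  zero_map <- array(0, dims)
  expect_error(relative_value(zero_map, roi, ref), "not positive")
})
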