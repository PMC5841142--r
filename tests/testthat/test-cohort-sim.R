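test_that("a minimal control cohort draws from the control conditions", {
  spec <- cohort_spec(n_subjects_per_group = 1, groups = "control",
                      visits_per_subject = 1, phantom = "wm",
                      block = c(3, 3, 1))
  coh <- make_cohort(spec, seed = 8, simulate_signal = FALSE)
  expect_length(coh$subjects, 1)
  rec <- coh$truth_records
  wm_cth <- rec$value[rec$region == "WM" & rec$map == "cth"]
  expect_gt(wm_cth, 1.2)
  expect_lt(wm_cth, 2.5)
  expect_error(cohort_spec(groups = character(0)), "non-empty")
})

test_that("hemizygote splenium heterogeneity peaks in childhood", {
  expect_gt(splenium_age_profile(7.5), splenium_age_profile(30))
  # ground truth at the phantom level
  spec <- cohort_spec(n_subjects_per_group = 1, groups = "hemizygote",
                      visits_per_subject = 1, phantom = "regional",
                      block = c(3, 3, 2))
  young <- cthmap:::subject_phantom(spec, "hemizygote", 7.5,
                                    acquisition_params(), aif_model(),
                                    seed = 1, simulate_signal = FALSE)
  old <- cthmap:::subject_phantom(spec, "hemizygote", 30,
                                  acquisition_params(), aif_model(),
                                  seed = 1, simulate_signal = FALSE)
  spl_young <- mean(young$truth$cth[young$labels == 1])
  spl_old <- mean(old$truth$cth[old$labels == 1])
  expect_gt(spl_young, spl_old)
  # thalamus-normalised contrast as in the longitudinal analyses
  tha_y <- mean(young$truth$cth[young$labels == 10])
  tha_o <- mean(old$truth$cth[old$labels == 10])
  expect_gt(spl_young / tha_y, spl_old / tha_o)
})

test_that("longitudinal hemizygote cohorts decline in splenium rCTH", {
  spec <- cohort_spec(n_subjects_per_group = 8, groups = "hemizygote",
                      visits_per_subject = 2, age_range = c(4, 9),
                      followup_years = 15, phantom = "regional",
                      block = c(3, 3, 1))
  coh <- make_cohort(spec, seed = 30, simulate_signal = FALSE)
  rec <- coh$truth_records
  rcth <- do.call(rbind, lapply(split(rec, list(rec$subject_id, rec$visit)),
    function(rs) {
      data.frame(subject_id = rs$subject_id[1], visit = rs$visit[1],
                 value = rs$value[rs$region == "SPL" & rs$map == "cth"] /
                         rs$value[rs$region == "THA" & rs$map == "cth"])
    }))
  first <- rcth$value[rcth$visit == 1]
  last <- rcth$value[rcth$visit == 2]
  expect_gt(mean(first), mean(last))
  # and the built-in contrast agrees
  cmp <- first_last_contrast(rcth)
  expect_gt(cmp$means[1], cmp$means[2])
})

test_that("cohort generation is deterministic in (spec, seed)", {
  spec <- cohort_spec(n_subjects_per_group = 2, groups = "control",
                      phantom = "wm", block = c(2, 2, 1), snr = 20)
  c1 <- make_cohort(spec, seed = 77)
  c2 <- make_cohort(spec, seed = 77)
  expect_identical(c1$truth_records, c2$truth_records)
  expect_identical(c1$subjects[[1]]$visits[[1]]$signal,
                   c2$subjects[[1]]$visits[[1]]$signal)
})

test_that("CALD and self-arrested subjects get lesion phantoms with the right contrast", {
  spec <- cohort_spec(n_subjects_per_group = 1,
                      groups = c("CALD", "self-arrested"),
                      phantom = "wm", block = c(2, 2, 1))
  coh <- make_cohort(spec, seed = 12, simulate_signal = FALSE)
  rec <- coh$truth_records
  zd_cald <- rec$value[rec$group == "CALD" & rec$region == "zone_d" &
                         rec$map == "cth"]
  zd_sa <- rec$value[rec$group == "self-arrested" & rec$region == "zone_d" &
                       rec$map == "cth"]
  expect_gt(zd_cald, zd_sa)
})
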