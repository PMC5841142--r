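rec_df <- function(values, groups, ids = NULL) {
  data.frame(subject_id = ids %||% paste0("S", seq_along(values)),
             group = groups, value = values)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("group comparisons match hand-computed closed forms", {
  # identical arms: t = 0, p = 1
  same <- rec_df(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  c0 <- compare_groups(same, arms = c("a", "b"))
  expect_equal(c0$statistic, 0)
  expect_equal(c0$p_value, 1)

  # Welch t for {1,2,3} vs {4,5,6}, computed from the textbook formula
  rec <- rec_df(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  cw <- compare_groups(rec, arms = c("a", "b"))
  se <- sqrt(1 / 3 + 1 / 3)               # s1^2 = s2^2 = 1, n = 3
  t_hand <- (2 - 5) / se
  df_hand <- (1 / 3 + 1 / 3)^2 / ((1 / 3)^2 / 2 + (1 / 3)^2 / 2)
  p_hand <- 2 * stats::pt(t_hand, df_hand)
  expect_equal(cw$statistic, t_hand, tolerance = 1e-12)
  expect_equal(cw$df, df_hand, tolerance = 1e-12)
  expect_equal(cw$p_value, p_hand, tolerance = 1e-12)
  expect_equal(cw$means, c(2, 5))
  expect_equal(cw$sds, c(1, 1))

  # pooled variant equals the classical two-sample t here (equal variances)
  cp <- compare_groups(rec, arms = c("a", "b"), pooled = TRUE)
  expect_equal(cp$statistic, t_hand, tolerance = 1e-12)
  expect_equal(cp$df, 4)
})

test_that("paired comparisons pair by subject and handle degeneracy", {
  rec <- data.frame(subject_id = rep(c("s1", "s2", "s3"), 2),
                    group = rep(c("pre", "post"), each = 3),
                    value = c(5, 6, 7, 4, 5, 6))
  cp <- compare_groups(rec, arms = c("pre", "post"), paired = TRUE)
  # constant difference of 1, zero variance: exact-difference policy
  expect_true(cp$degenerate)
  expect_equal(cp$statistic, Inf)
  expect_equal(cp$p_value, 0)

  # zero difference: t = 0, p = 1
  rec0 <- rec; rec0$value[4:6] <- c(5, 6, 7)
  c0 <- compare_groups(rec0, arms = c("pre", "post"), paired = TRUE)
  expect_equal(c0$statistic, 0)
  expect_equal(c0$p_value, 1)

  # non-degenerate paired agrees with stats::t.test
  rec2 <- rec; rec2$value <- c(5, 6, 7, 4.2, 5.9, 5.1)
  c2 <- compare_groups(rec2, arms = c("pre", "post"), paired = TRUE)
  tt <- stats::t.test(c(5, 6, 7), c(4.2, 5.9, 5.1), paired = TRUE)
  expect_equal(c2$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(c2$p_value, tt$p.value, tolerance = 1e-12)

  # unmatched subjects are a pairing error naming the offender
  bad <- rec[-4, ]
  expect_error(compare_groups(bad, arms = c("pre", "post"), paired = TRUE),
               "s1")
})

test_that("comparisons are invariant to record ordering", {
  set.seed(9)
  rec <- data.frame(subject_id = paste0("s", 1:12),
                    group = rep(c("a", "b"), 6),
                    value = stats::rnorm(12))
  c1 <- compare_groups(rec, arms = c("a", "b"))
  c2 <- compare_groups(rec[sample(12), ], arms = c("a", "b"))
  expect_equal(c1$statistic, c2$statistic, tolerance = 1e-12)
  expect_equal(c1$p_value, c2$p_value, tolerance = 1e-12)
})

test_that("first-vs-last contrasts exclude single-visit subjects and ignore order", {
  rec <- data.frame(subject_id = rep(c("s1", "s2", "s3"), each = 3),
                    visit = rep(1:3, 3),
                    value = c(5, 4, 3, 6, 5, 4, 7, 6, 5))
  fl <- first_last_contrast(rec)
  expect_equal(fl$means, c(6, 4))        # first visits {5,6,7}, last {3,4,5}
  expect_lt(fl$p_value, 0.05)

  shuffled <- rec[sample(nrow(rec)), ]
  fl2 <- first_last_contrast(shuffled)
  expect_equal(fl$statistic, fl2$statistic, tolerance = 1e-12)

  rec_single <- rbind(rec, data.frame(subject_id = "s4", visit = 1, value = 9))
  expect_warning(fl3 <- first_last_contrast(rec_single), "single-visit")
  expect_equal(fl3$n, c(3, 3))

  same <- rec; same$value <- rep(c(5, 5, 5), 3)
  expect_equal(first_last_contrast(same)$p_value, 1)
})

test_that("cohort summaries conserve counts and match a brute-force group-by", {
  set.seed(21)
  rec <- expand.grid(subject_id = paste0("s", 1:6),
                     region = c("SPL", "FWM"), map = c("cth", "k_app"),
                     stringsAsFactors = FALSE)
  rec$group <- ifelse(rec$subject_id %in% paste0("s", 1:3), "control", "hemizygote")
  rec$visit <- 1
  rec$value <- stats::rnorm(nrow(rec))
  tab <- summarize_cohort(rec)

  # conservation: per-group subject counts in every cell
  expect_true(all(tab$n_subjects == 3))
  # brute-force oracle for one cell
  cell <- rec[rec$group == "control" & rec$region == "SPL" & rec$map == "cth", ]
  row <- tab[tab$group == "control" & tab$region == "SPL" & tab$map == "cth", ]
  expect_equal(row$mean, mean(cell$value), tolerance = 1e-12)
  expect_equal(row$sd, stats::sd(cell$value), tolerance = 1e-12)
  expect_equal(row$median, stats::median(cell$value), tolerance = 1e-12)

  single <- summarize_cohort(rec[1, , drop = FALSE])
  expect_equal(single$mean, rec$value[1])
  expect_true(is.na(single$sd))
})
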