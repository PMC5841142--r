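# Group-level comparison layer on tidy cohort record tables
# (subject_id, age, group, visit, region, map, value).

#' Two-arm group comparison
#'
#' Two-tailed t comparison between two arms of a record table: Welch
#' (default) or pooled-variance unpaired, or paired on subjects. The
#' degenerate paired case with zero variance of the differences is
#' reported exactly (statistic `0` and p `1` when the common difference is
#' zero, otherwise a signed infinite statistic with p `0`) rather than
#' dividing by zero.
#'
#' @param records data frame with at least the arm column, `value`, and
#'   `subject_id` when paired.
#' @param arms length-2 character vector naming the two arms.
#' @param by column holding the arm labels (default `"group"`).
#' @param value column holding the measurements.
#' @param paired match observations by `subject_id`.
#' @param pooled use the classical pooled-variance t-test instead of
#'   Welch for unpaired comparisons.
#' @return An object of class `comparison_result`.
#' @export
compare_groups <- function(records, arms, by = "group", value = "value",
                           paired = FALSE, pooled = FALSE) {
  if (length(arms) != 2) stopf("exactly two arms are required")
  if (!by %in% names(records) || !value %in% names(records))
    stopf("records must contain columns '%s' and '%s'", by, value)
  x <- records[records[[by]] == arms[1], , drop = FALSE]
  y <- records[records[[by]] == arms[2], , drop = FALSE]
  if (paired) {
    if (!"subject_id" %in% names(records))
      stopf("paired comparison requires a subject_id column")
    common <- intersect(x$subject_id, y$subject_id)
    lonely <- setdiff(union(x$subject_id, y$subject_id), common)
    if (length(lonely) > 0)
      stopf("unmatched subjects in paired comparison: %s",
            paste(sort(lonely), collapse = ", "))
    x <- x[match(common, x$subject_id), , drop = FALSE]
    y <- y[match(common, y$subject_id), , drop = FALSE]
  }
  xv <- x[[value]]; yv <- y[[value]]
  if (paired) {
    ok <- is.finite(xv) & is.finite(yv)
    xv <- xv[ok]; yv <- yv[ok]
  } else {
    xv <- xv[is.finite(xv)]; yv <- yv[is.finite(yv)]
  }
  if (length(xv) < 2 || length(yv) < 2)
    stopf("each arm needs at least 2 observations")
  contrast <- sprintf("%s vs %s%s", arms[1], arms[2],
                      if (paired) " (paired)" else "")
  if (paired) {
    d <- xv - yv
    if (stats::sd(d) == 0) {
      delta <- mean(d)
      res <- list(statistic = if (delta == 0) 0 else sign(delta) * Inf,
                  p.value = if (delta == 0) 1 else 0,
                  parameter = length(d) - 1, degenerate = TRUE)
    } else {
      tt <- stats::t.test(xv, yv, paired = TRUE)
      res <- list(statistic = unname(tt$statistic), p.value = tt$p.value,
                  parameter = unname(tt$parameter), degenerate = FALSE)
    }
  } else {
    if (stats::sd(xv) == 0 && stats::sd(yv) == 0) {
      delta <- mean(xv) - mean(yv)
      res <- list(statistic = if (delta == 0) 0 else sign(delta) * Inf,
                  p.value = if (delta == 0) 1 else 0,
                  parameter = length(xv) + length(yv) - 2, degenerate = TRUE)
    } else {
      tt <- stats::t.test(xv, yv, var.equal = pooled)
      res <- list(statistic = unname(tt$statistic), p.value = tt$p.value,
                  parameter = unname(tt$parameter), degenerate = FALSE)
    }
  }
  structure(list(contrast = contrast,
                 n = c(length(xv), length(yv)),
                 means = c(mean(xv), mean(yv)),
                 sds = c(stats::sd(xv), stats::sd(yv)),
                 statistic = res$statistic, df = res$parameter,
                 p_value = res$p.value, paired = paired,
                 method = if (paired) "paired t" else if (pooled) "pooled t" else "Welch t",
                 degenerate = res$degenerate,
                 arms = arms),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s (%s):\n", x$contrast, x$method))
  cat(sprintf("  %s: %.4g +/- %.4g (n=%d) vs %s: %.4g +/- %.4g (n=%d)\n",
              x$arms[1], x$means[1], x$sds[1], x$n[1],
              x$arms[2], x$means[2], x$sds[2], x$n[2]))
  cat(sprintf("  t = %.4g, df = %.4g, two-sided p = %.4g%s\n",
              x$statistic, x$df, x$p_value,
              if (x$degenerate) " (degenerate: zero variance)" else ""))
  invisible(x)
}

#' @export
as.data.frame.comparison_result <- function(x, ...) {
  data.frame(contrast = x$contrast, method = x$method,
             n1 = x$n[1], n2 = x$n[2],
             mean1 = x$means[1], sd1 = x$sds[1],
             mean2 = x$means[2], sd2 = x$sds[2],
             statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' First-versus-last visit longitudinal contrast
#'
#' Paired comparison between every subject's first and last available
#' visit values; subjects with a single visit are excluded with a
#' warning reporting the count.
#'
#' @param records record table with `subject_id`, `visit` and a value
#'   column.
#' @param value name of the value column.
#' @return A `comparison_result` comparing first-visit vs last-visit.
#' @export
first_last_contrast <- function(records, value = "value") {
  if (!all(c("subject_id", "visit") %in% names(records)))
    stopf("records must contain subject_id and visit columns")
  split_by <- split(records, records$subject_id)
  firsts <- list(); lasts <- list()
  n_single <- 0L
  for (s in names(split_by)) {
    rs <- split_by[[s]]
    if (length(unique(rs$visit)) < 2) { n_single <- n_single + 1L; next }
    rs <- rs[order(rs$visit), , drop = FALSE]
    firsts[[s]] <- data.frame(subject_id = s, arm = "first",
                              value = rs[[value]][1])
    lasts[[s]] <- data.frame(subject_id = s, arm = "last",
                             value = rs[[value]][nrow(rs)])
  }
  if (n_single > 0)
    warnf("%d single-visit subject(s) excluded from first-vs-last contrast",
          n_single)
  both <- rbind(do.call(rbind, firsts), do.call(rbind, lasts))
  if (is.null(both) || length(unique(both$subject_id)) < 2)
    stopf("need at least 2 subjects with repeat visits")
  compare_groups(both, arms = c("first", "last"), by = "arm",
                 value = "value", paired = TRUE)
}

#' Cohort summary table
#'
#' Per (group, region, map): number of distinct subjects, mean, SD and
#' quartiles of the values. A single observation reports `NA` SD.
#'
#' @param records record table.
#' @return Data frame, one row per (group, region, map) cell.
#' @export
summarize_cohort <- function(records) {
  if (nrow(records) == 0) stopf("records must be non-empty")
  key <- interaction(records$group, records$region, records$map, drop = TRUE)
  rows <- lapply(split(records, key), function(rs) {
    v <- rs$value[is.finite(rs$value)]
    q <- if (length(v) > 0) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
         else rep(NA_real_, 3)
    data.frame(group = rs$group[1], region = rs$region[1], map = rs$map[1],
               n_subjects = length(unique(rs$subject_id)),
               n_obs = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               q25 = q[1], median = q[2], q75 = q[3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$group, out$region, out$map), , drop = FALSE]
}
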