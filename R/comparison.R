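#' Bland-Altman agreement analysis
#'
#' Differences are taken as `y - x` (method B minus method A). The SD of
#' the differences uses the n-1 denominator and the limits of agreement are
#' `mean_diff +/- 1.96 * sd_diff`.
#'
#' @param x paired values of method A (the reference).
#' @param y paired values of method B (the comparator).
#' @param parameter optional label carried into the report.
#' @return An object of class `comparison_report` (a one-row data.frame)
#'   with n, per-method means/SDs, `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`, `pearson_r`, `p_value`, `slope`, `intercept`.
#' @export
bland_altman <- function(x, y, parameter = NA_character_) {
  if (length(x) != length(y)) validation_error("x and y must be paired")
  if (length(x) < 2L) validation_error("need at least 2 pairs")
  if (anyNA(x) || anyNA(y)) validation_error("missing values are not allowed")
  d <- y - x
  md <- mean(d)
  sdd <- stats::sd(d)
  r <- NA_real_; pv <- NA_real_; slope <- NA_real_; icept <- NA_real_
  if (length(x) >= 3L && stats::sd(x) > 0 && stats::sd(y) > 0) {
    ct <- stats::cor.test(x, y, method = "pearson")
    r <- unname(ct$estimate); pv <- ct$p.value
    cf <- stats::coef(stats::lm(y ~ x))
    icept <- unname(cf[1]); slope <- unname(cf[2])
  }
  out <- data.frame(
    parameter = parameter, n = length(x),
    mean_a = mean(x), sd_a = stats::sd(x),
    mean_b = mean(y), sd_b = stats::sd(y),
    mean_diff = md, sd_diff = sdd,
    loa_low = md - 1.96 * sdd, loa_high = md + 1.96 * sdd,
    pearson_r = r, p_value = pv, slope = slope, intercept = icept,
    stringsAsFactors = FALSE
  )
  class(out) <- c("comparison_report", "data.frame")
  out
}

#' Pearson correlation with a two-sided t-test
#'
#' Product-moment correlation; the p-value comes from the t transform with
#' n-2 degrees of freedom.
#'
#' @param x,y numeric vectors, n >= 3, each with nonzero variance.
#' @return A list with `r` and `p`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    validation_error("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    validation_error("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Compare the two analysis arms parameter by parameter
#'
#' Runs [bland_altman()] (including correlation and the B-on-A regression
#' line) for each shared parameter column of two per-subject result tables,
#' with differences oriented as model minus measured.
#'
#' @param measured,model data.frames of per-subject parameters, matched by
#'   an `id` column.
#' @param parameters character vector of parameter columns to compare.
#' @return A `comparison_report` data.frame, one row per parameter.
#' @export
compare_arms <- function(measured, model,
                         parameters = intersect(names(measured), names(model))) {
  parameters <- setdiff(parameters, "id")
  m <- merge(measured, model, by = "id", suffixes = c("_meas", "_mod"))
  if (nrow(m) == 0L) validation_error("no matching subject ids")
  rows <- lapply(parameters, function(p) {
    bland_altman(m[[paste0(p, "_meas")]], m[[paste0(p, "_mod")]], parameter = p)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_report", "data.frame")
  out
}

#' Subgroup means and SDs by age bin and sex
#'
#' Default bins follow the cohort quartile layout: 35-40, 41-45, 46-50 and
#' 51-56 years on integer age.
#'
#' @param data data.frame with `age`, optionally `sex`, and parameter
#'   columns.
#' @param parameters character vector of parameter columns to summarize.
#' @param age_bins list of `c(lo, hi)` inclusive integer age bins.
#' @param by_sex split groups by sex as well (requires a `sex` column).
#' @return A data.frame with one row per (bin x sex) group and
#'   `<param>_mean` / `<param>_sd` columns, plus group `n`.
#' @export
subgroup_summary <- function(data, parameters,
                             age_bins = list(c(35, 40), c(41, 45),
                                             c(46, 50), c(51, 56)),
                             by_sex = TRUE) {
  lo <- vapply(age_bins, `[`, numeric(1), 1)
  hi <- vapply(age_bins, `[`, numeric(1), 2)
  bin_of <- function(a) {
    i <- which(a >= lo & a <= hi)
    if (length(i) != 1L)
      validation_error(sprintf("age %s falls in %d bins", a, length(i)))
    i
  }
  bins <- vapply(data$age, bin_of, integer(1))
  labels <- sprintf("Q%d (%d-%d y)", seq_along(age_bins), lo, hi)
  grp <- if (by_sex) interaction(labels[bins], data$sex, drop = TRUE, sep = " / ")
         else factor(labels[bins], levels = labels)
  pieces <- lapply(split(seq_len(nrow(data)), grp), function(idx) {
    row <- data.frame(group = NA_character_, n = length(idx),
                      stringsAsFactors = FALSE)
    for (p in parameters) {
      row[[paste0(p, "_mean")]] <- mean(data[[p]][idx])
      row[[paste0(p, "_sd")]] <- stats::sd(data[[p]][idx])
    }
    row
  })
  out <- do.call(rbind, pieces)
  out$group <- names(pieces)
  rownames(out) <- NULL
  out
}

#' Grade a PWV method comparison against the ARTERY Society bands
#'
#' A comparator is rated `"acceptable"` when the absolute mean difference
#' against the gold standard is below 1 m/s with an SD of the differences
#' below 1.5 m/s, otherwise `"not acceptable"`. Finer bands can be supplied
#' as a data.frame with columns `grade`, `mean_max`, `sd_max` (rows tried
#' in order).
#'
#' @param mean_diff mean difference (m/s).
#' @param sd_diff SD of the differences (m/s), >= 0.
#' @param bands optional custom grading bands.
#' @return The grade as a character scalar.
#' @export
artery_rating <- function(mean_diff, sd_diff, bands = NULL) {
  if (!is.finite(sd_diff) || sd_diff < 0)
    validation_error("sd_diff must be non-negative")
  if (is.null(bands))
    bands <- data.frame(grade = "acceptable", mean_max = 1.0, sd_max = 1.5)
  for (i in seq_len(nrow(bands))) {
    if (abs(mean_diff) < bands$mean_max[i] && sd_diff < bands$sd_max[i])
      return(bands$grade[i])
  }
  "not acceptable"
}
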