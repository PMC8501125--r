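#' Mean absolute percentage error
#'
#' \deqn{M\% = \frac{100}{n}\sum_t \left|\frac{A_t - F_t}{A_t}\right|}
#' with `A` the reference (video truth or indirect calorimetry) and `F` the
#' device estimate. The companion spread is the standard deviation of the
#' per-unit absolute percentage errors. MAPE above 5% is conventionally
#' treated as relevant disagreement between methods.
#'
#' @param actual reference values, all > 0.
#' @param estimated device estimates, same length.
#' @return A list: `mean_pct`, `sd_pct` (NA for a single pair), `per_unit_pct`
#'   (the individual absolute percentage errors), and `disagreement`
#'   (`TRUE` when `mean_pct > 5`).
#' @examples
#' mape(c(100, 200), c(90, 210))$mean_pct  # 7.5
#' @export
mape <- function(actual, estimated) {
  if (length(actual) != length(estimated)) stop("length mismatch")
  if (length(actual) == 0L) stop("empty sample")
  if (any(actual <= 0)) stop("actual values must be > 0 for MAPE")
  per <- 100 * abs(actual - estimated) / actual
  m <- mean(per)
  list(mean_pct = m,
       sd_pct = if (length(per) > 1L) stats::sd(per) else NA_real_,
       per_unit_pct = per,
       disagreement = m > 5)
}

#' Paired t-test on method differences
#'
#' Classical paired t-test on `actual - estimated` (positive mean difference
#' = the device undercounts), with the two-sided p-value and the 95%
#' confidence interval of the mean difference.
#'
#' @param actual,estimated paired vectors, length >= 2.
#' @param conf_level confidence level (default 0.95).
#' @return A list: `mean_diff`, `sd_diff`, `ci` (length 2), `t`, `df`, `p`,
#'   and `degenerate` (`TRUE` when the differences have zero variance, in
#'   which case `t`, `p` and `ci` are NA).
#' @export
paired_t <- function(actual, estimated, conf_level = 0.95) {
  if (length(actual) != length(estimated)) stop("length mismatch")
  n <- length(actual)
  if (n < 2L) stop("paired t-test needs n >= 2")
  d <- actual - estimated
  if (stats::sd(d) == 0) {
    return(list(mean_diff = mean(d), sd_diff = 0,
                ci = c(NA_real_, NA_real_), t = NA_real_,
                df = n - 1L, p = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(d, conf.level = conf_level)
  list(mean_diff = unname(tt$estimate), sd_diff = stats::sd(d),
       ci = as.numeric(tt$conf.int), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, degenerate = FALSE)
}

#' Intraclass correlation for method agreement
#'
#' Single-measure intraclass correlation between two measurement methods
#' from the two-way ANOVA decomposition (subjects x methods). The default is
#' the two-way random-effects, absolute-agreement, single-measures form
#' ICC(2,1), the standard choice for method comparison; the two-way mixed
#' consistency form ICC(3,1) is available via `type`. The F-test is
#' `MSR / MSE` with `(n - 1, (n - 1)(k - 1))` degrees of freedom, and the
#' confidence interval uses the F-distribution bounds of the two-way model.
#' Estimates can be negative in poorly agreeing data; they classify as
#' "low".
#'
#' @param actual,estimated paired ratings, length >= 3.
#' @param type `"ICC2_1"` (absolute agreement, default) or `"ICC3_1"`
#'   (consistency).
#' @param conf_level confidence level (default 0.95).
#' @return A list: `icc`, `ci` (length 2), `F`, `df1`, `df2`, `p`, `type`
#'   and `category` (see [classify_icc()]).
#' @export
icc_agreement <- function(actual, estimated, type = c("ICC2_1", "ICC3_1"),
                          conf_level = 0.95) {
  type <- match.arg(type)
  if (length(actual) != length(estimated)) stop("length mismatch")
  n <- length(actual)
  if (n < 3L) stop("ICC needs n >= 3 paired ratings")
  x <- cbind(actual, estimated)
  k <- 2L
  if (stats::var(as.vector(x)) == 0)
    stop("degenerate ANOVA: ratings are constant")
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  grand <- mean(x)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr == 0 && mse == 0)
    stop("degenerate ANOVA: no between-subject or residual variance")
  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    # identical columns: perfect agreement, no residual to bound the CI with
    return(list(icc = 1, ci = c(1, 1), F = Inf, df1 = n - 1,
                df2 = (n - 1) * (k - 1), p = 0, type = type,
                category = "excellent"))
  }
  if (type == "ICC3_1") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    f_obs <- msr / mse
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    fl <- f_obs / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f_obs * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    icc <- (msr - mse) /
      (msr + (k - 1) * mse + (k / n) * (msc - mse))
    f_obs <- msr / mse
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    # McGraw & Wong F-based interval for the absolute-agreement form
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lower, upper)
  }
  p <- stats::pf(f_obs, df1, df2, lower.tail = FALSE)
  list(icc = icc, ci = ci, F = f_obs, df1 = df1, df2 = df2, p = p,
       type = type, category = classify_icc(icc))
}

#' Qualitative ICC category
#'
#' Banding convention: above 0.90 excellent, (0.75, 0.90\] good,
#' \[0.60, 0.75\] moderate, below 0.60 (including negative estimates) low.
#'
#' @param value an ICC estimate, <= 1.
#' @return One of `"excellent"`, `"good"`, `"moderate"`, `"low"`.
#' @examples
#' classify_icc(0.92)  # excellent
#' classify_icc(0.60)  # moderate
#' @export
classify_icc <- function(value) {
  if (any(value > 1)) stop("ICC cannot exceed 1")
  vapply(value, function(v) {
    if (v > 0.90) "excellent"
    else if (v > 0.75) "good"
    else if (v >= 0.60) "moderate"
    else "low"
  }, character(1))
}

#' Bland-Altman limits of agreement
#'
#' Mean difference between methods and the 95% limits of agreement
#' `mean +/- 1.96 x sd` of the differences, plus the per-pair (mean,
#' difference) payload for plotting. Differences are `actual - estimated`,
#' matching [paired_t()].
#'
#' @param actual,estimated paired vectors, length >= 2.
#' @return A list: `mean_diff`, `loa_low`, `loa_high`, and `payload`
#'   (data.frame with `pair_mean` and `pair_diff`).
#' @export
bland_altman <- function(actual, estimated) {
  if (length(actual) != length(estimated)) stop("length mismatch")
  if (length(actual) < 2L) stop("Bland-Altman needs n >= 2")
  d <- actual - estimated
  m <- mean(d); s <- stats::sd(d)
  list(mean_diff = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       payload = data.frame(pair_mean = (actual + estimated) / 2,
                            pair_diff = d))
}

#' Coefficient of determination of estimated on actual
#'
#' Ordinary least-squares R-squared of the device estimates regressed on the
#' reference values.
#'
#' @param actual,estimated paired vectors, length >= 3; `actual` must vary.
#' @return R-squared in \[0, 1\].
#' @export
regression_r2 <- function(actual, estimated) {
  if (length(actual) != length(estimated)) stop("length mismatch")
  if (length(actual) < 3L) stop("regression needs n >= 3")
  if (stats::var(actual) == 0) stop("actual values have zero variance")
  fit <- stats::lm(estimated ~ actual)
  ss_tot <- sum((estimated - mean(estimated))^2)
  if (ss_tot == 0) return(0)  # flat response carries no explained variance
  1 - sum(stats::residuals(fit)^2) / ss_tot
}

#' Full agreement report for one device
#'
#' Runs the whole agreement battery — MAPE, paired t-test, ICC with CI and
#' F-test, Bland-Altman limits, regression R-squared — once per speed and
#' once on per-subject totals, mirroring the standard device-validation
#' table layout. Every subject must contribute a value at every speed.
#'
#' @param data data.frame with columns `subject`, `speed_kmh`, `actual`,
#'   `estimated` (one row per subject x speed).
#' @param icc_type passed to [icc_agreement()].
#' @return A data.frame of class `agreement_report` with one row per speed
#'   plus a `"total"` row: `speed`, `n`, `mape_pct`, `mape_sd`,
#'   `disagreement`, `t_mean_diff`, `t_sd_diff`, `t_ci_low`, `t_ci_high`,
#'   `t_p`, `icc`, `icc_ci_low`, `icc_ci_high`, `icc_F`, `icc_F_p`,
#'   `icc_category`, `ba_mean_diff`, `ba_loa_low`, `ba_loa_high`,
#'   `r_squared`.
#' @export
evaluate_device <- function(data, icc_type = "ICC2_1") {
  req <- c("subject", "speed_kmh", "actual", "estimated")
  if (!all(req %in% names(data)))
    stop("data needs columns subject, speed_kmh, actual, estimated")
  speeds <- sort(unique(data$speed_kmh))
  subjects <- sort(unique(data$subject))
  tab <- table(data$subject, data$speed_kmh)
  if (any(tab != 1L))
    stop("label mismatch: every subject needs exactly one row per speed")

  one_row <- function(label, actual, estimated) {
    mp <- mape(actual, estimated)
    tt <- paired_t(actual, estimated)
    ic <- icc_agreement(actual, estimated, type = icc_type)
    ba <- bland_altman(actual, estimated)
    data.frame(speed = label, n = length(actual),
               mape_pct = mp$mean_pct, mape_sd = mp$sd_pct,
               disagreement = mp$disagreement,
               t_mean_diff = tt$mean_diff, t_sd_diff = tt$sd_diff,
               t_ci_low = tt$ci[1L], t_ci_high = tt$ci[2L], t_p = tt$p,
               icc = ic$icc, icc_ci_low = ic$ci[1L],
               icc_ci_high = ic$ci[2L], icc_F = ic$F, icc_F_p = ic$p,
               icc_category = ic$category,
               ba_mean_diff = ba$mean_diff, ba_loa_low = ba$loa_low,
               ba_loa_high = ba$loa_high,
               r_squared = regression_r2(actual, estimated),
               stringsAsFactors = FALSE)
  }

  rows <- lapply(speeds, function(sp) {
    d <- data[data$speed_kmh == sp, ]
    d <- d[order(d$subject), ]
    one_row(as.character(sp), d$actual, d$estimated)
  })
  totals <- do.call(rbind, lapply(subjects, function(su) {
    d <- data[data$subject == su, ]
    data.frame(actual = sum(d$actual), estimated = sum(d$estimated))
  }))
  rows[[length(rows) + 1L]] <- one_row("total", totals$actual,
                                       totals$estimated)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("agreement_report", "data.frame")
  out
}

#' @export
print.agreement_report <- function(x, digits = 3, ...) {
  cat("<agreement_report>\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
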