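test_that("MAPE follows the printed equation and flags 5% disagreement", {
  expect_equal(mape(c(100, 200), c(100, 200))$mean_pct, 0)
  m <- mape(c(100, 200), c(90, 210))
  expect_equal(m$mean_pct, 7.5)
  expect_equal(m$per_unit_pct, c(10, 5))
  expect_true(m$disagreement)
  single <- mape(100, 105)
  expect_equal(single$mean_pct, 5.0)
  expect_false(single$disagreement)  # strictly over 5 flags
  expect_true(is.na(single$sd_pct))
  expect_error(mape(c(0, 1), c(1, 1)), "> 0")

  # scale invariance
  set.seed(2)
  a <- runif(20, 50, 500); f <- a * runif(20, 0.8, 1.2)
  expect_equal(mape(3 * a, 3 * f)$mean_pct, mape(a, f)$mean_pct)
  expect_equal(mape(3 * a, 3 * f)$sd_pct, mape(a, f)$sd_pct)
})

test_that("paired t-test matches the closed form and its symmetries", {
  # differences {1,2,3}: mean 2, sd 1, t = 2 / (1/sqrt(3))
  a <- c(11, 12, 13); e <- c(10, 10, 10)
  tt <- paired_t(a, e)
  expect_equal(tt$mean_diff, 2)
  expect_equal(tt$t, 2 * sqrt(3))
  expect_equal(tt$df, 2)
  expect_equal(tt$p, 2 * pt(2 * sqrt(3), df = 2, lower.tail = FALSE))

  flipped <- paired_t(e, a)  # sign flip of all differences
  expect_equal(flipped$t, -tt$t)
  expect_equal(flipped$p, tt$p)

  deg <- paired_t(c(5, 6, 7), c(4, 5, 6))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p))

  # null calibration: p-values roughly uniform under no difference
  set.seed(99)
  ps <- replicate(400, {
    d <- rnorm(15)
    paired_t(d, rep(0, 15))$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("ICC matches a from-scratch ANOVA oracle and known values", {
  actual <- c(10, 12, 14, 16, 18, 20)
  estimated <- c(11, 12, 15, 15, 19, 21)

  # from-scratch two-way ANOVA mean squares on the 6x2 fixture
  x <- cbind(actual, estimated)
  n <- nrow(x); k <- 2
  grand <- mean(x)
  msr <- k * sum((rowMeans(x) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(x) - grand)^2) / (k - 1)
  mse <- (sum((x - grand)^2) - k * sum((rowMeans(x) - grand)^2) -
            n * sum((colMeans(x) - grand)^2)) / ((n - 1) * (k - 1))
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))

  got <- icc_agreement(actual, estimated)
  expect_equal(got$icc, icc_oracle)
  # frozen values independently verified with a reference implementation
  expect_equal(got$icc, 0.9714937286202964, tolerance = 1e-12)
  expect_equal(got$F, 82.142857142857, tolerance = 1e-10)
  expect_equal(got$p, 8.50779078134108e-05, tolerance = 1e-9)
  expect_equal(round(got$ci, 2), c(0.83, 1.00))
  expect_equal(got$category, "excellent")

  got3 <- icc_agreement(actual, estimated, type = "ICC3_1")
  expect_equal(got3$icc, (msr - mse) / (msr + (k - 1) * mse))
  expect_equal(got3$icc, 0.9759450171821304, tolerance = 1e-12)

  # duplicated identical ratings: perfect agreement
  perf <- icc_agreement(actual, actual)
  expect_equal(perf$icc, 1)
  expect_equal(perf$ci, c(1, 1))

  # independent large noise drives agreement towards zero
  set.seed(17)
  a <- rnorm(200, 100, 5)
  b <- a + rnorm(200, 0, 60)
  expect_lt(abs(icc_agreement(a, b)$icc), 0.25)

  expect_error(icc_agreement(rep(3, 5), rep(3, 5)), "degenerate")
  expect_error(icc_agreement(c(1, 2), c(1, 2)), "n >= 3")
})

test_that("ICC approaches Pearson r for centered equal-variance columns", {
  set.seed(41)
  z <- rnorm(500)
  a <- scale(z + rnorm(500, 0, 0.5))[, 1]
  b <- scale(z + rnorm(500, 0, 0.5))[, 1]
  expect_lt(abs(icc_agreement(a, b)$icc - cor(a, b)), 0.02)
  expect_lte(icc_agreement(a, b)$icc, 1)
})

test_that("ICC category bands follow the stated cut points", {
  expect_equal(classify_icc(0.92), "excellent")
  expect_equal(classify_icc(0.90), "good")
  expect_equal(classify_icc(0.80), "good")
  expect_equal(classify_icc(0.75), "moderate")
  expect_equal(classify_icc(0.60), "moderate")
  expect_equal(classify_icc(0.10), "low")
  expect_equal(classify_icc(-0.5), "low")
  expect_error(classify_icc(1.2), "exceed")
})

test_that("Bland-Altman limits are mean +/- 1.96 sd of differences", {
  ident <- bland_altman(c(5, 6, 7), c(5, 6, 7))
  expect_equal(c(ident$mean_diff, ident$loa_low, ident$loa_high), c(0, 0, 0))

  ba <- bland_altman(c(11, 12, 13), c(10, 10, 10))
  expect_equal(ba$mean_diff, 2)
  expect_equal(ba$loa_low, 2 - 1.96)
  expect_equal(ba$loa_high, 2 + 1.96)
  expect_equal(ba$payload$pair_diff, c(1, 2, 3))

  set.seed(13)
  a <- rnorm(1e4, 100, 10); e <- a + rnorm(1e4, 1, 2)
  ba2 <- bland_altman(a, e)
  inside <- mean(ba2$payload$pair_diff >= ba2$loa_low &
                   ba2$payload$pair_diff <= ba2$loa_high)
  expect_gt(inside, 0.94); expect_lt(inside, 0.96)
  # LoA width identity
  expect_equal(ba2$loa_high - ba2$loa_low,
               2 * 1.96 * sd(a - e))
  expect_error(bland_altman(1, 2), "n >= 2")
})

test_that("regression R2 equals the normal-equation oracle", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(regression_r2(a, 3 + 2 * a), 1.0)

  e <- c(2.1, 2.9, 4.3, 5.2, 5.8)
  beta <- sum((a - mean(a)) * (e - mean(e))) / sum((a - mean(a))^2)
  fitted <- mean(e) + beta * (a - mean(a))
  r2_oracle <- 1 - sum((e - fitted)^2) / sum((e - mean(e))^2)
  expect_equal(regression_r2(a, e), r2_oracle)

  set.seed(8)
  x <- rnorm(1e4); y <- rnorm(1e4)
  expect_lt(regression_r2(x, y), 0.01)
  expect_error(regression_r2(rep(1, 5), 1:5), "zero variance")
})

test_that("evaluate_device composes the battery per speed plus totals", {
  set.seed(55)
  speeds <- c(1.5, 3, 4.5, 9, 10.5)
  subjects <- 1:8
  grid <- expand.grid(subject = subjects, speed_kmh = speeds)
  grid$actual <- round(350 + 20 * grid$speed_kmh + rnorm(nrow(grid), 0, 25))
  grid$estimated <- round(grid$actual * runif(nrow(grid), 0.9, 1.02))

  rep_tab <- evaluate_device(grid)
  expect_s3_class(rep_tab, "agreement_report")
  expect_equal(rep_tab$speed, c(as.character(speeds), "total"))
  expect_equal(unique(rep_tab$n), length(subjects))

  # row-by-row equality with direct statistic calls
  for (sp in speeds) {
    d <- grid[grid$speed_kmh == sp, ]
    d <- d[order(d$subject), ]
    row <- rep_tab[rep_tab$speed == as.character(sp), ]
    expect_equal(row$mape_pct, mape(d$actual, d$estimated)$mean_pct)
    expect_equal(row$t_p, paired_t(d$actual, d$estimated)$p)
    expect_equal(row$icc, icc_agreement(d$actual, d$estimated)$icc)
    expect_equal(row$ba_loa_low,
                 bland_altman(d$actual, d$estimated)$loa_low)
    expect_equal(row$r_squared, regression_r2(d$actual, d$estimated))
  }
  tot <- aggregate(cbind(actual, estimated) ~ subject, grid, sum)
  row <- rep_tab[rep_tab$speed == "total", ]
  expect_equal(row$mape_pct, mape(tot$actual, tot$estimated)$mean_pct)
  expect_true(row$ba_loa_low <= row$ba_mean_diff &
                row$ba_mean_diff <= row$ba_loa_high)

  # perfect device
  perfect <- grid; perfect$estimated <- perfect$actual
  rep_perf <- evaluate_device(perfect)
  expect_true(all(rep_perf$mape_pct == 0))
  expect_true(all(rep_perf$icc == 1))
  expect_true(all(rep_perf$ba_mean_diff == 0))
  expect_false(any(rep_perf$disagreement))

  expect_error(evaluate_device(grid[-3, ]), "label mismatch")
})
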