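test_that("excursion finding returns maximal supra-threshold runs", {
  expect_equal(nrow(find_excursions(series_from_r(rep(1, 100)), 1.3)), 0L)

  # triangular pulse 1 -> 2 -> 1 in 0.05 g sample steps, pad 30 samples:
  # strict crossings of 1.3 g sit at samples 38 (first > on the rise) and
  # 64 (last > on the fall), so the half-open run is [38, 65)
  r <- triangle_r(baseline = 1, apex = 2, half_samples = 20, pad = 30)
  exc <- find_excursions(series_from_r(r), 1.3)
  expect_equal(nrow(exc), 1L)
  expect_equal(exc$start_index, 38L)
  expect_equal(exc$end_index, 65L)

  r2 <- c(r, r)  # sub-threshold valley between two pulses
  expect_equal(nrow(find_excursions(series_from_r(r2), 1.3)), 2L)
})

test_that("peak features read off amplitude, symmetry and area", {
  r <- triangle_r(baseline = 1, apex = 2, half_samples = 20, pad = 30)
  s <- series_from_r(r)
  exc <- find_excursions(s, 1.3)
  f <- extract_peak_features(s, exc, 1.3)
  expect_equal(f$amplitude, 2)
  expect_equal(f$rise_time, f$decline_time)  # symmetric pulse
  expect_true(f$start_t <= f$peak_t && f$peak_t <= f$end_t)
  expect_error(extract_peak_features(s, c(5L, 5L), 1.3), "empty excursion")

  # smooth raised-cosine pulse: trapezoidal area vs a rectangle-sum oracle
  # of the analytic pulse at 10x oversampling
  set.seed(5)
  for (rep in 1:5) {
    amp <- runif(1, 0.8, 2); width <- runif(1, 0.3, 0.6); theta <- 1.2
    fs <- 100; tc <- 1.0
    t <- (0:(2 * fs)) / fs
    pulse <- function(tt) 1 + amp * ifelse(abs(tt - tc) < width / 2,
                                           cos(pi * (tt - tc) / width)^2, 0)
    s <- series_from_r(pulse(t), fs = fs)
    f <- extract_peak_features(s, find_excursions(s, theta), theta)
    tf <- seq(f$start_t, f$end_t, by = 1 / (10 * fs))
    oracle <- sum(pmax(pulse(tf) - theta, 0)) / (10 * fs)
    expect_lt(abs(f$area - oracle) / oracle, 0.02)
  }
})

test_that("vectorised feature table agrees with the single-excursion path", {
  set.seed(9)
  s <- series_from_r(pmax(1 + cumsum(rnorm(2000, 0, 0.05)) * 0.2, 0.2))
  exc <- find_excursions(s, 1.1)
  skip_if(nrow(exc) == 0)
  tab <- peak_features(s, 1.1)
  expect_equal(nrow(tab), nrow(exc))
  for (i in seq_len(nrow(exc))) {
    one <- extract_peak_features(s, c(exc$start_index[i],
                                      exc$end_index[i]), 1.1)
    expect_equal(unlist(tab[i, ]), unlist(one), tolerance = 1e-12)
  }
})

test_that("the gate applies thresholds and the sequential gap rule", {
  feats <- data.frame(start_t = c(0.9, 1.0, 1.1),
                      peak_t = c(1.0, 1.1, 1.2),
                      end_t = c(1.05, 1.15, 1.25),
                      amplitude = c(2, 2, 2), rise_time = 0.1,
                      decline_time = 0.05, slope = 8, area = 0.1)
  p_easy <- detector_params(1.1, 1.2, 1, 0.01, 5, 0.05)
  expect_equal(nrow(gate_steps(feats, p_easy)), 3L)

  p_amp <- detector_params(1.1, 10, 1, 0.01, 5, 0.05)
  expect_equal(nrow(gate_steps(feats, p_amp)), 0L)

  # 0.1 s apart with a 0.2 s refractory: middle peak rejected, third
  # accepted because its gap is measured against the first ACCEPTED peak
  p_refr <- detector_params(1.1, 1.2, 1, 0.01, 5, 0.2)
  acc <- gate_steps(feats, p_refr)
  expect_equal(acc$peak_t, c(1.0, 1.2))
  expect_equal(acc$gap_prev, c(NA, 0.2))

  expect_error(gate_steps(feats[c(2, 1, 3), ], p_refr), "ordered")
})

test_that("count_steps recovers planted impulses and bins by segment", {
  pl <- planted_recording(n_steps = 40, gap_s = 0.5, amp = 1)
  p <- detector_params(1.2, 1.4, 2, 0.02, 1.0, 0.2)
  res <- count_steps(pl$recording, p, pl$segments)
  expect_equal(res$per_segment$steps, 40L)
  expect_equal(res$total, 40L)

  p_impossible <- detector_params(1.2, 10, 2, 0.02, 1.0, 0.2)
  expect_equal(count_steps(pl$recording, p_impossible, pl$segments)$total, 0L)

  overlapping <- data.frame(speed_kmh = c(3, 9), start_s = c(0, 5),
                            end_s = c(10, 15))
  expect_error(count_steps(pl$recording, p, overlapping), "overlap")
})

test_that("detector equals an independent single-pass reference on noisy data", {
  reference_steps <- function(r, t, fs, p) {
    accepted <- numeric(0); last <- NA_real_
    i <- 1L; n <- length(r)
    while (i <= n) {
      if (r[i] > p$theta_I) {
        j <- i
        while (j < n && r[j + 1L] > p$theta_I) j <- j + 1L
        seg <- r[i:j]
        k <- which.max(seg)
        amp <- seg[k]
        peak_t <- t[i + k - 1L]
        rise <- peak_t - t[i]
        slope <- if (rise > 0) (amp - p$theta_I) / rise else
          (amp - p$theta_I) * fs
        ex <- seg - p$theta_I
        area <- if (length(ex) > 1L)
          sum((ex[-1L] + ex[-length(ex)]) / 2) / fs else 0
        ok <- amp >= p$theta_II && slope >= p$theta_III && area >= p$theta_IV
        if (ok && !is.na(last)) {
          gap <- peak_t - last
          ok <- gap >= p$theta_V_min - 1e-9 && gap <= p$theta_V_max + 1e-9
        }
        if (ok) {
          accepted <- c(accepted, peak_t)
          last <- peak_t
        }
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
    accepted
  }

  sub <- simulate_recording(gait_sim_config(), short_protocol(), seed = 77)
  series <- resultant_norm(sub$recording)
  for (p in list(detector_params(1.15, 1.3, 2, 0.02, 1.2, 0.2),
                 detector_params(1.05, 1.1, 0, 0, 2.0, 0.2),
                 detector_params(1.3, 1.6, 8, 0.05, 0.8, 0.3))) {
    res <- count_steps(sub$recording, p, sub$segments)
    ref <- reference_steps(series$r, series$t, series$fs, p)
    expect_equal(res$step_times, ref)
  }
})

test_that("detection is deterministic", {
  sub <- simulate_recording(gait_sim_config(), short_protocol(), seed = 5)
  p <- detector_params(1.2, 1.4, 2, 0.02, 1.2, 0.2)
  r1 <- count_steps(sub$recording, p, sub$segments)
  r2 <- count_steps(sub$recording, p, sub$segments)
  expect_identical(r1, r2)
})

test_that("detector_params validates its invariants", {
  expect_error(detector_params(-1, 1.2), "theta_I")
  expect_error(detector_params(1.3, 1.2), "theta_II")
  expect_error(detector_params(1.1, 1.2, theta_V_max = 0.1,
                               theta_V_min = 0.2), "theta_V_min")
})
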