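#' Treadmill protocol description
#'
#' Ordered fixed-speed stages, each `segment_min` minutes, matching the two
#' study-style protocols: the optimization protocol walks/runs at 1.5, 3,
#' 4.5, 9 and 10.5 km/h (20 min) and the validation protocol adds a brisk
#' 6 km/h stage (24 min). Segment intervals are half-open `[start_s, end_s)`
#' in seconds from recording start; the 5-10 s acceleration ramp to each
#' speed belongs to the start of its segment.
#'
#' @param cohort `"optimization"` or `"validation"`; ignored when `speeds`
#'   is given.
#' @param segment_min stage duration in minutes (default 4).
#' @param speeds optional explicit speed sequence in km/h.
#' @return A data.frame: `speed_kmh`, `start_s`, `end_s`.
#' @examples
#' study_protocol("validation")
#' @export
study_protocol <- function(cohort = c("optimization", "validation"),
                           segment_min = 4, speeds = NULL) {
  if (is.null(speeds)) {
    cohort <- match.arg(cohort)
    speeds <- if (cohort == "optimization") c(1.5, 3, 4.5, 9, 10.5)
              else c(1.5, 3, 4.5, 6, 9, 10.5)
  }
  if (any(speeds <= 0) || segment_min <= 0)
    stop("speeds and segment_min must be > 0")
  dur <- segment_min * 60
  n <- length(speeds)
  data.frame(speed_kmh = speeds,
             start_s = (seq_len(n) - 1) * dur,
             end_s = seq_len(n) * dur)
}

#' Gait-simulation configuration
#'
#' Parameters of the synthetic gait generator. Cadence and impulse amplitude
#' are looked up per protocol speed; each simulated subject draws one
#' multiplicative cadence factor (sd `cadence_jitter_sd`), and each stage
#' starts with a linear 5-10 s ramp interpolating cadence and amplitude from
#' the previous stage. Step impulses are smooth raised-cosine bumps of
#' `impulse_width_s` seconds added to the 1 g gravity baseline of the
#' resultant; Gaussian sensor noise of sd `noise_sd` is added to the
#' resultant magnitude before it is distributed over the three axes along a
#' fixed per-subject unit orientation vector. The default cadences and
#' amplitudes are plausible human walking/running values chosen by the
#' package, not measured constants.
#'
#' @param cadence_table named numeric, steps/min per speed (km/h as names);
#'   must be strictly increasing with speed.
#' @param amplitude_table named numeric, impulse peak amplitude in g above
#'   the 1 g baseline, per speed.
#' @param impulse_width_s full width of one step impulse in seconds.
#' @param noise_sd sensor noise sd in g on the resultant.
#' @param cadence_jitter_sd sd of the per-subject multiplicative cadence
#'   factor.
#' @param ramp_range_s length-2 range (seconds) the per-stage acceleration
#'   ramp duration is drawn from.
#' @param baseline_g gravity baseline of the resultant (default 1).
#' @return A list of class `gait_sim_config`.
#' @export
gait_sim_config <- function(
    cadence_table = c("1.5" = 70, "3" = 95, "4.5" = 110, "6" = 120,
                      "9" = 150, "10.5" = 160),
    amplitude_table = c("1.5" = 0.4, "3" = 0.8, "4.5" = 1.2, "6" = 1.5,
                        "9" = 2.2, "10.5" = 2.5),
    impulse_width_s = 0.2,
    noise_sd = 0.05,
    cadence_jitter_sd = 0.05,
    ramp_range_s = c(5, 10),
    baseline_g = 1) {
  sp <- as.numeric(names(cadence_table))
  if (anyNA(sp)) stop("cadence_table must be named by speed in km/h")
  if (any(diff(cadence_table[order(sp)]) <= 0))
    stop("cadence must be strictly increasing with speed")
  if (any(amplitude_table <= noise_sd))
    stop("impulse amplitudes must exceed the noise sd")
  if (impulse_width_s <= 0 || noise_sd < 0 || cadence_jitter_sd < 0)
    stop("impulse_width_s must be > 0, sds >= 0")
  if (length(ramp_range_s) != 2L || ramp_range_s[1L] > ramp_range_s[2L])
    stop("ramp_range_s must be an increasing length-2 range")
  structure(list(cadence_table = cadence_table,
                 amplitude_table = amplitude_table,
                 impulse_width_s = impulse_width_s, noise_sd = noise_sd,
                 cadence_jitter_sd = cadence_jitter_sd,
                 ramp_range_s = ramp_range_s, baseline_g = baseline_g),
            class = "gait_sim_config")
}

lookup_speed <- function(table, speed, what) {
  v <- table[as.character(speed)]
  if (anyNA(v))
    stop(sprintf("no %s configured for speed %s km/h", what,
                 paste(speed[is.na(v)], collapse = ", ")))
  unname(v)
}

#' Simulate one subject's treadmill recording
#'
#' Generates a triaxial recording with exact ground-truth step times for a
#' given protocol. Within each stage, steps are placed sequentially at the
#' (ramped) instantaneous cadence; each step contributes a raised-cosine
#' impulse on the resultant whose peak amplitude follows the stage's
#' (ramped) amplitude. The first stage ramps amplitude up from half its
#' target (gait settling) at constant cadence; later stages ramp both
#' cadence and amplitude linearly from the previous stage over a 5-10 s
#' window, mirroring the treadmill's speed changes.
#'
#' @param config a [gait_sim_config()].
#' @param protocol a [study_protocol()] data.frame.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param fs sampling rate in Hz (default 100).
#' @return A list of class `simulated_subject`: `recording`
#'   ([triaxial_recording()]), `segments` (protocol with `true_steps`),
#'   `step_times` (exact impulse-peak seconds), `cadence_factor` and
#'   `orientation`.
#' @export
simulate_recording <- function(config, protocol, seed, fs = 100) {
  stopifnot(inherits(config, "gait_sim_config"))
  set.seed(as.integer(seed))
  n_seg <- nrow(protocol)
  cad_target <- lookup_speed(config$cadence_table, protocol$speed_kmh,
                             "cadence")
  amp_target <- lookup_speed(config$amplitude_table, protocol$speed_kmh,
                             "amplitude")
  m <- min(max(1 + stats::rnorm(1) * config$cadence_jitter_sd, 0.7), 1.3)
  cad_target <- cad_target * m
  v <- stats::rnorm(3)
  u <- v / sqrt(sum(v^2))
  ramps <- stats::runif(n_seg, config$ramp_range_s[1L],
                        config$ramp_range_s[2L])
  if (max(cad_target) > 60 / config$impulse_width_s)
    stop("cadence too high: step impulses would overlap")

  # stepping is continuous over the whole protocol (a treadmill walker
  # never pauses at a speed change); cadence and amplitude follow piecewise
  # profiles with a linear on-ramp at each stage start
  ramps <- pmin(ramps, protocol$end_s - protocol$start_s)
  profile_at <- function(t, target, first_from) {
    i <- findInterval(t, protocol$start_s)
    from <- if (i == 1L) first_from else target[i - 1L]
    frac <- min((t - protocol$start_s[i]) / ramps[i], 1)
    from + (target[i] - from) * frac
  }
  t_end <- protocol$end_s[n_seg]
  step_t <- numeric(0)
  step_a <- numeric(0)
  t <- 30 / profile_at(0, cad_target, cad_target[1L])  # half a stride in
  while (t < t_end) {
    step_t <- c(step_t, t)
    step_a <- c(step_a, profile_at(t, amp_target, amp_target[1L] / 2))
    t <- t + 60 / profile_at(t, cad_target, cad_target[1L])
  }

  n <- round(protocol$end_s[n_seg] * fs)
  tt <- (seq_len(n) - 1L) / fs
  r <- rep(config$baseline_g, n)
  w <- config$impulse_width_s
  for (j in seq_along(step_t)) {
    lo <- max(1L, ceiling((step_t[j] - w / 2) * fs) + 1L)
    hi <- min(n, floor((step_t[j] + w / 2) * fs) + 1L)
    if (hi < lo) next
    idx <- lo:hi
    r[idx] <- r[idx] + step_a[j] * cos(pi * (tt[idx] - step_t[j]) / w)^2
  }
  r <- r + stats::rnorm(n, 0, config$noise_sd)

  segments <- protocol
  segments$true_steps <- vapply(seq_len(n_seg), function(i) {
    sum(step_t >= protocol$start_s[i] & step_t < protocol$end_s[i])
  }, integer(1))
  rec <- triaxial_recording(t = tt, ax = u[1L] * r, ay = u[2L] * r,
                            az = u[3L] * r, fs = fs)
  structure(list(recording = rec, segments = segments, step_times = step_t,
                 cadence_factor = m, orientation = u),
            class = "simulated_subject")
}

#' @export
print.simulated_subject <- function(x, ...) {
  cat(sprintf("<simulated_subject> %d true steps over %d segments\n",
              length(x$step_times), nrow(x$segments)))
  invisible(x)
}

#' Simulate a cohort of subjects
#'
#' Independent subjects drawn with per-subject seeds derived
#' deterministically from the master seed (`seed * 1000 + subject index`),
#' so a cohort is reproducible as a whole while subjects differ.
#'
#' @param n_subjects number of subjects, >= 1.
#' @param protocol a [study_protocol()] data.frame.
#' @param config a [gait_sim_config()].
#' @param seed master integer seed.
#' @param fs sampling rate in Hz.
#' @return A list of `n_subjects` [simulate_recording()] results.
#' @export
simulate_cohort <- function(n_subjects, protocol, config, seed, fs = 100) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  lapply(seq_len(n_subjects), function(i) {
    simulate_recording(config, protocol, seed = seed * 1000 + i, fs = fs)
  })
}

#' Simulate a per-minute indirect-calorimetry trace
#'
#' Synthetic reference for the energy-expenditure chain: each protocol
#' minute gets VO2 = MET x 3.5 x body mass (ml/min) with multiplicative
#' Gaussian noise, and VCO2 = RER x VO2 with RER drawn uniformly inside the
#' resting plausibility band \[0.7, 0.99\].
#'
#' @param protocol a [study_protocol()] data.frame.
#' @param met_per_speed named numeric, MET per speed (km/h as names), all
#'   >= 1.
#' @param body_mass body mass in kg.
#' @param seed integer seed.
#' @param noise_sd multiplicative VO2 noise sd (0 for an exact trace).
#' @return An [ic_trace()] with one entry per whole protocol minute.
#' @export
simulate_ic_trace <- function(protocol, met_per_speed, body_mass = 70,
                              seed = 1, noise_sd = 0.05) {
  if (any(met_per_speed < 1)) stop("MET values must be >= 1")
  set.seed(as.integer(seed))
  n_min <- floor(protocol$end_s[nrow(protocol)] / 60)
  if (n_min < 1L) stop("protocol shorter than one minute")
  minute_start <- (seq_len(n_min) - 1) * 60
  met <- vapply(minute_start, function(t0) {
    i <- which(protocol$start_s <= t0 & t0 < protocol$end_s)
    lookup_speed(met_per_speed, protocol$speed_kmh[i[1L]], "MET")
  }, numeric(1))
  vo2 <- met * 3.5 * body_mass * pmax(1 + stats::rnorm(n_min, 0, noise_sd),
                                      0.1)
  rer <- stats::runif(n_min, 0.7, 0.99)
  ic_trace(vo2, rer * vo2)
}
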