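# Build a resultant series with a prescribed positive magnitude trace by
# putting the whole signal on one axis.
series_from_r <- function(r, fs = 100) {
  stopifnot(all(r >= 0))
  t <- (seq_along(r) - 1) / fs
  resultant_norm(triaxial_recording(t, ax = r, ay = rep(0, length(r)),
                                    az = rep(0, length(r)), fs = fs))
}

# Symmetric triangular pulse: baseline -> apex -> baseline, one sample apart.
triangle_r <- function(baseline = 1, apex = 2, half_samples = 20,
                       pad = 30, fs = 100) {
  up <- seq(baseline, apex, length.out = half_samples + 1)
  c(rep(baseline, pad), up, rev(up)[-1], rep(baseline, pad))
}

# Recording with `n_steps` identical raised-cosine impulses on a 1 g
# baseline, evenly spaced; exact, noiseless.
planted_recording <- function(n_steps = 40, gap_s = 0.5, amp = 1,
                              width_s = 0.2, fs = 100, lead_s = 1) {
  dur <- lead_s * 2 + n_steps * gap_s
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  r <- rep(1, n)
  centers <- lead_s + (seq_len(n_steps) - 1) * gap_s
  for (tc in centers) {
    idx <- which(abs(t - tc) < width_s / 2)
    r[idx] <- r[idx] + amp * cos(pi * (t[idx] - tc) / width_s)^2
  }
  list(recording = triaxial_recording(t, ax = r, ay = rep(0, n),
                                      az = rep(0, n), fs = fs),
       step_times = centers,
       segments = data.frame(speed_kmh = 3, start_s = 0, end_s = dur,
                             true_steps = n_steps))
}

# Short two-segment protocol for fast end-to-end tests.
short_protocol <- function(speeds = c(3, 9), segment_min = 1) {
  study_protocol(speeds = speeds, segment_min = segment_min)
}
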