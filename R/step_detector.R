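#' Detector gating thresholds
#'
#' The five-parameter acceptance gate of the step detector. A candidate step
#' is an excursion of the resultant above `theta_I`; its peak features are
#' then gated on amplitude, slope, area and inter-peak timing:
#'
#' * `theta_I` (g): excursion threshold; a peak starts where the resultant
#'   exceeds this value.
#' * `theta_II` (g): minimum peak amplitude.
#' * `theta_III` (g/s): minimum rising slope.
#' * `theta_IV` (g.s): minimum area above the `theta_I` baseline.
#' * `theta_V_max` (s): maximum gap to the previous accepted peak.
#' * `theta_V_min` (s): refractory minimum gap, preventing double counts from
#'   heel-strike ringing.
#'
#' @param theta_I excursion threshold in g, > 0.
#' @param theta_II minimum amplitude in g, >= `theta_I`.
#' @param theta_III minimum slope in g/s, >= 0.
#' @param theta_IV minimum area in g.s, >= 0.
#' @param theta_V_max maximum inter-peak gap in seconds.
#' @param theta_V_min minimum inter-peak gap in seconds, < `theta_V_max`.
#' @return An object of class `detector_params`.
#' @examples
#' detector_params(1.2, 1.5, 2, 0.05, 1.5)
#' @export
detector_params <- function(theta_I, theta_II, theta_III = 0, theta_IV = 0,
                            theta_V_max = 2, theta_V_min = 0.2) {
  p <- list(theta_I = as.numeric(theta_I), theta_II = as.numeric(theta_II),
            theta_III = as.numeric(theta_III),
            theta_IV = as.numeric(theta_IV),
            theta_V_max = as.numeric(theta_V_max),
            theta_V_min = as.numeric(theta_V_min))
  if (any(vapply(p, length, 1L) != 1L) || anyNA(unlist(p)))
    stop("all thresholds must be single non-NA numbers")
  if (p$theta_I <= 0) stop("theta_I must be > 0")
  if (p$theta_II < p$theta_I) stop("theta_II must be >= theta_I")
  if (p$theta_III < 0 || p$theta_IV < 0)
    stop("theta_III and theta_IV must be >= 0")
  if (p$theta_V_min >= p$theta_V_max)
    stop("theta_V_min must be < theta_V_max")
  structure(p, class = "detector_params")
}

#' @export
print.detector_params <- function(x, ...) {
  cat(sprintf(paste0("<detector_params> theta_I=%.3g g, theta_II=%.3g g, ",
                     "theta_III=%.3g g/s, theta_IV=%.3g g.s, ",
                     "gap in [%.3g, %.3g] s\n"),
              x$theta_I, x$theta_II, x$theta_III, x$theta_IV,
              x$theta_V_min, x$theta_V_max))
  invisible(x)
}

#' Find supra-threshold excursions of the resultant
#'
#' Returns the maximal contiguous runs of samples whose resultant strictly
#' exceeds `theta_I`, as half-open 1-based index intervals
#' `[start_index, end_index)`, in time order. Each run is a candidate step
#' event whose shape is analysed by [extract_peak_features()].
#'
#' @param series a [resultant_norm()] series.
#' @param theta_I excursion threshold in g.
#' @return A data.frame with columns `start_index`, `end_index` (half-open);
#'   zero rows when nothing crosses the threshold.
#' @export
find_excursions <- function(series, theta_I) {
  if (!inherits(series, "resultant_series"))
    stop("series must be a resultant_series")
  above <- series$r > theta_I
  if (!any(above))
    return(data.frame(start_index = integer(0), end_index = integer(0)))
  d <- diff(c(FALSE, above, FALSE))
  data.frame(start_index = which(d == 1L),
             end_index = which(d == -1L))
}

#' Peak features of one excursion
#'
#' Reads off the shape descriptors the gate evaluates: `amplitude` is the
#' maximum resultant in the excursion (first sample wins on ties); the
#' rise/decline times run from the first/to the last supra-threshold sample;
#' `slope = (amplitude - theta_I) / rise_time` (over one sample period when
#' the peak is the first sample); `area` is the trapezoidal integral of
#' `r - theta_I` across the excursion, the area "exceeding" the threshold.
#'
#' @param series a [resultant_norm()] series.
#' @param excursion a length-2 vector or one-row data.frame giving the
#'   half-open index interval `[start_index, end_index)`.
#' @param theta_I the excursion threshold the excursion was found at, in g.
#' @return A one-row data.frame: `start_t`, `peak_t`, `end_t`, `amplitude`,
#'   `rise_time`, `decline_time`, `slope`, `area`.
#' @export
extract_peak_features <- function(series, excursion, theta_I) {
  if (is.data.frame(excursion))
    excursion <- c(excursion$start_index[1L], excursion$end_index[1L])
  s <- as.integer(excursion[1L]); e <- as.integer(excursion[2L])
  if (is.na(s) || is.na(e) || e <= s) stop("empty excursion")
  idx <- s:(e - 1L)
  r <- series$r[idx]
  k <- which.max(r)
  amplitude <- r[k]
  start_t <- series$t[s]
  peak_t <- series$t[idx[k]]
  end_t <- series$t[e - 1L]
  rise <- peak_t - start_t
  decline <- end_t - peak_t
  slope <- if (rise > 0) (amplitude - theta_I) / rise else
    (amplitude - theta_I) * series$fs
  excess <- r - theta_I
  area <- if (length(excess) > 1L)
    sum((excess[-1L] + excess[-length(excess)]) / 2) / series$fs else 0
  data.frame(start_t = start_t, peak_t = peak_t, end_t = end_t,
             amplitude = amplitude, rise_time = rise, decline_time = decline,
             slope = slope, area = area)
}

#' Peak features of every excursion in a series
#'
#' @inheritParams find_excursions
#' @return A data.frame with one [extract_peak_features()] row per excursion,
#'   in time order.
#' @export
peak_features <- function(series, theta_I) {
  exc <- find_excursions(series, theta_I)
  m <- nrow(exc)
  if (m == 0L)
    return(data.frame(start_t = numeric(0), peak_t = numeric(0),
                      end_t = numeric(0), amplitude = numeric(0),
                      rise_time = numeric(0), decline_time = numeric(0),
                      slope = numeric(0), area = numeric(0)))
  # single preallocated pass; must agree with extract_peak_features()
  r <- series$r; tt <- series$t; fs <- series$fs
  amplitude <- peak_t <- start_t <- end_t <- area <- numeric(m)
  for (i in seq_len(m)) {
    s <- exc$start_index[i]; e <- exc$end_index[i]
    seg <- r[s:(e - 1L)]
    k <- which.max(seg)
    amplitude[i] <- seg[k]
    start_t[i] <- tt[s]
    peak_t[i] <- tt[s + k - 1L]
    end_t[i] <- tt[e - 1L]
    excess <- seg - theta_I
    area[i] <- if (length(excess) > 1L)
      sum((excess[-1L] + excess[-length(excess)]) / 2) / fs else 0
  }
  rise <- peak_t - start_t
  slope <- ifelse(rise > 0, (amplitude - theta_I) / rise,
                  (amplitude - theta_I) * fs)
  data.frame(start_t = start_t, peak_t = peak_t, end_t = end_t,
             amplitude = amplitude, rise_time = rise,
             decline_time = end_t - peak_t, slope = slope, area = area)
}

#' Gate candidate peaks into accepted steps
#'
#' Applies the acceptance rules sequentially in time order: a peak is
#' accepted iff `amplitude >= theta_II`, `slope >= theta_III`,
#' `area >= theta_IV`, and — except for the first accepted peak — the gap to
#' the previous *accepted* peak lies in `[theta_V_min, theta_V_max]`. The gap
#' is evaluated against accepted peaks only, so a rejected peak does not
#' reset the refractory clock.
#'
#' @param features a time-ordered data.frame from [peak_features()].
#' @param params a [detector_params()].
#' @return The accepted rows of `features`, with a `gap_prev` column (seconds
#'   since the previous accepted peak; `NA` for the first).
#' @export
gate_steps <- function(features, params) {
  stopifnot(inherits(params, "detector_params"))
  n <- nrow(features)
  if (n == 0L) {
    features$gap_prev <- numeric(0)
    return(features)
  }
  if (is.unsorted(features$peak_t, strictly = FALSE))
    stop("features must be ordered by peak_t")
  keep <- logical(n)
  gap_prev <- rep(NA_real_, n)
  last_t <- NA_real_
  for (i in seq_len(n)) {
    if (features$amplitude[i] < params$theta_II) next
    if (features$slope[i] < params$theta_III) next
    if (features$area[i] < params$theta_IV) next
    if (!is.na(last_t)) {
      gap <- features$peak_t[i] - last_t
      # 1 ns slack: gaps are differences of sampled times and must not
      # fail an exact-boundary comparison through rounding alone
      if (gap < params$theta_V_min - 1e-9 ||
          gap > params$theta_V_max + 1e-9) next
      gap_prev[i] <- gap
    }
    keep[i] <- TRUE
    last_t <- features$peak_t[i]
  }
  out <- features[keep, , drop = FALSE]
  out$gap_prev <- gap_prev[keep]
  rownames(out) <- NULL
  out
}

#' Count steps in a recording, per protocol segment
#'
#' The full detector: resultant norm, excursion finding, feature extraction
#' and gating, followed by binning of accepted peak times into the protocol
#' segments (half-open `[start_s, end_s)` intervals; speed-change ramps at a
#' segment start are counted inside that segment).
#'
#' @param rec a [triaxial_recording()].
#' @param params a [detector_params()].
#' @param segments a protocol data.frame with columns `speed_kmh`, `start_s`,
#'   `end_s` (non-overlapping, within the recording span), e.g. from
#'   [study_protocol()]. If `NULL`, the whole recording is one segment.
#' @return An object of class `step_result`: list with `step_times` (seconds
#'   of accepted peaks), `per_segment` (the `segments` data.frame with a
#'   `steps` column), and `total`.
#' @export
count_steps <- function(rec, params, segments = NULL) {
  series <- resultant_norm(rec)
  if (is.null(segments)) {
    segments <- data.frame(speed_kmh = NA_real_, start_s = series$t[1L],
                           end_s = series$t[length(series$t)] + 1 / series$fs)
  }
  validate_segments(segments, series$t[length(series$t)])
  accepted <- gate_steps(peak_features(series, params$theta_I), params)
  counts <- vapply(seq_len(nrow(segments)), function(i) {
    sum(accepted$peak_t >= segments$start_s[i] &
          accepted$peak_t < segments$end_s[i])
  }, integer(1))
  per_segment <- segments
  per_segment$steps <- counts
  structure(list(step_times = accepted$peak_t, per_segment = per_segment,
                 total = length(accepted$peak_t)),
            class = "step_result")
}

#' @export
print.step_result <- function(x, ...) {
  cat(sprintf("<step_result> %d steps total\n", x$total))
  print(x$per_segment)
  invisible(x)
}

validate_segments <- function(segments, t_max) {
  req <- c("start_s", "end_s")
  if (!all(req %in% names(segments)))
    stop("segments need columns start_s and end_s")
  if (any(segments$end_s <= segments$start_s))
    stop("segments must have end_s > start_s")
  o <- order(segments$start_s)
  s <- segments[o, ]
  if (nrow(s) > 1L && any(s$start_s[-1L] < s$end_s[-nrow(s)]))
    stop("overlapping segments")
  if (any(segments$start_s < 0) || any(segments$end_s > t_max + 1))
    stop("segments outside the recording span")
  invisible(TRUE)
}
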