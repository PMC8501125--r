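#' Construct a triaxial accelerometer recording
#'
#' Bundles a uniformly sampled 3-axis acceleration series into a validated
#' `triaxial_recording` object, the raw input of the step-detection pipeline.
#' Axis values are accelerations in g; timestamps are seconds from the start
#' of the recording.
#'
#' The constructor enforces uniform sampling: consecutive timestamps must be
#' `1/fs` apart within 1e-6 s. Hip-worn devices in this class record on a
#' +/- 8 g range, so axis values beyond 8 g in magnitude trigger a warning
#' (possible clipping or unit error) but are kept.
#'
#' @param t numeric vector of timestamps in seconds, strictly increasing.
#' @param ax,ay,az numeric vectors of axis accelerations in g, same length
#'   as `t`.
#' @param fs sampling rate in Hz. If `NULL`, inferred as the reciprocal of
#'   the median timestamp spacing.
#' @return An object of class `triaxial_recording`: a list with elements
#'   `t`, `ax`, `ay`, `az` and `fs`.
#' @examples
#' rec <- triaxial_recording(t = (0:99) / 100,
#'                           ax = rnorm(100, 0, 0.02),
#'                           ay = rnorm(100, 0, 0.02),
#'                           az = rnorm(100, 1, 0.02))
#' rec
#' @seealso [resultant_norm()], [read_raw_csv()]
#' @export
triaxial_recording <- function(t, ax, ay, az, fs = NULL) {
  t <- as.numeric(t); ax <- as.numeric(ax)
  ay <- as.numeric(ay); az <- as.numeric(az)
  n <- length(t)
  if (n == 0L) stop("empty recording: no samples")
  if (length(ax) != n || length(ay) != n || length(az) != n)
    stop("t, ax, ay, az must have equal length")
  if (anyNA(t) || anyNA(ax) || anyNA(ay) || anyNA(az))
    stop("recording contains NA values")
  if (is.null(fs)) {
    if (n < 2L) stop("cannot infer sampling rate from a single sample")
    fs <- 1 / stats::median(diff(t))
  }
  fs <- as.numeric(fs)
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  if (n >= 2L) {
    gaps <- diff(t)
    bad <- which(abs(gaps - 1 / fs) > 1e-6)
    if (length(bad) > 0L)
      stop(sprintf(paste0("non-uniform sampling: gap of %.6f s between ",
                          "samples %d and %d (expected %.6f s)"),
                   gaps[bad[1L]], bad[1L], bad[1L] + 1L, 1 / fs))
  }
  if (max(abs(c(ax, ay, az))) > 8)
    warning("axis values exceed the 8 g device range; check units/clipping")
  structure(list(t = t, ax = ax, ay = ay, az = az, fs = fs),
            class = "triaxial_recording")
}

#' @export
print.triaxial_recording <- function(x, ...) {
  cat(sprintf("<triaxial_recording> %d samples @ %g Hz (%.1f s)\n",
              length(x$t), x$fs, length(x$t) / x$fs))
  invisible(x)
}

#' Resultant (vector-magnitude) acceleration series
#'
#' Collapses the three axes of a recording into the per-sample Euclidean norm
#' `sqrt(ax^2 + ay^2 + az^2)`. Gravity is deliberately not removed: during
#' quiet standing the resultant sits near 1 g, and every detector threshold
#' downstream is interpreted on this gravity-inclusive signal.
#'
#' @param rec a [triaxial_recording()].
#' @return An object of class `resultant_series`: list with `t` (seconds),
#'   `r` (resultant magnitude in g) and `fs` (Hz).
#' @examples
#' rec <- triaxial_recording((0:9) / 100, rep(0.6, 10), rep(0.8, 10),
#'                           rep(0, 10))
#' resultant_norm(rec)$r   # all exactly 1
#' @export
resultant_norm <- function(rec) {
  if (!inherits(rec, "triaxial_recording"))
    stop("rec must be a triaxial_recording")
  r <- sqrt(rec$ax^2 + rec$ay^2 + rec$az^2)
  structure(list(t = rec$t, r = r, fs = rec$fs), class = "resultant_series")
}

#' @export
print.resultant_series <- function(x, ...) {
  cat(sprintf("<resultant_series> %d samples @ %g Hz, r in [%.3f, %.3f] g\n",
              length(x$r), x$fs, min(x$r), max(x$r)))
  invisible(x)
}

#' Cut a resultant series into contiguous fixed-length epochs
#'
#' Tiles the series prefix with non-overlapping epochs of `epoch_len` seconds
#' (i.e. `round(epoch_len * fs)` samples); a trailing partial epoch is
#' dropped. Epoch boundaries are half-open sample-index intervals
#' `[start_index, end_index)`.
#'
#' @param series a [resultant_norm()] result.
#' @param epoch_len epoch length in seconds; must cover at least one sample.
#' @return A data.frame with one row per epoch: `start_index`, `end_index`
#'   (1-based, half-open: the epoch covers samples `start_index` to
#'   `end_index - 1`), and `start_t` (seconds).
#' @export
segment_epochs <- function(series, epoch_len = 6) {
  if (!inherits(series, "resultant_series"))
    stop("series must be a resultant_series")
  spe <- round(epoch_len * series$fs)
  if (spe < 1) stop("epoch shorter than one sample")
  n_epochs <- floor(length(series$r) / spe)
  starts <- seq_len(n_epochs) * spe - spe + 1L
  data.frame(start_index = as.integer(starts),
             end_index = as.integer(starts + spe),
             start_t = series$t[starts])
}

#' Mean amplitude deviation (MAD) of a resultant segment
#'
#' The mean absolute deviation of the resultant acceleration from its mean
#' over the epoch,
#' \deqn{\mathrm{MAD} = \frac{1}{N}\sum_{i=1}^{N} |r_i - \bar r|,}
#' reported in milli-g. MAD is the activity-intensity metric feeding the
#' VO2 estimation chain ([vo2_from_mad()]), which consumes milli-g, hence
#' the x1000 conversion from the g-unit input.
#'
#' @param values numeric vector of resultant accelerations in g (one epoch).
#' @return MAD in mg (milli-g).
#' @examples
#' mad_mg(c(1, 3))  # mean 2, mean |dev| 1 g = 1000 mg
#' @export
mad_mg <- function(values) {
  if (length(values) == 0L) stop("empty input")
  values <- as.numeric(values)
  if (anyNA(values)) stop("NA values in input")
  1000 * mean(abs(values - mean(values)))
}

#' Per-epoch MAD of a resultant series
#'
#' Convenience wrapper: tiles the series with [segment_epochs()] and computes
#' [mad_mg()] on each epoch.
#'
#' @inheritParams segment_epochs
#' @return The [segment_epochs()] data.frame with an added `mad_mg` column.
#' @export
epoch_mad <- function(series, epoch_len = 6) {
  ep <- segment_epochs(series, epoch_len)
  ep$mad_mg <- vapply(seq_len(nrow(ep)), function(i) {
    mad_mg(series$r[ep$start_index[i]:(ep$end_index[i] - 1L)])
  }, numeric(1))
  ep
}

#' Resample a recording onto a uniform grid
#'
#' Strict uniformity is the default contract of [triaxial_recording()]; this
#' helper exists for recordings with small timing jitter or a different
#' nominal rate. Each axis is linearly interpolated onto a uniform grid at
#' `fs_target` spanning the original time range.
#'
#' @param t,ax,ay,az raw (possibly non-uniform) series; `t` strictly
#'   increasing, in seconds.
#' @param fs_target target sampling rate in Hz.
#' @return A [triaxial_recording()] at `fs_target`.
#' @export
resample_recording <- function(t, ax, ay, az, fs_target = 100) {
  if (length(t) < 2L) stop("need at least two samples to resample")
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  tt <- seq(t[1L], t[length(t)], by = 1 / fs_target)
  triaxial_recording(
    t = tt - tt[1L],
    ax = stats::approx(t, ax, xout = tt)$y,
    ay = stats::approx(t, ay, xout = tt)$y,
    az = stats::approx(t, az, xout = tt)$y,
    fs = fs_target)
}
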