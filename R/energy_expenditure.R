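#' VO2 from mean amplitude deviation
#'
#' The accelerometer energy-expenditure chain starts from a linear MAD-to-VO2
#' regression, `VO2 = 7.920 + 0.0331 x MAD`, with MAD in milli-g and VO2 in
#' ml per kg per minute. The published form of this equation is
#' typographically ambiguous about the sign of the MAD coefficient; a literal
#' minus would make estimated VO2 fall as movement intensity rises, which
#' contradicts the monotone MAD-intensity relationship the regression
#' lineage establishes, so the default is the increasing ("plus") reading.
#' Set `literal_sign = TRUE` for the literal decreasing form.
#'
#' @param mad_mg MAD in milli-g, >= 0. Vectorised.
#' @param literal_sign use the literal minus coefficient (default `FALSE`).
#' @return VO2 in ml.kg^-1.min^-1.
#' @examples
#' vo2_from_mad(0)      # 7.920, the intercept
#' vo2_from_mad(100)    # 11.23
#' @export
vo2_from_mad <- function(mad_mg, literal_sign = FALSE) {
  if (any(mad_mg < 0)) stop("MAD must be >= 0")
  if (literal_sign) 7.920 - 0.0331 * mad_mg else 7.920 + 0.0331 * mad_mg
}

#' MET from VO2
#'
#' Standard conversion: 1 MET = 3.5 ml O2 per kg per minute.
#'
#' @param vo2 VO2 in ml.kg^-1.min^-1, >= 0. Vectorised.
#' @return MET value(s).
#' @export
met_from_vo2 <- function(vo2) {
  if (any(vo2 < 0)) stop("VO2 must be >= 0")
  vo2 / 3.5
}

#' Weir-equation metabolic rate
#'
#' Abbreviated Weir equation for indirect calorimetry:
#' `kcal/day = 1.44 x (3.94 x VO2 + 1.11 x VCO2)` with both gas exchange
#' rates in ml/min. Passing L/min values produces kcal/day figures ~1000x
#' too small; inputs are ml/min by contract.
#'
#' @param vo2_ml_min oxygen uptake in ml/min, >= 0. Vectorised.
#' @param vco2_ml_min carbon dioxide production in ml/min, >= 0.
#' @return Metabolic rate in kcal/day.
#' @examples
#' weir_kcal_day(250, 200)  # 1738.08
#' @export
weir_kcal_day <- function(vo2_ml_min, vco2_ml_min) {
  if (any(vo2_ml_min < 0) || any(vco2_ml_min < 0))
    stop("gas exchange rates must be >= 0")
  1.44 * (3.94 * vo2_ml_min + 1.11 * vco2_ml_min)
}

#' Per-minute indirect-calorimetry trace
#'
#' @param vo2_ml_min,vco2_ml_min per-minute oxygen uptake and carbon dioxide
#'   production in ml/min; equal lengths, all > 0.
#' @return An object of class `ic_trace` with an added `rer` element
#'   (respiratory exchange ratio, VCO2/VO2, per minute).
#' @export
ic_trace <- function(vo2_ml_min, vco2_ml_min) {
  if (length(vo2_ml_min) != length(vco2_ml_min))
    stop("vo2 and vco2 series must have equal length")
  if (length(vo2_ml_min) == 0L) stop("empty trace")
  if (any(vo2_ml_min <= 0) || any(vco2_ml_min <= 0))
    stop("gas exchange rates must be > 0")
  structure(list(vo2_ml_min = as.numeric(vo2_ml_min),
                 vco2_ml_min = as.numeric(vco2_ml_min),
                 rer = as.numeric(vco2_ml_min) / as.numeric(vo2_ml_min)),
            class = "ic_trace")
}

#' @export
print.ic_trace <- function(x, ...) {
  cat(sprintf("<ic_trace> %d min, VO2 %.0f-%.0f ml/min, RER %.2f-%.2f\n",
              length(x$vo2_ml_min), min(x$vo2_ml_min), max(x$vo2_ml_min),
              min(x$rer), max(x$rer)))
  invisible(x)
}

#' Resting metabolic rate from a supine calorimetry trace
#'
#' Applies the resting-measurement rules: the last 5 minutes of the trace
#' provide the plateau, raw RMR is the Weir metabolic rate of the mean VO2
#' and VCO2 over that window, and a +7% correction compensates for the
#' supine (rather than seated) posture. Minutes whose respiratory exchange
#' ratio falls outside the resting plausibility band \[0.7, 0.99\] are
#' flagged for review but not discarded.
#'
#' @param trace an [ic_trace()] of at least 5 minutes.
#' @return A list of class `rmr_result`: `rmr_kcal_day` (posture-corrected),
#'   `raw_rmr_kcal_day`, and `rer_flags` (minute indices outside the RER
#'   band).
#' @export
rmr_from_ic <- function(trace) {
  stopifnot(inherits(trace, "ic_trace"))
  n <- length(trace$vo2_ml_min)
  if (n < 5L) stop("RMR needs at least 5 minutes of trace")
  win <- (n - 4L):n
  raw <- weir_kcal_day(mean(trace$vo2_ml_min[win]),
                       mean(trace$vco2_ml_min[win]))
  structure(list(rmr_kcal_day = 1.07 * raw,
                 raw_rmr_kcal_day = raw,
                 rer_flags = which(trace$rer < 0.7 | trace$rer > 0.99)),
            class = "rmr_result")
}

#' @export
print.rmr_result <- function(x, ...) {
  cat(sprintf("<rmr_result> RMR %.1f kcal/day (raw %.1f, +7%% posture)\n",
              x$rmr_kcal_day, x$raw_rmr_kcal_day))
  if (length(x$rer_flags))
    cat(sprintf("  RER outside [0.7, 0.99] at minutes: %s\n",
                paste(x$rer_flags, collapse = ", ")))
  invisible(x)
}

#' Freedson adult MET equation
#'
#' The ActiGraph cut-point equation:
#' `MET = 1.439008 + 0.000795 x CPM`, CPM being activity counts per minute.
#' CPM is an input here, never derived from raw acceleration.
#'
#' @param cpm counts per minute, >= 0. Vectorised.
#' @return MET value(s).
#' @examples
#' freedson_met(0)     # 1.439008, the sedentary intercept
#' freedson_met(1000)  # 2.234008
#' @export
freedson_met <- function(cpm) {
  if (any(cpm < 0)) stop("CPM must be >= 0")
  1.439008 + 0.000795 * cpm
}

#' activPAL MET-hours equation
#'
#' `MET.h = 1.4 x d + (4 - 1.4) x (c / 120) x d`, with cadence `c` in
#' steps/min and duration `d` in hours. The published constant is printed as
#' "(4 - 14)", which would give negative energy expenditure at any cadence;
#' the default uses the corrected (4 - 1.4) reading matching the device's
#' published MVPA constant pattern, with the literal form available behind
#' `literal_constant = TRUE`.
#'
#' @param cadence steps per minute, >= 0. Vectorised.
#' @param duration_h activity duration in hours, >= 0.
#' @param literal_constant use the literal (4 - 14) constant (default
#'   `FALSE`).
#' @return Energy expenditure in MET-hours.
#' @examples
#' activpal_met_hours(120, 1)  # 1.4 + 2.6 = 4 MET.h
#' @export
activpal_met_hours <- function(cadence, duration_h, literal_constant = FALSE) {
  if (any(cadence < 0) || any(duration_h < 0))
    stop("cadence and duration must be >= 0")
  k <- if (literal_constant) 4 - 14 else 4 - 1.4
  1.4 * duration_h + k * (cadence / 120) * duration_h
}

#' Total protocol energy expenditure from per-minute data
#'
#' Sums per-minute energy expenditure over a protocol: each minute's
#' metabolic rate (Weir, kcal/day) is divided by 1440 to get that minute's
#' kcal, and the minutes are added together.
#'
#' @param per_minute an [ic_trace()] (per-minute Weir EE is computed from
#'   it) or a numeric vector of per-minute metabolic rates already in
#'   kcal/day.
#' @return Total kcal over the trace.
#' @examples
#' total_ee_protocol(ic_trace(rep(1000, 20), rep(850, 20)))
#' @export
total_ee_protocol <- function(per_minute) {
  if (inherits(per_minute, "ic_trace")) {
    kcal_day <- weir_kcal_day(per_minute$vo2_ml_min, per_minute$vco2_ml_min)
  } else {
    kcal_day <- as.numeric(per_minute)
    if (length(kcal_day) == 0L) stop("empty per-minute series")
    if (any(kcal_day < 0)) stop("per-minute EE must be >= 0")
  }
  sum(kcal_day / 1440)
}

#' Per-segment MET estimate from the MAD chain
#'
#' For each protocol segment: MAD is computed on fixed-length epochs whose
#' start lies in the segment, converted to VO2 ([vo2_from_mad()]) and MET
#' ([met_from_vo2()]) per epoch, and averaged.
#'
#' @param series a [resultant_norm()] series.
#' @param segments protocol data.frame (`speed_kmh`, `start_s`, `end_s`).
#' @param epoch_len MAD epoch length in seconds (default 6).
#' @param literal_sign passed to [vo2_from_mad()].
#' @return The `segments` data.frame with an added `met` column.
#' @export
met_per_segment <- function(series, segments, epoch_len = 6,
                            literal_sign = FALSE) {
  stopifnot(inherits(series, "resultant_series"))
  validate_segments(segments, max(series$t))
  ep <- epoch_mad(series, epoch_len)
  met <- met_from_vo2(vo2_from_mad(ep$mad_mg, literal_sign = literal_sign))
  out <- segments
  out$met <- vapply(seq_len(nrow(segments)), function(i) {
    in_seg <- ep$start_t >= segments$start_s[i] &
      ep$start_t < segments$end_s[i]
    if (!any(in_seg))
      stop(sprintf("segment %d is shorter than one %g s epoch", i, epoch_len))
    mean(met[in_seg])
  }, numeric(1))
  out
}
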