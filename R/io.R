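#' Read a raw triaxial acceleration CSV
#'
#' Expected format: header `time,ax,ay,az`; time in seconds, axes in g,
#' comma-separated with `.` decimals. The sampling rate is inferred from the
#' median timestamp spacing and uniformity is enforced (a timing gap is
#' reported with the offending row).
#'
#' @param path path to the CSV file.
#' @return A [triaxial_recording()].
#' @export
read_raw_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time", "ax", "ay", "az")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  for (col in req) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric value in column %s at data row %d",
                     col, bad[1L]))
      df[[col]] <- vn
    }
  }
  triaxial_recording(df$time, df$ax, df$ay, df$az)
}

#' Write a recording as raw CSV
#'
#' Inverse of [read_raw_csv()]; full double precision is kept so a
#' write-read round trip reproduces the recording.
#'
#' @param rec a [triaxial_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raw_csv <- function(rec, path) {
  stopifnot(inherits(rec, "triaxial_recording"))
  df <- data.frame(time = rec$t, ax = rec$ax, ay = rec$ay, az = rec$az)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a protocol description from JSON
#'
#' The JSON is an array of segment objects with `speed_kmh`, `duration_s`
#' and optionally `true_steps`; segments are laid out back to back from
#' time 0.
#'
#' @param path path to the JSON file.
#' @return A protocol data.frame (`speed_kmh`, `start_s`, `end_s`, and
#'   `true_steps` when present).
#' @export
read_protocol_json <- function(path) {
  segs <- jsonlite::fromJSON(path)
  if (!all(c("speed_kmh", "duration_s") %in% names(segs)))
    stop("protocol JSON needs speed_kmh and duration_s per segment")
  if (any(segs$duration_s <= 0)) stop("segment durations must be > 0")
  ends <- cumsum(segs$duration_s)
  out <- data.frame(speed_kmh = segs$speed_kmh,
                    start_s = c(0, ends[-length(ends)]), end_s = ends)
  if (!is.null(segs$true_steps)) out$true_steps <- segs$true_steps
  out
}

#' Read / write detector parameters as JSON
#'
#' Parameters are serialized as a flat JSON object with the six named
#' thresholds.
#'
#' @param path JSON path.
#' @return [read_params_json()]: a [detector_params()];
#'   [write_params_json()]: `path`, invisibly.
#' @export
read_params_json <- function(path) {
  p <- jsonlite::fromJSON(path)
  detector_params(p$theta_I, p$theta_II, p$theta_III, p$theta_IV,
                  p$theta_V_max, p$theta_V_min)
}

#' @rdname read_params_json
#' @param params a [detector_params()].
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "detector_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a per-minute indirect-calorimetry CSV
#'
#' Expected header: `minute,vo2_ml_min,vco2_ml_min`.
#'
#' @param path CSV path.
#' @return An [ic_trace()] in minute order.
#' @export
read_ic_csv <- function(path) {
  df <- utils::read.csv(path)
  req <- c("minute", "vo2_ml_min", "vco2_ml_min")
  if (!all(req %in% names(df)))
    stop("IC CSV needs columns minute, vo2_ml_min, vco2_ml_min")
  df <- df[order(df$minute), ]
  ic_trace(df$vo2_ml_min, df$vco2_ml_min)
}

# stable polynomial rolling hash of a config for the run manifest
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 0
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Default pipeline configuration
#'
#' @param seed master seed; every random stage derives its seed from it.
#' @param n_train,n_holdout simulated cohort sizes.
#' @param speeds protocol speeds in km/h.
#' @param grid a [param_grid()] for the optimizer.
#' @param epoch_len MAD epoch length in seconds.
#' @param body_mass body mass in kg for the IC simulation.
#' @param literal_ee_sign,icc_type the equation-sign and ICC-model choices,
#'   logged on every run.
#' @param out_dir output directory (`NULL` for no files).
#' @param verbose print stage progress.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_train = 10, n_holdout = 10,
                       speeds = c(3, 4.5, 6, 9), grid = param_grid(),
                       epoch_len = 6, body_mass = 70,
                       literal_ee_sign = FALSE, icc_type = "ICC2_1",
                       out_dir = NULL, verbose = FALSE) {
  structure(list(seed = seed, n_train = n_train, n_holdout = n_holdout,
                 speeds = speeds, grid = grid, epoch_len = epoch_len,
                 body_mass = body_mass, literal_ee_sign = literal_ee_sign,
                 icc_type = icc_type, out_dir = out_dir, verbose = verbose),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Any field of [run_config()] may be set; `grid` axes are given as named
#' lists of candidate values.
#'
#' @param path YAML path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$grid)) y$grid <- do.call(param_grid, y$grid)
  do.call(run_config, y)
}

#' Run the full synthetic validation pipeline
#'
#' End-to-end: simulate a training cohort, optimize the detector thresholds
#' by exhaustive grid search, count steps on a held-out cohort with the
#' optimized gate, run the agreement battery on the held-out step counts,
#' and estimate energy expenditure (MAD chain vs a simulated
#' indirect-calorimetry reference) for the first held-out subject. Writes
#' steps, parameters, the agreement table and a manifest (config hash and
#' seeds) when `out_dir` is set.
#'
#' @param config a [run_config()] or a YAML path accepted by
#'   [read_run_config()].
#' @return A list of class `pipeline_result`: `params`
#'   (optimized [detector_params()]), `train_objective`, `holdout_mape`
#'   (list from [mape()] on per-subject totals), `agreement`
#'   ([evaluate_device()] table on per-segment counts), `energy`
#'   (per-segment MET table plus total protocol kcal), `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (config$verbose) message(sprintf(...))
  say("EE sign convention: %s; ICC model: %s",
      if (config$literal_ee_sign) "literal minus" else "plus",
      config$icc_type)

  protocol <- study_protocol(speeds = config$speeds)
  sim_cfg <- gait_sim_config()

  say("simulate: training cohort n=%d (seed %d)", config$n_train,
      config$seed)
  train <- simulate_cohort(config$n_train, protocol, sim_cfg,
                           seed = config$seed)
  say("simulate: held-out cohort n=%d (seed %d)", config$n_holdout,
      config$seed + 1)
  holdout <- simulate_cohort(config$n_holdout, protocol, sim_cfg,
                             seed = config$seed + 1)

  say("optimize: exhaustive grid search")
  training <- lapply(train, function(s) training_example(s$recording,
                                                         s$segments))
  fit <- grid_search(config$grid, training, keep_scores = FALSE)

  say("detect: held-out cohort")
  rows <- list()
  totals_actual <- integer(0); totals_est <- integer(0)
  for (i in seq_along(holdout)) {
    res <- count_steps(holdout[[i]]$recording, fit$best_params,
                       holdout[[i]]$segments)
    rows[[i]] <- data.frame(subject = i,
                            speed_kmh = res$per_segment$speed_kmh,
                            actual = holdout[[i]]$segments$true_steps,
                            estimated = res$per_segment$steps)
    totals_actual <- c(totals_actual,
                       sum(holdout[[i]]$segments$true_steps))
    totals_est <- c(totals_est, res$total)
  }
  counts <- do.call(rbind, rows)
  holdout_mape <- mape(totals_actual, totals_est)
  agreement <- evaluate_device(counts, icc_type = config$icc_type)

  say("energy: MAD chain vs simulated indirect calorimetry")
  sub1 <- holdout[[1L]]
  series <- resultant_norm(sub1$recording)
  met_tab <- met_per_segment(series, sub1$segments,
                             epoch_len = config$epoch_len,
                             literal_sign = config$literal_ee_sign)
  ic <- simulate_ic_trace(protocol, met_per_speed =
                            stats::setNames(met_tab$met,
                                            met_tab$speed_kmh),
                          body_mass = config$body_mass,
                          seed = config$seed + 2, noise_sd = 0.05)
  energy <- list(met_per_segment = met_tab,
                 ic_total_kcal = total_ee_protocol(ic))

  manifest <- list(config_hash = config_hash(unclass(config)[
    setdiff(names(unclass(config)), c("out_dir", "verbose"))]),
    seed = config$seed,
    seeds = list(train = config$seed, holdout = config$seed + 1,
                 ic = config$seed + 2),
    ee_sign = if (config$literal_ee_sign) "literal-minus" else "plus",
    icc_type = config$icc_type)

  out <- structure(list(params = fit$best_params,
                        train_objective = fit$objective,
                        holdout_counts = counts,
                        holdout_mape = holdout_mape,
                        agreement = agreement, energy = energy,
                        manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_params_json(fit$best_params,
                      file.path(config$out_dir, "best_params.json"))
    utils::write.csv(counts, file.path(config$out_dir, "steps.csv"),
                     row.names = FALSE)
    utils::write.csv(agreement, file.path(config$out_dir, "agreement.csv"),
                     row.names = FALSE)
    utils::write.csv(energy$met_per_segment,
                     file.path(config$out_dir, "energy.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$params)
  cat(sprintf("  training mean relative error: %.4f\n", x$train_objective))
  cat(sprintf("  held-out total-step MAPE: %.2f%%%s\n",
              x$holdout_mape$mean_pct,
              if (x$holdout_mape$disagreement)
                " (relevant disagreement)" else ""))
  invisible(x)
}
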