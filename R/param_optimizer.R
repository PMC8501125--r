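#' Relative step-count error
#'
#' `|detected - actual| / actual`, the per-segment training loss of the
#' supervised threshold search. Vectorised over both arguments.
#'
#' @param detected detected step count(s).
#' @param actual ground-truth (video-counted) step count(s), >= 1.
#' @return Absolute relative error(s) as fractions.
#' @examples
#' relative_error(110, 100)  # 0.1
#' @export
relative_error <- function(detected, actual) {
  if (any(actual < 1)) stop("actual step counts must be >= 1")
  abs(detected - actual) / actual
}

#' Assemble a training example
#'
#' Pairs a recording with protocol segments carrying video-truth step counts.
#'
#' @param recording a [triaxial_recording()].
#' @param segments protocol data.frame with `speed_kmh`, `start_s`, `end_s`
#'   and `true_steps` (all >= 1).
#' @return A list of class `training_example`.
#' @export
training_example <- function(recording, segments) {
  stopifnot(inherits(recording, "triaxial_recording"))
  if (is.null(segments$true_steps) || any(segments$true_steps < 1))
    stop("every segment needs true_steps >= 1")
  validate_segments(segments, max(recording$t))
  structure(list(recording = recording, segments = segments),
            class = "training_example")
}

#' Mean relative error of a parameter set over a training set
#'
#' The optimisation objective: the unweighted mean of [relative_error()]
#' over every (example, segment) pair. Per-speed weights can be supplied to
#' emphasise particular speeds.
#'
#' @param params a [detector_params()].
#' @param training list of [training_example()] objects.
#' @param speed_weights optional named numeric vector of weights keyed by
#'   speed (km/h as character); defaults to unweighted.
#' @return The mean relative error (fraction).
#' @export
step_error_objective <- function(params, training, speed_weights = NULL) {
  if (length(training) == 0L) stop("training set is empty")
  errs <- numeric(0); wts <- numeric(0)
  for (ex in training) {
    res <- count_steps(ex$recording, params, ex$segments)
    e <- relative_error(res$per_segment$steps, ex$segments$true_steps)
    w <- if (is.null(speed_weights)) rep(1, length(e)) else
      speed_weights[as.character(ex$segments$speed_kmh)]
    errs <- c(errs, e); wts <- c(wts, w)
  }
  sum(errs * wts) / sum(wts)
}

#' Candidate-value grids for the six detector thresholds
#'
#' Each axis is a sorted vector of candidate values; [grid_search()] scans
#' the full Cartesian product. The defaults bracket human cadence (step
#' frequency roughly 0.5-3 Hz) and the amplitude range of walking-to-running
#' impulses on the gravity-inclusive resultant; they are starting points, not
#' measured constants, and are meant to be overridden per device.
#'
#' @param theta_I excursion-threshold candidates (g).
#' @param theta_II amplitude-threshold candidates (g).
#' @param theta_III slope-threshold candidates (g/s).
#' @param theta_IV area-threshold candidates (g.s).
#' @param theta_V_max maximum-gap candidates (s).
#' @param theta_V_min minimum-gap (refractory) candidates (s).
#' @return A list of class `param_grid`.
#' @export
param_grid <- function(theta_I = seq(1.05, 1.6, by = 0.05),
                       theta_II = seq(1.1, 2.5, by = 0.1),
                       theta_III = seq(0, 20, by = 2),
                       theta_IV = seq(0, 0.4, by = 0.05),
                       theta_V_max = seq(0.6, 2.0, by = 0.2),
                       theta_V_min = 0.2) {
  g <- list(theta_I = theta_I, theta_II = theta_II, theta_III = theta_III,
            theta_IV = theta_IV, theta_V_max = theta_V_max,
            theta_V_min = theta_V_min)
  for (nm in names(g)) {
    v <- as.numeric(g[[nm]])
    if (length(v) == 0L) stop(sprintf("empty grid axis: %s", nm))
    if (is.unsorted(v, strictly = TRUE))
      stop(sprintf("grid axis %s must be sorted ascending", nm))
    g[[nm]] <- v
  }
  structure(g, class = "param_grid")
}

#' @export
print.param_grid <- function(x, ...) {
  sizes <- vapply(x, length, 1L)
  cat(sprintf("<param_grid> %s points (%s)\n",
              format(prod(sizes), big.mark = ","),
              paste(sprintf("%s:%d", names(sizes), sizes), collapse = ", ")))
  invisible(x)
}

#' Exhaustive supervised threshold search
#'
#' Evaluates the step detector at every point of the Cartesian product of
#' the six grid axes against video-truth step counts, and returns the
#' parameter combination with the lowest mean relative error. The scan is
#' deterministic: combinations are ordered lexicographically by
#' (`theta_I`, `theta_II`, `theta_III`, `theta_IV`, `theta_V_max`,
#' `theta_V_min`) and ties are broken by the earliest point in that order.
#'
#' Combinations violating the gate's structural constraints
#' (`theta_II >= theta_I`, `theta_V_min < theta_V_max`) appear in the score
#' table with `objective = NA` and are excluded from the argmin, so the
#' table always has exactly `prod(lengths(grid))` rows.
#'
#' Excursion finding and feature extraction depend only on `theta_I`, so
#' features are computed once per (`theta_I`, recording) and the sequential
#' gate is replayed over all remaining combinations in compiled code.
#'
#' @param grid a [param_grid()].
#' @param training list of [training_example()] objects.
#' @param speed_weights optional per-speed weights, see
#'   [step_error_objective()].
#' @param keep_scores return the full score table (default `TRUE`).
#' @return A list of class `grid_search_result`: `best_params`
#'   ([detector_params()]), `objective` (mean relative error at the optimum),
#'   and `scores` (data.frame of every combination with its objective).
#' @export
grid_search <- function(grid, training, speed_weights = NULL,
                        keep_scores = TRUE) {
  stopifnot(inherits(grid, "param_grid"))
  if (length(training) == 0L) stop("training set is empty")

  # per-example invariants: series, segment ids and weights
  prep <- lapply(training, function(ex) {
    series <- resultant_norm(ex$recording)
    validate_segments(ex$segments, max(series$t))
    w <- if (is.null(speed_weights)) rep(1, nrow(ex$segments)) else
      as.numeric(speed_weights[as.character(ex$segments$speed_kmh)])
    list(series = series, segments = ex$segments, weights = w,
         true_steps = ex$segments$true_steps)
  })
  w_total <- sum(vapply(prep, function(p) sum(p$weights), numeric(1)))

  # inner combos (all axes but theta_I), lexicographic with theta_V_min
  # fastest; expand.grid varies its first factor fastest
  inner <- expand.grid(theta_V_min = grid$theta_V_min,
                       theta_V_max = grid$theta_V_max,
                       theta_IV = grid$theta_IV,
                       theta_III = grid$theta_III,
                       theta_II = grid$theta_II,
                       KEEP.OUT.ATTRS = FALSE)
  inner <- inner[, c("theta_II", "theta_III", "theta_IV",
                     "theta_V_max", "theta_V_min")]
  n_inner <- nrow(inner)

  blocks <- vector("list", length(grid$theta_I))
  for (bi in seq_along(grid$theta_I)) {
    th1 <- grid$theta_I[bi]
    feasible <- inner$theta_II >= th1 &
      inner$theta_V_min < inner$theta_V_max
    obj <- rep(NA_real_, n_inner)
    if (any(feasible)) {
      combo_mat <- as.matrix(inner[feasible, , drop = FALSE])
      th2_min <- min(combo_mat[, "theta_II"])
      err_sum <- numeric(sum(feasible))
      for (p in prep) {
        feats <- peak_features(p$series, th1)
        keep <- feats$amplitude >= th2_min   # fails every combo otherwise
        feats <- feats[keep, , drop = FALSE]
        seg_id <- segment_index(feats$peak_t, p$segments)
        counts <- gate_count_grid_cpp(feats$peak_t, feats$amplitude,
                                      feats$slope, feats$area,
                                      seg_id, nrow(p$segments), combo_mat)
        rel <- abs(sweep(counts, 2L, p$true_steps)) /
          matrix(p$true_steps, nrow(counts), length(p$true_steps),
                 byrow = TRUE)
        err_sum <- err_sum + as.vector(rel %*% p$weights)
      }
      obj[feasible] <- err_sum / w_total
    }
    blk <- inner
    blk$theta_I <- th1
    blk$objective <- obj
    blocks[[bi]] <- blk[, c("theta_I", "theta_II", "theta_III", "theta_IV",
                            "theta_V_max", "theta_V_min", "objective")]
  }
  scores <- do.call(rbind, blocks)
  rownames(scores) <- NULL
  if (all(is.na(scores$objective)))
    stop("no feasible grid point (check theta_II vs theta_I ranges)")
  best_i <- which.min(replace(scores$objective, is.na(scores$objective), Inf))
  best <- scores[best_i, ]
  structure(list(
    best_params = detector_params(best$theta_I, best$theta_II,
                                  best$theta_III, best$theta_IV,
                                  best$theta_V_max, best$theta_V_min),
    objective = best$objective,
    scores = if (keep_scores) scores else NULL),
    class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search_result> best mean relative error %.4f\n",
              x$objective))
  print(x$best_params)
  invisible(x)
}

# 0-based protocol-segment index of each peak time; -1 outside all segments
segment_index <- function(peak_t, segments) {
  id <- rep(-1L, length(peak_t))
  for (i in seq_len(nrow(segments))) {
    id[peak_t >= segments$start_s[i] & peak_t < segments$end_s[i]] <-
      i - 1L
  }
  id
}
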