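#' Build a bias detection curve
#'
#' A bias detection curve plots, for one MA procedure, the median number of
#' results needed to detect each simulated bias size against the bias size in
#' percent. An `NA` median marks a bias the procedure never detected.
#'
#' @param summaries Data frame of per-bias rows as produced by
#'   [summarize_runs()] / [simulate_bias_grid()], all from one procedure.
#' @param config_id Identifier of the procedure.
#' @return An object of class `bias_detection_curve`: a data frame with
#'   columns `bias_percent` and `median_n`, ordered by `bias_percent`.
#' @export
build_bias_detection_curve <- function(summaries, config_id) {
  stopifnot(all(c("bias_percent", "median_n") %in% names(summaries)))
  if (anyDuplicated(summaries$bias_percent))
    stop_validation("summaries contain duplicated bias sizes")
  df <- summaries[order(summaries$bias_percent), c("bias_percent", "median_n")]
  rownames(df) <- NULL
  structure(df, config_id = config_id,
            class = c("bias_detection_curve", "data.frame"))
}

#' Build validation-chart data
#'
#' A validation chart shows, per bias size, the median (bar) and minimum /
#' maximum (error bars) number of results needed for detection, plus the
#' fraction of injections in which the bias was detected at all.
#'
#' @inheritParams build_bias_detection_curve
#' @param config Optional [ma_config()] of the procedure; stored for
#'   tie-breaking in [rank_candidates()].
#' @return An object of class `validation_chart`: a data frame with columns
#'   `bias_percent`, `median_n`, `min_n`, `max_n`, `detected_fraction`.
#' @export
build_validation_chart <- function(summaries, config_id, config = NULL) {
  needed <- c("bias_percent", "median_n", "min_n", "max_n", "n_runs", "n_detected")
  stopifnot(all(needed %in% names(summaries)))
  df <- summaries[order(summaries$bias_percent), ]
  out <- data.frame(bias_percent = df$bias_percent, median_n = df$median_n,
                    min_n = df$min_n, max_n = df$max_n,
                    detected_fraction = df$n_detected / df$n_runs)
  rownames(out) <- NULL
  structure(out, config_id = config_id, config = config,
            class = c("validation_chart", "data.frame"))
}

#' Optimization criteria for candidate MA procedures
#'
#' Encodes the two selection criteria: (a) a clinically significant bias (the
#' TEa) must be detectable with certainty within the analyte's daily number of
#' results, and (b) every bias larger than the TEa must remain detectable
#' within the daily volume (all of them are clinically significant too).
#' Certainty is judged on the worst case: every injection must detect, and the
#' maximum results-to-detection must not exceed the daily volume.
#'
#' @param tea_percent Allowable total error in percent (unrounded; it is
#'   rounded with [round_tea()] to locate the grid rows).
#' @param daily_volume Average daily number of results for the analyte.
#' @param require_all_larger_biases If `FALSE`, criterion (b) is skipped.
#' @return An object of class `optimization_criteria`.
#' @export
optimization_criteria <- function(tea_percent, daily_volume,
                                  require_all_larger_biases = TRUE) {
  if (!is_scalar_number(tea_percent) || tea_percent <= 0)
    stop_validation("'tea_percent' must be a positive number")
  if (!is_scalar_number(daily_volume) || daily_volume < 1)
    stop_validation("'daily_volume' must be a positive integer")
  structure(list(tea_percent = tea_percent,
                 daily_volume = as.integer(daily_volume),
                 require_all_larger_biases = isTRUE(require_all_larger_biases)),
            class = "optimization_criteria")
}

#' Judge one candidate procedure against the optimization criteria
#'
#' @param chart A [build_validation_chart()] result covering both signed TEa
#'   rows and the full bias grid.
#' @param criteria An [optimization_criteria()] object.
#' @return A list of class `candidate_evaluation` with logical flags
#'   `tea_detectable_within_day`, `large_bias_safe` and `feasible`.
#' @export
evaluate_candidate <- function(chart, criteria) {
  stopifnot(inherits(chart, "validation_chart"),
            inherits(criteria, "optimization_criteria"))
  tea_r <- round_tea(criteria$tea_percent)
  tea_rows <- chart[chart$bias_percent %in% c(-tea_r, tea_r), ]
  if (nrow(tea_rows) != 2L)
    stop_validation("chart is missing the +/-", tea_r, "% (TEa) bias rows")

  within_day <- function(rows) {
    nrow(rows) == 0L ||
      all(rows$detected_fraction == 1 & rows$max_n <= criteria$daily_volume)
  }
  a <- within_day(tea_rows)
  large_rows <- chart[abs(chart$bias_percent) > tea_r, ]
  b <- within_day(large_rows)

  structure(list(config_id = attr(chart, "config_id"),
                 tea_percent_rounded = tea_r,
                 daily_volume = criteria$daily_volume,
                 tea_detectable_within_day = a,
                 large_bias_safe = b,
                 feasible = a && (b || !criteria$require_all_larger_biases)),
            class = "candidate_evaluation")
}

#' @export
print.candidate_evaluation <- function(x, ...) {
  cat(sprintf("<candidate_evaluation> %s: TEa (+/-%d%%) within %d/day: %s; large biases safe: %s; feasible: %s\n",
              x$config_id %||% "?", x$tea_percent_rounded, x$daily_volume,
              x$tea_detectable_within_day, x$large_bias_safe, x$feasible))
  invisible(x)
}

#' Rank candidate MA procedures
#'
#' Candidates are partitioned into feasible and infeasible under
#' [evaluate_candidate()]; feasible candidates are ordered by ascending median
#' results-to-detection at +TEa, then at -TEa, then by the worst (largest)
#' median over all biases at least as large as the TEa. Remaining ties prefer
#' the simpler procedure: fewer truncation limits, then larger weighting
#' factor / smaller batch size, then the identifier. The ordering is
#' deterministic for identical inputs.
#'
#' @param charts List of [build_validation_chart()] objects (one per
#'   candidate).
#' @param criteria An [optimization_criteria()] object.
#' @return Data frame with one row per candidate, ordered by `rank`, carrying
#'   `config_id`, `feasible`, `reason`, the ranking metrics and the rank.
#' @export
rank_candidates <- function(charts, criteria) {
  stopifnot(length(charts) >= 1L)
  tea_r <- round_tea(criteria$tea_percent)

  rows <- lapply(charts, function(chart) {
    ev <- evaluate_candidate(chart, criteria)
    cfg <- attr(chart, "config", exact = TRUE)
    med_at <- function(b) {
      m <- chart$median_n[chart$bias_percent == b]
      if (length(m) && !is.na(m)) m else Inf
    }
    ge_tea <- chart[abs(chart$bias_percent) >= tea_r, ]
    worst <- if (any(is.na(ge_tea$median_n))) Inf else max(ge_tea$median_n)
    reason <- if (ev$feasible) "feasible"
      else if (!ev$tea_detectable_within_day)
        "TEa bias not reliably detected within the daily volume"
      else "loses detection of biases larger than the TEa"
    data.frame(config_id = attr(chart, "config_id"),
               feasible = ev$feasible, reason = reason,
               median_plus_tea = med_at(tea_r),
               median_minus_tea = med_at(-tea_r),
               worst_large_median = worst,
               n_truncation = if (!is.null(cfg)) n_truncation_limits(cfg$truncation) else NA_integer_,
               weighting_factor = if (!is.null(cfg) && !is.null(cfg$weighting_factor))
                 cfg$weighting_factor else NA_real_,
               batch_size = if (!is.null(cfg) && !is.null(cfg$batch_size))
                 cfg$batch_size else NA_integer_)
  })
  df <- do.call(rbind, rows)

  key_num <- function(x, na = Inf) ifelse(is.na(x), na, x)
  ord <- order(!df$feasible,
               df$median_plus_tea, df$median_minus_tea, df$worst_large_median,
               key_num(df$n_truncation),
               -key_num(df$weighting_factor, na = 0),
               key_num(df$batch_size),
               df$config_id)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
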