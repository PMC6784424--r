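#' Round an allowable total error to an integer bias percentage
#'
#' Bias simulation works on integer percentages, so the analyte's allowable
#' total error (TEa) is rounded to the nearest integer, halves away from zero
#' (e.g. a TEa of 17.97% is simulated as an 18% bias, 3.57% as 4%).
#'
#' @param tea_percent Positive TEa in percent.
#' @return Integer percent.
#' @export
round_tea <- function(tea_percent) {
  stopifnot(is.numeric(tea_percent), all(tea_percent > 0))
  as.integer(sign(tea_percent) * floor(abs(tea_percent) + 0.5))
}

#' Build the grid of simulated bias sizes
#'
#' The default grid is +/- {50, 40, 30, 20, 10, 5, 3, 1} percent; when a TEa
#' is supplied, +/- [round_tea()] of it is added if not already present.
#'
#' @param tea_percent Optional TEa in percent (unrounded).
#' @param base Base magnitudes in percent.
#' @return Sorted numeric vector of signed bias percentages.
#' @export
bias_grid <- function(tea_percent = NULL, base = c(1, 3, 5, 10, 20, 30, 40, 50)) {
  mags <- base
  if (!is.null(tea_percent)) mags <- c(mags, round_tea(tea_percent))
  sort(unique(c(-mags, mags)))
}

#' Inject a persistent proportional bias into a value sequence
#'
#' Values before `start` are unchanged; values at and after `start` are
#' multiplied by `1 + bias_percent / 100`. The bias persists to the end of the
#' sequence, emulating a systematic analytical shift.
#'
#' @param values Numeric vector in measurement order.
#' @param start 1-based index of the first biased result.
#' @param bias_percent Signed bias in percent.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' inject_bias(c(140, 140, 140), start = 2, bias_percent = 4)
inject_bias <- function(values, start, bias_percent) {
  stopifnot(start >= 1, start <= length(values) + 1)
  out <- values
  if (start <= length(values))
    out[start:length(values)] <- out[start:length(values)] * (1 + bias_percent / 100)
  out
}

#' Simulate one bias injection and measure results-to-detection
#'
#' Replays the unbiased stream up to just before `injection_index` to
#' establish the MA state under `config` (truncation applied; EWMA
#' "population mean" initialization uses the accepted values of the full
#' unbiased stream). From `injection_index` on, each result is presented with
#' the bias applied; truncation is evaluated on the biased value, the MA
#' updates on accepted results only, and the alarm is checked after each
#' update.
#'
#' `n_to_detection` counts all results presented after injection — accepted
#' and truncation-rejected alike — up to and including the first alarming one
#' (it measures patient-result exposure); `n_accepted_to_detection` counts
#' only the accepted ones. A run with no alarm within `window` results is
#' censored.
#'
#' @param stream A `result_stream` or numeric vector of results.
#' @param config An [ma_config()].
#' @param limits `control_limits` derived from the unbiased stream under the
#'   same config (a mismatching `config_id` raises an error).
#' @param injection_index 1-based index of the first biased result.
#' @param bias_percent Signed bias in percent.
#' @param window Maximum number of presented results before censoring
#'   (default 400).
#' @return One-row data frame with columns `injection_index`, `bias_percent`,
#'   `window`, `n_to_detection`, `n_accepted_to_detection`, `censored`.
#' @export
run_single_simulation <- function(stream, config, limits, injection_index,
                                  bias_percent, window = 400) {
  stopifnot(inherits(config, "ma_config"), inherits(limits, "control_limits"))
  values <- if (is.numeric(stream)) stream else stream$value
  nlen <- length(values)
  if (injection_index < 1 || injection_index > nlen)
    stop_validation("injection_index must fall within the stream")
  if (!is.null(limits$config_id) && !identical(limits$config_id, config$id))
    stop_validation("control limits were derived under config '", limits$config_id,
                    "' but the simulation uses '", config$id, "'")

  window <- min(window, nlen - injection_index + 1L)
  mask_full <- apply_truncation(values, config$truncation)

  pre_values <- values[seq_len(injection_index - 1L)]
  pre_acc <- pre_values[mask_full[seq_len(injection_index - 1L)]]

  vb <- values[injection_index:(injection_index + window - 1L)] *
    (1 + bias_percent / 100)
  mb <- apply_truncation(vb, config$truncation)
  xa <- vb[mb]

  if (length(xa)) {
    if (config$algorithm == "simple") {
      n <- config$batch_size
      pre_t <- utils::tail(pre_acc, n - 1L)
      m <- length(pre_t)
      # same convolution arithmetic as compute_simple_ma, so that replaying
      # the unbiased stream reproduces the limit-defining MA bit for bit
      z <- trailing_mean(c(pre_t, xa), n)[m + seq_along(xa)]
    } else {
      lambda <- config$weighting_factor
      init0 <- resolve_init(values, mask_full, config)
      z0 <- if (length(pre_acc))
        as.numeric(stats::filter(lambda * pre_acc, 1 - lambda,
                                 method = "recursive", init = init0))[length(pre_acc)]
      else init0
      z <- as.numeric(stats::filter(lambda * xa, 1 - lambda,
                                    method = "recursive", init = z0))
    }
    alarm <- !is.na(z) & check_alarm(z, limits)
    jstar <- which(alarm)[1]
  } else {
    jstar <- NA_integer_
  }

  if (is.na(jstar)) {
    data.frame(injection_index = injection_index, bias_percent = bias_percent,
               window = window, n_to_detection = NA_integer_,
               n_accepted_to_detection = NA_integer_, censored = TRUE)
  } else {
    pos_acc <- which(mb)
    data.frame(injection_index = injection_index, bias_percent = bias_percent,
               window = window, n_to_detection = pos_acc[jstar],
               n_accepted_to_detection = jstar, censored = FALSE)
  }
}

#' Run the full bias-injection grid over a stream
#'
#' The stream is divided into consecutive non-overlapping blocks of `block`
#' results. Bias is injected at the first result of each block from the
#' second block onward (so the MA state is warmed by at least one block of
#' unbiased results), and each injection is followed for at most `block`
#' results. Every bias size in `grid` is simulated at every injection point,
#' and runs are aggregated per bias size by [summarize_runs()].
#'
#' @param stream A `result_stream` or numeric vector, length >= `2 * block`.
#' @param config An [ma_config()].
#' @param limits Optional `control_limits`; derived from the unbiased stream
#'   under `config` when omitted.
#' @param grid Numeric vector of signed bias percentages (see [bias_grid()]).
#' @param block Block length; also the detection window (default 400).
#' @return An object of class `bias_simulation`: a list with `runs` (one row
#'   per injection x bias), `summaries` (one row per bias, see
#'   [summarize_runs()]), `limits`, `config_id` and `analyte`.
#' @export
simulate_bias_grid <- function(stream, config, limits = NULL,
                               grid = bias_grid(), block = 400) {
  values <- if (is.numeric(stream)) stream else stream$value
  if (length(values) < 2 * block)
    stop_validation("stream must contain at least 2 * block results")
  if (is.null(limits))
    limits <- derive_control_limits(compute_ma_series(stream, config))

  n_blocks <- floor(length(values) / block)
  injections <- block * seq_len(n_blocks - 1L) + 1L

  runs <- do.call(rbind, lapply(grid, function(b) {
    do.call(rbind, lapply(injections, function(i) {
      run_single_simulation(stream, config, limits, i, b, window = block)
    }))
  }))
  summaries <- do.call(rbind, lapply(split(runs, runs$bias_percent),
                                     summarize_runs))
  summaries <- summaries[order(summaries$bias_percent), , drop = FALSE]
  rownames(summaries) <- NULL

  structure(list(runs = runs, summaries = summaries, limits = limits,
                 config_id = config$id,
                 analyte = if (!is.numeric(stream)) attr(stream, "analyte")),
            class = "bias_simulation")
}

#' @export
print.bias_simulation <- function(x, ...) {
  cat(sprintf("<bias_simulation> %s%s: %d runs over %d bias sizes, limits [%g, %g]\n",
              x$analyte %||% "", if (is.null(x$analyte)) x$config_id
              else paste0(" / ", x$config_id),
              nrow(x$runs), nrow(x$summaries), x$limits$lower, x$limits$upper))
  print(x$summaries)
  invisible(x)
}

#' Aggregate injection runs of one bias size
#'
#' Median, minimum and maximum of `n_to_detection` are computed over detected
#' (non-censored) runs only; the median of an even count is the mean of the
#' two central values. When no run detected the bias, the three statistics
#' are `NA`.
#'
#' @param runs Data frame of rows from [run_single_simulation()], all sharing
#'   one `bias_percent`.
#' @return One-row data frame: `bias_percent`, `median_n`, `min_n`, `max_n`,
#'   `n_runs`, `n_detected`.
#' @export
summarize_runs <- function(runs) {
  stopifnot(length(unique(runs$bias_percent)) == 1L)
  det <- runs$n_to_detection[!runs$censored]
  if (length(det)) {
    data.frame(bias_percent = runs$bias_percent[1],
               median_n = stats::median(det), min_n = min(det), max_n = max(det),
               n_runs = nrow(runs), n_detected = length(det))
  } else {
    data.frame(bias_percent = runs$bias_percent[1],
               median_n = NA_real_, min_n = NA_integer_, max_n = NA_integer_,
               n_runs = nrow(runs), n_detected = 0L)
  }
}
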