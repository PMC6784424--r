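#' Truncation limits for result inclusion
#'
#' Truncation limits are the end points of the concentration range included in
#' moving-average calculation; results outside them are treated as outliers
#' and excluded. Limits are inclusive: a result exactly equal to a limit is
#' accepted.
#'
#' @param lower,upper Optional numeric bounds (analyte units); `NULL` means no
#'   bound on that side.
#' @return An object of class `truncation_limits`.
#' @export
truncation_limits <- function(lower = NULL, upper = NULL) {
  if (!is.null(lower) && !is_scalar_number(lower))
    stop_validation("truncation 'lower' must be a single number or NULL")
  if (!is.null(upper) && !is_scalar_number(upper))
    stop_validation("truncation 'upper' must be a single number or NULL")
  if (!is.null(lower) && !is.null(upper) && lower >= upper)
    stop_validation("truncation limits must satisfy lower < upper")
  structure(list(lower = lower, upper = upper), class = "truncation_limits")
}

n_truncation_limits <- function(tr) {
  sum(!vapply(tr[c("lower", "upper")], is.null, logical(1)))
}

#' Configure a moving-average procedure
#'
#' An MA procedure is the combination of a calculation formula (simple MA with
#' batch size `n`, or EWMA with weighting factor `lambda`), truncation limits,
#' and — for EWMA — a starting value.
#'
#' @param algorithm `"simple"` or `"ewma"`.
#' @param batch_size Batch size `n` for simple MA (number of consecutive
#'   accepted results averaged). Required iff `algorithm = "simple"`.
#' @param weighting_factor Weighting factor `lambda` in (0, 1) for EWMA.
#'   Required iff `algorithm = "ewma"`.
#' @param truncation A [truncation_limits()] object.
#' @param init_value EWMA starting value: a number, or `"population_mean"`
#'   (default) to use the mean of the truncation-accepted values of the stream
#'   the procedure is applied to.
#' @param id Optional identifier; auto-generated from the parameters if
#'   omitted (e.g. `"simple_n25"`, `"ewma_w0.1_up6"`).
#' @return An object of class `ma_config`.
#' @export
#' @examples
#' ma_config("simple", batch_size = 25)
#' ma_config("ewma", weighting_factor = 0.1,
#'           truncation = truncation_limits(upper = 6))
ma_config <- function(algorithm = c("simple", "ewma"), batch_size = NULL,
                      weighting_factor = NULL,
                      truncation = truncation_limits(),
                      init_value = "population_mean", id = NULL) {
  algorithm <- match.arg(algorithm)
  if (!inherits(truncation, "truncation_limits"))
    stop_validation("'truncation' must be a truncation_limits object")
  if (algorithm == "simple") {
    if (is.null(batch_size) || !is_scalar_number(batch_size) ||
        batch_size < 1 || batch_size != round(batch_size))
      stop_validation("simple MA requires a positive integer 'batch_size'")
    if (!is.null(weighting_factor))
      stop_validation("'weighting_factor' must not be set for simple MA")
    batch_size <- as.integer(batch_size)
  } else {
    if (is.null(weighting_factor) || !is_scalar_number(weighting_factor) ||
        weighting_factor <= 0 || weighting_factor >= 1)
      stop_validation("EWMA requires 'weighting_factor' in (0, 1)")
    if (!is.null(batch_size))
      stop_validation("'batch_size' must not be set for EWMA")
  }
  if (!identical(init_value, "population_mean") && !is_scalar_number(init_value))
    stop_validation("'init_value' must be a number or \"population_mean\"")
  cfg <- structure(
    list(algorithm = algorithm, batch_size = batch_size,
         weighting_factor = weighting_factor, truncation = truncation,
         init_value = init_value, id = NULL),
    class = "ma_config"
  )
  cfg$id <- id %||% default_config_id(cfg)
  cfg
}

default_config_id <- function(cfg) {
  base <- if (cfg$algorithm == "simple")
    sprintf("simple_n%d", cfg$batch_size)
  else
    sprintf("ewma_w%s", format(cfg$weighting_factor))
  tr <- cfg$truncation
  if (!is.null(tr$lower)) base <- paste0(base, "_lo", format(tr$lower))
  if (!is.null(tr$upper)) base <- paste0(base, "_up", format(tr$upper))
  base
}

#' @export
print.ma_config <- function(x, ...) {
  cat(sprintf("<ma_config> %s\n", x$id))
  if (x$algorithm == "simple")
    cat(sprintf("  simple MA, batch size %d\n", x$batch_size))
  else
    cat(sprintf("  EWMA, weighting factor %g, init %s\n", x$weighting_factor,
                if (is.numeric(x$init_value)) format(x$init_value) else x$init_value))
  tr <- x$truncation
  cat(sprintf("  truncation: lower %s, upper %s\n",
              if (is.null(tr$lower)) "none" else format(tr$lower),
              if (is.null(tr$upper)) "none" else format(tr$upper)))
  invisible(x)
}

#' Apply truncation limits to a value sequence
#'
#' @param values Numeric vector of results, in measurement order.
#' @param limits A [truncation_limits()] object.
#' @return Logical acceptance mask: `TRUE` where the value lies inside the
#'   (inclusive) limits.
#' @export
apply_truncation <- function(values, limits = truncation_limits()) {
  stopifnot(inherits(limits, "truncation_limits"))
  ok <- rep(TRUE, length(values))
  if (!is.null(limits$lower)) ok <- ok & values >= limits$lower
  if (!is.null(limits$upper)) ok <- ok & values <= limits$upper
  ok
}

# Mean of the trailing n elements at every position (NA before the n-th),
# computed as a moving convolution with weights 1/n.
trailing_mean <- function(x, n) {
  if (length(x) < n) return(rep(NA_real_, length(x)))
  as.numeric(stats::filter(x, rep(1 / n, n), method = "convolution", sides = 1))
}

new_ma_series <- function(values, mask, ma_full, config = NULL, timestamp = NULL) {
  df <- data.frame(index = seq_along(values), value = values,
                   accepted = mask, ma_value = ma_full)
  if (!is.null(timestamp)) df <- cbind(df[1], timestamp = timestamp, df[-1])
  structure(df, config = config, class = c("ma_series", "data.frame"))
}

#' Simple moving average over an accepted-value sequence
#'
#' At each accepted result the MA is the arithmetic mean of the most recent
#' `n` accepted results; it is undefined (`NA`) until `n` accepted results
#' have occurred. At non-accepted positions the last defined MA is carried
#' forward unchanged (the MA only updates when a result is accepted).
#'
#' @param values Numeric vector of results in order.
#' @param mask Logical acceptance mask (from [apply_truncation()]).
#' @param n Batch size (positive integer).
#' @return An `ma_series` data frame with columns `index`, `value`,
#'   `accepted`, `ma_value`.
#' @export
compute_simple_ma <- function(values, mask, n) {
  stopifnot(length(mask) == length(values), n >= 1)
  va <- values[mask]
  # convolution form (sum of x_i / n) rather than a prefix-sum difference:
  # replaying any suffix of the accepted sequence then reproduces the same
  # doubles bit for bit, which the zero-false-alarm construction relies on
  ma_acc <- trailing_mean(va, n)
  ma_full <- rep(NA_real_, length(values))
  ma_full[mask] <- ma_acc
  new_ma_series(values, mask, locf(ma_full))
}

#' Exponentially weighted moving average over an accepted-value sequence
#'
#' Implements the recursion `z_t = lambda * x_t + (1 - lambda) * z_{t-1}`
#' over accepted results, starting from `z_0 = init`. The MA is defined from
#' the first accepted result onward; non-accepted positions carry the last
#' value forward.
#'
#' @inheritParams compute_simple_ma
#' @param lambda Weighting factor in (0, 1) (values up to 1 are accepted for
#'   the limiting case `lambda = 1`, which reproduces the raw results).
#' @param init Starting value `z_0`.
#' @return An `ma_series` data frame.
#' @export
compute_ewma <- function(values, mask, lambda, init) {
  stopifnot(length(mask) == length(values), lambda > 0, lambda <= 1,
            is_scalar_number(init))
  va <- values[mask]
  z <- if (length(va))
    as.numeric(stats::filter(lambda * va, 1 - lambda,
                             method = "recursive", init = init))
  else numeric(0)
  ma_full <- rep(NA_real_, length(values))
  ma_full[mask] <- z
  new_ma_series(values, mask, locf(ma_full))
}

#' Compute the moving-average series of a stream under a procedure
#'
#' Applies the procedure's truncation limits, resolves the EWMA starting value
#' (the mean of all truncation-accepted values of the stream when
#' `init_value = "population_mean"`), and runs the configured algorithm. The
#' MA is recalculated each time a result is accepted.
#'
#' @param stream A `result_stream`, or a bare numeric vector of results.
#' @param config An [ma_config()].
#' @return An `ma_series` data frame (with a `timestamp` column when the input
#'   carries timestamps) whose `"config"` attribute records the procedure.
#' @export
compute_ma_series <- function(stream, config) {
  stopifnot(inherits(config, "ma_config"))
  if (is.numeric(stream)) {
    values <- stream; ts <- NULL
  } else {
    values <- stream$value; ts <- stream$timestamp
  }
  mask <- apply_truncation(values, config$truncation)
  if (!any(mask))
    stop("no results are accepted under the truncation limits; cannot compute an MA series")
  series <- if (config$algorithm == "simple") {
    compute_simple_ma(values, mask, config$batch_size)
  } else {
    init <- resolve_init(values, mask, config)
    compute_ewma(values, mask, config$weighting_factor, init)
  }
  if (!is.null(ts)) series <- new_ma_series(values, mask, series$ma_value,
                                            timestamp = ts)
  attr(series, "config") <- config
  series
}

resolve_init <- function(values, mask, config) {
  if (identical(config$init_value, "population_mean")) mean(values[mask])
  else config$init_value
}

#' Derive control limits from an unbiased MA series
#'
#' Control limits are the minimum and maximum of the defined MA values of the
#' series computed on unbiased (routine) data. By construction, replaying the
#' same stream can never strictly exceed them, so the procedure raises no
#' false alarms on the data it was trained on.
#'
#' @param series An `ma_series` with at least one defined `ma_value`.
#' @return An object of class `control_limits` with fields `lower`, `upper`
#'   and (when the series carries a config) `config_id`.
#' @export
derive_control_limits <- function(series) {
  d <- series$ma_value[!is.na(series$ma_value)]
  if (!length(d)) stop("series has no defined MA values")
  cfg <- attr(series, "config", exact = TRUE)
  structure(list(lower = min(d), upper = max(d),
                 config_id = if (!is.null(cfg)) cfg$id),
            class = "control_limits")
}

#' Construct control limits directly
#'
#' Mostly useful for replaying procedures whose limits were established
#' elsewhere (e.g. published limits); within a pipeline run
#' [derive_control_limits()] is the normal source.
#'
#' @param lower,upper Numeric limits, `lower <= upper`.
#' @param config_id Optional identifier of the procedure the limits belong to.
#' @return A `control_limits` object.
#' @export
control_limits <- function(lower, upper, config_id = NULL) {
  stopifnot(is_scalar_number(lower), is_scalar_number(upper), lower <= upper)
  structure(list(lower = lower, upper = upper, config_id = config_id),
            class = "control_limits")
}

#' @export
print.control_limits <- function(x, ...) {
  cat(sprintf("<control_limits> [%g, %g]%s\n", x$lower, x$upper,
              if (!is.null(x$config_id)) paste0(" (", x$config_id, ")") else ""))
  invisible(x)
}

#' Test MA values against control limits
#'
#' An alarm requires strict exceedance: the limits themselves are attained by
#' the limit-defining series, so a value exactly equal to a limit does not
#' alarm.
#'
#' @param ma_value Numeric vector of MA values.
#' @param limits A `control_limits` object.
#' @return Logical vector, `TRUE` where the MA strictly exceeds a limit.
#' @export
check_alarm <- function(ma_value, limits) {
  stopifnot(inherits(limits, "control_limits"))
  ma_value > limits$upper | ma_value < limits$lower
}

#' Export an MA series as CSV
#'
#' Writes `index,timestamp,value,accepted,ma_value,alarm` with empty
#' `ma_value` where the MA is undefined. Alarms are evaluated only at
#' positions where the MA was recalculated (accepted results with a defined
#' MA); elsewhere the `alarm` column is `FALSE` (or empty where the MA is
#' undefined).
#'
#' @param series An `ma_series`.
#' @param path Output path.
#' @param limits Optional `control_limits`; when omitted the `alarm` column is
#'   left empty.
#' @export
write_ma_series <- function(series, path, limits = NULL) {
  df <- as.data.frame(series)
  if (!"timestamp" %in% names(df)) df$timestamp <- NA
  alarm <- rep(NA, nrow(df))
  if (!is.null(limits)) {
    evaluable <- df$accepted & !is.na(df$ma_value)
    alarm[!is.na(df$ma_value)] <- FALSE
    alarm[evaluable] <- check_alarm(df$ma_value[evaluable], limits)
  }
  out <- data.frame(
    index = df$index,
    timestamp = ifelse(is.na(df$timestamp), "",
                       format(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")),
    value = df$value, accepted = df$accepted,
    ma_value = ifelse(is.na(df$ma_value), "", sprintf("%.15g", df$ma_value)),
    alarm = ifelse(is.na(alarm), "", as.character(alarm))
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
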