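#' Generate a synthetic LIS-like result stream
#'
#' Produces an ordered stream of patient results for one analyte, emulating a
#' laboratory information system extract: Poisson-distributed daily counts
#' around the profile's daily volume, second-resolution timestamps within
#' working hours, and values drawn from the profile's fitted mixture
#' distribution. Values are clipped to `[0.9 * min_value, 1.1 * max_value]`.
#' The stream is fully determined by `(profile, n_days, seed)` and the
#' optional arguments; the caller's RNG state is left untouched.
#'
#' @param profile An [analyte_profile()].
#' @param n_days Number of generated days (>= 1).
#' @param seed Integer seed; identical inputs give byte-identical streams.
#' @param start_date First calendar day of the stream.
#' @param work_start,work_end Working-hour window (hours, local clock) inside
#'   which timestamps fall; defaults 07:00-15:00 (outpatient pattern).
#' @param skip_weekends If `TRUE`, Saturdays/Sundays carry no results and the
#'   calendar is extended so that `n_days` working days are produced. Default
#'   `FALSE` (no weekend structure).
#' @param drift_amplitude Amplitude (analyte units) of an optional slow
#'   sinusoidal day-level drift added to every value; default 0 (none).
#' @param drift_period Period of the drift, in days.
#'
#' @return A `result_stream`: a data frame with columns `timestamp` (POSIXct,
#'   UTC, non-decreasing) and `value`, with attributes `analyte`, `unit` and
#'   `seed`.
#' @export
#' @examples
#' na <- builtin_profiles()[["sodium"]]
#' s <- generate_stream(na, n_days = 5, seed = 1)
#' summarize_stream(s)
generate_stream <- function(profile, n_days, seed,
                            start_date = as.Date("2018-01-01"),
                            work_start = 7, work_end = 15,
                            skip_weekends = FALSE,
                            drift_amplitude = 0, drift_period = 30) {
  stopifnot(inherits(profile, "analyte_profile"))
  if (!is_scalar_number(n_days) || n_days < 1 || n_days != round(n_days))
    stop_validation("n_days must be a positive integer")
  params <- fit_profile_params(profile)

  days <- seq(start_date, by = "day", length.out = if (skip_weekends) n_days * 2L else n_days)
  if (skip_weekends) {
    days <- days[!format(days, "%u") %in% c("6", "7")]
    days <- days[seq_len(n_days)]
  }

  span <- (work_end - work_start) * 3600

  with_seed(seed, {
    counts <- stats::rpois(n_days, profile$daily_volume)
    total <- sum(counts)
    secs <- lapply(seq_len(n_days), function(i)
      sort(round(stats::runif(counts[i], 0, span))))
    values <- draw_profile_values(params, total)

    day_idx <- rep.int(seq_len(n_days), counts)
    if (drift_amplitude != 0)
      values <- values + drift_amplitude * sin(2 * pi * day_idx / drift_period)

    lo <- max(0.9 * profile$min_value, .Machine$double.eps)
    hi <- 1.1 * profile$max_value
    values <- pmin(pmax(values, lo), hi)

    ts <- as.POSIXct(rep(days, counts), tz = "UTC") +
      work_start * 3600 + unlist(secs)

    new_result_stream(ts, values, analyte = profile$name, unit = profile$unit,
                      seed = as.integer(seed))
  })
}

new_result_stream <- function(timestamp, value, analyte, unit = NULL, seed = NULL) {
  df <- data.frame(timestamp = timestamp, value = value)
  if (is.unsorted(as.numeric(df$timestamp)))
    stop("result_stream timestamps must be non-decreasing")
  if (any(df$value <= 0))
    stop("result_stream values must be positive")
  structure(df, analyte = analyte, unit = unit, seed = seed,
            class = c("result_stream", "data.frame"))
}

#' Summarize a result stream
#'
#' Computes the descriptive statistics a laboratory would tabulate for a
#' dataset: total count, median and quartiles, extremes, and the mean number
#' of results per distinct calendar day.
#'
#' @param stream A `result_stream` from [generate_stream()] or [read_stream()].
#' @return One-row data frame with columns `analyte`, `n`, `median`, `q1`,
#'   `q3`, `min`, `max`, `mean_daily`.
#' @export
summarize_stream <- function(stream) {
  if (nrow(stream) == 0L) stop("cannot summarize an empty stream")
  v <- stream$value
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  n_days <- length(unique(as.Date(stream$timestamp, tz = "UTC")))
  data.frame(analyte = attr(stream, "analyte") %||% NA_character_,
             n = length(v), median = q[2], q1 = q[1], q3 = q[3],
             min = min(v), max = max(v), mean_daily = length(v) / n_days)
}

#' Write / read a result stream as CSV
#'
#' The on-disk format is a plain CSV with header `timestamp,value`, ISO 8601
#' timestamps (`YYYY-MM-DDTHH:MM:SS`) and full-precision values. Metadata
#' (analyte, seed, configuration hash) is written as leading `#` comment
#' lines, which [read_stream()] parses back.
#'
#' @param stream A `result_stream`.
#' @param path Output/input file path.
#' @param extra_comments Named character vector of additional `key=value`
#'   metadata comment lines.
#' @return `write_stream()` returns `path` invisibly; `read_stream()` returns
#'   a `result_stream`.
#' @export
write_stream <- function(stream, path, extra_comments = NULL) {
  meta <- c(analyte = attr(stream, "analyte"), unit = attr(stream, "unit"),
            seed = attr(stream, "seed"), extra_comments)
  meta <- meta[!vapply(meta, is.null, logical(1))]
  lines <- c(
    sprintf("# %s=%s", names(meta), vapply(meta, as.character, character(1))),
    "timestamp,value",
    sprintf("%s,%.15g", format(stream$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
            stream$value)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  if (any(is_meta)) {
    kv <- sub("^#\\s*", "", lines[is_meta])
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    meta <- stats::setNames(as.list(vals), keys)
  }
  df <- utils::read.csv(text = lines[!is_meta], stringsAsFactors = FALSE)
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(ts)) stop_validation("unparseable timestamps in ", path)
  new_result_stream(ts, as.numeric(df$value),
                    analyte = meta$analyte, unit = meta$unit,
                    seed = if (!is.null(meta$seed)) as.integer(meta$seed))
}
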