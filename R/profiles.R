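#' Describe the result population of one analyte
#'
#' An analyte profile captures the summary statistics a laboratory can read
#' off its own LIS extract — median, quartiles, observed extremes and the
#' average daily number of results — together with a qualitative skew family
#' and the rate of rare pathological extremes. Profiles drive the synthetic
#' stream generator ([generate_stream()]) and supply the daily volume used by
#' the optimization criteria.
#'
#' @param name Analyte name (e.g. `"sodium"`).
#' @param unit Concentration unit, informational (e.g. `"mmol/L"`).
#' @param daily_volume Average number of results per working day (>= 1).
#' @param median,q1,q3 Median and quartiles of the result population, in
#'   analyte units. Must satisfy `min_value <= q1 <= median <= q3 <= max_value`.
#' @param min_value,max_value Smallest and largest concentration ever observed
#'   in the population; the generator's pathological tail reaches toward them.
#' @param skew_family One of `"symmetric"`, `"right_tailed"`, `"left_tailed"`;
#'   selects the core distribution family fitted by [fit_profile_params()].
#' @param outlier_rate Fraction of results drawn from the pathological-extreme
#'   tail component, in `[0, 0.05)`. Default 0.01.
#' @param tea_percent Optional allowable total error (TEa) for the analyte, in
#'   percent; carried along for the bias grid and optimization criteria.
#'
#' @return An object of class `analyte_profile`.
#' @seealso [builtin_profiles()] for the four profiles shipped with the
#'   package, [fit_profile_params()], [generate_stream()].
#' @export
#' @examples
#' analyte_profile("sodium", "mmol/L", daily_volume = 55,
#'                 median = 140, q1 = 139, q3 = 141,
#'                 min_value = 123, max_value = 149,
#'                 skew_family = "symmetric", tea_percent = 3.57)
analyte_profile <- function(name, unit, daily_volume, median, q1, q3,
                            min_value, max_value,
                            skew_family = c("symmetric", "right_tailed", "left_tailed"),
                            outlier_rate = 0.01, tea_percent = NULL) {
  skew_family <- match.arg(skew_family)
  for (f in c("daily_volume", "median", "q1", "q3", "min_value", "max_value",
              "outlier_rate")) {
    v <- get(f)
    if (!is_scalar_number(v))
      stop_validation("profile field '", f, "' must be a single finite number")
  }
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_validation("profile field 'name' must be a non-empty string")
  if (daily_volume < 1 || daily_volume != round(daily_volume))
    stop_validation("profile field 'daily_volume' must be a positive integer")
  if (!(min_value <= q1 && q1 <= median && median <= q3 && q3 <= max_value))
    stop_validation("profile quantiles must satisfy min <= q1 <= median <= q3 <= max")
  if (min_value <= 0)
    stop_validation("profile field 'min_value' must be positive (concentrations)")
  if (outlier_rate < 0 || outlier_rate >= 0.05)
    stop_validation("profile field 'outlier_rate' must lie in [0, 0.05)")
  if (!is.null(tea_percent) && (!is_scalar_number(tea_percent) || tea_percent <= 0))
    stop_validation("profile field 'tea_percent' must be a positive number")
  structure(
    list(name = name, unit = unit, daily_volume = as.integer(daily_volume),
         median = median, q1 = q1, q3 = q3,
         min_value = min_value, max_value = max_value,
         skew_family = skew_family, outlier_rate = outlier_rate,
         tea_percent = tea_percent),
    class = "analyte_profile"
  )
}

#' @export
print.analyte_profile <- function(x, ...) {
  cat(sprintf("<analyte_profile> %s [%s]\n", x$name, x$unit))
  cat(sprintf("  median %g (Q1-Q3 %g-%g), range %g-%g, ~%d results/day\n",
              x$median, x$q1, x$q3, x$min_value, x$max_value, x$daily_volume))
  cat(sprintf("  skew: %s, outlier rate: %g%s\n", x$skew_family, x$outlier_rate,
              if (!is.null(x$tea_percent))
                sprintf(", TEa %g%%", x$tea_percent) else ""))
  invisible(x)
}

#' Profiles of the four study analytes
#'
#' Reads the packaged profile fixture describing four outpatient analyte
#' populations: creatinine (high volume, heavy right tail), potassium and
#' sodium (moderate volume, narrow symmetric cores) and albumin (low volume,
#' mild left tail), each with its CLIA allowable total error.
#'
#' @param path Path to a profile YAML file; defaults to the packaged fixture.
#' @return Named list of [analyte_profile()] objects.
#' @export
builtin_profiles <- function(path = system.file("extdata", "profiles.yaml",
                                                package = "pbrtqc")) {
  raw <- yaml::read_yaml(path)
  profs <- lapply(raw$profiles, profile_from_list)
  names(profs) <- vapply(profs, function(p) p$name, character(1))
  profs
}

profile_from_list <- function(x) {
  required <- c("name", "unit", "daily_volume", "median", "q1", "q3",
                "min_value", "max_value", "skew_family")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop_validation("missing profile field(s): ", paste(missing, collapse = ", "),
                    if (!is.null(x$name)) paste0(" (analyte '", x$name, "')") else "")
  analyte_profile(x$name, x$unit, x$daily_volume, x$median, x$q1, x$q3,
                  x$min_value, x$max_value, x$skew_family,
                  outlier_rate = x$outlier_rate %||% 0.01,
                  tea_percent = x$tea_percent)
}

#' Fit a sampling distribution to an analyte profile
#'
#' Translates the printed summary statistics of a profile into parameters of a
#' two-component mixture: a quantile-matched core distribution plus a
#' low-weight "pathological tail" that reaches toward the observed extremes.
#'
#' Core families by `skew_family`:
#' * `symmetric` — normal with mean = median and sd = IQR / (2 * qnorm(0.75)),
#'   truncated to `[min_value, max_value]` (sampled by inverse-CDF).
#' * `right_tailed` — shifted log-normal whose shift, meanlog and sdlog are
#'   solved so that Q1, median and Q3 are matched exactly
#'   (shift = (q1*q3 - median^2) / (q1 + q3 - 2*median)).
#' * `left_tailed` — the mirror image of the shifted log-normal solution.
#'
#' When the profile quantiles carry no skew the skewed families fall back to
#' the truncated normal. A degenerate profile with zero IQR is valid only when
#' the whole range collapses to a point (all draws equal the median);
#' otherwise the quantile system has no solution and a parameterization error
#' is raised.
#'
#' The tail component has total weight `outlier_rate`, split evenly between a
#' uniform draw on `[min_value, q1]` and one on `[q3, max_value]` (all weight
#' moves to one side when the other has zero width).
#'
#' @param profile An [analyte_profile()].
#' @return An object of class `profile_params` consumed by [generate_stream()].
#' @export
fit_profile_params <- function(profile) {
  stopifnot(inherits(profile, "analyte_profile"))
  p <- profile
  iqr <- p$q3 - p$q1

  if (iqr == 0) {
    if (p$min_value < p$max_value)
      stop_validation("cannot parameterize profile '", p$name,
                      "': zero IQR with a non-degenerate range")
    core <- list(family = "point", value = p$median)
  } else {
    core <- switch(p$skew_family,
      symmetric   = core_truncnorm(p),
      right_tailed = core_shifted_lognormal(p, mirror = FALSE),
      left_tailed  = core_shifted_lognormal(p, mirror = TRUE)
    )
  }

  lower_width <- p$q1 - p$min_value
  upper_width <- p$max_value - p$q3
  if (lower_width <= 0 && upper_width <= 0) {
    w_lower <- w_upper <- 0
  } else if (lower_width <= 0) {
    w_lower <- 0; w_upper <- 1
  } else if (upper_width <= 0) {
    w_lower <- 1; w_upper <- 0
  } else {
    w_lower <- w_upper <- 0.5
  }

  structure(
    list(core = core,
         tail = list(rate = p$outlier_rate,
                     lower = c(p$min_value, p$q1), w_lower = w_lower,
                     upper = c(p$q3, p$max_value), w_upper = w_upper),
         profile = p),
    class = "profile_params"
  )
}

core_truncnorm <- function(p) {
  sd <- (p$q3 - p$q1) / (2 * stats::qnorm(0.75))
  list(family = "truncnorm", mean = p$median, sd = sd,
       lower = p$min_value, upper = p$max_value)
}

# Shifted log-normal matched to (q1, median, q3); mirrored variant handles a
# left tail by solving on the negated quantiles.
core_shifted_lognormal <- function(p, mirror) {
  if (mirror) {
    q1 <- -p$q3; med <- -p$median; q3 <- -p$q1
  } else {
    q1 <- p$q1; med <- p$median; q3 <- p$q3
  }
  denom <- q1 + q3 - 2 * med
  if (denom <= 0) return(core_truncnorm(p))  # no skew in the quantiles
  shift <- (q1 * q3 - med^2) / denom
  if (shift >= q1) return(core_truncnorm(p))
  z75 <- stats::qnorm(0.75)
  sdlog <- log((q3 - shift) / (med - shift)) / z75
  meanlog <- log(med - shift)
  list(family = "shifted_lognormal", shift = shift, meanlog = meanlog,
       sdlog = sdlog, mirror = mirror)
}

# Draw n values from a fitted profile mixture (uses the current RNG stream).
draw_profile_values <- function(params, n) {
  stopifnot(inherits(params, "profile_params"))
  if (n == 0L) return(numeric(0))
  core <- params$core
  tl <- params$tail
  u <- stats::runif(n)
  out <- numeric(n)

  in_lower <- u < tl$rate * tl$w_lower
  in_upper <- !in_lower & u < tl$rate * (tl$w_lower + tl$w_upper)
  in_core <- !(in_lower | in_upper)

  out[in_lower] <- stats::runif(sum(in_lower), tl$lower[1], tl$lower[2])
  out[in_upper] <- stats::runif(sum(in_upper), tl$upper[1], tl$upper[2])

  k <- sum(in_core)
  out[in_core] <- switch(core$family,
    point = rep(core$value, k),
    truncnorm = {
      plo <- stats::pnorm(core$lower, core$mean, core$sd)
      phi <- stats::pnorm(core$upper, core$mean, core$sd)
      stats::qnorm(stats::runif(k, plo, phi), core$mean, core$sd)
    },
    shifted_lognormal = {
      v <- core$shift + stats::rlnorm(k, core$meanlog, core$sdlog)
      if (core$mirror) -v else v
    }
  )
  out
}
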