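# Independent brute-force oracles used to cross-check the vectorized engines.

# Trailing-window mean over accepted values, recomputed from scratch at every
# position; carries the last defined value forward at rejected positions.
oracle_simple_ma <- function(values, mask, n) {
  out <- rep(NA_real_, length(values))
  acc <- numeric(0)
  last <- NA_real_
  for (i in seq_along(values)) {
    if (mask[i]) {
      acc <- c(acc, values[i])
      if (length(acc) >= n)
        last <- mean(acc[(length(acc) - n + 1):length(acc)])
    }
    out[i] <- last
  }
  out
}

# EWMA by explicit expansion: z_t = lambda * sum_i (1-lambda)^i x_(t-i)
#                                   + (1-lambda)^t * z_0
oracle_ewma <- function(values, mask, lambda, init) {
  va <- values[mask]
  z <- vapply(seq_along(va), function(t) {
    i <- 0:(t - 1)
    lambda * sum((1 - lambda)^i * va[t - i]) + (1 - lambda)^t * init
  }, numeric(1))
  out <- rep(NA_real_, length(values))
  out[mask] <- z
  ok <- !is.na(out)
  if (any(ok)) out <- c(NA_real_, out[ok])[cumsum(ok) + 1]
  out
}

# Sort-based quantile (linear interpolation of order statistics).
oracle_quantile <- function(x, p) {
  sx <- sort(x)
  n <- length(sx)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    sx[lo] + (h - lo) * (sx[hi] - sx[lo])
  }, numeric(1))
}

# Replay-based detection oracle: applies the bias to the whole stream tail,
# recomputes the full MA series from scratch with the stated oracle, and scans
# for the first alarm at or after the injection.
oracle_detection <- function(values, config, limits, inj, bias, window) {
  biased <- inject_bias(values, inj, bias)
  mask <- apply_truncation(biased, config$truncation)
  ma <- if (config$algorithm == "simple") {
    oracle_simple_ma(biased, mask, config$batch_size)
  } else {
    init <- if (identical(config$init_value, "population_mean")) {
      m0 <- apply_truncation(values, config$truncation)
      mean(values[m0])
    } else config$init_value
    oracle_ewma(biased, mask, config$weighting_factor, init)
  }
  last <- min(inj + window - 1, length(values))
  for (i in inj:last) {
    if (mask[i] && !is.na(ma[i]) && (ma[i] > limits$upper || ma[i] < limits$lower))
      return(i - inj + 1L)
  }
  NA_integer_
}

# The full calculation-formula grid of the study: five batch sizes for the
# simple MA and four weighting factors for the EWMA.
methods_grid_configs <- function(truncation = truncation_limits()) {
  c(
    lapply(c(5, 10, 25, 50, 100), function(n)
      ma_config("simple", batch_size = n, truncation = truncation)),
    lapply(c(0.2, 0.1, 0.05, 0.02), function(l)
      ma_config("ewma", weighting_factor = l, truncation = truncation))
  )
}

# Truncation variants examined per analyte (including no truncation).
analyte_truncations <- function(analyte) {
  switch(analyte,
    creatinine = c(list(truncation_limits()),
                   lapply(c(150, 200, 300, 400),
                          function(u) truncation_limits(upper = u))),
    sodium = list(truncation_limits(), truncation_limits(upper = 145),
                  truncation_limits(lower = 130, upper = 145)),
    potassium = list(truncation_limits(), truncation_limits(upper = 6)),
    albumin = list(truncation_limits(), truncation_limits(lower = 30))
  )
}
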