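test_that("TEa rounding is nearest-integer, halves away from zero", {
  expect_identical(round_tea(17.97), 18L)
  expect_identical(round_tea(3.57), 4L)
  expect_identical(round_tea(10.0), 10L)
  expect_identical(round_tea(2.5), 3L)   # half away from zero, not to even
  expect_error(round_tea(-4))
})

test_that("the bias grid is the signed default magnitudes plus the rounded TEa", {
  g <- bias_grid()
  expect_equal(g, sort(c(-c(1, 3, 5, 10, 20, 30, 40, 50),
                         c(1, 3, 5, 10, 20, 30, 40, 50))))
  g_k <- bias_grid(17.97)
  expect_true(all(c(-18, 18) %in% g_k))
  expect_equal(length(g_k), 18)
  # TEa coinciding with an existing magnitude adds nothing
  expect_equal(length(bias_grid(10)), 16)
})

test_that("inject_bias applies a persistent multiplicative shift", {
  expect_equal(inject_bias(c(140, 140, 140), start = 2, bias_percent = 4),
               c(140, 145.6, 145.6))
  v <- c(1.5, 2.5, 3.5)
  expect_equal(inject_bias(v, 1, 0), v)
  expect_equal(inject_bias(rep(4.3, 4), 1, 50), rep(6.45, 4))
})

test_that("detection counts on constant streams match the closed forms", {
  # simple MA: the MA moves by c*b/100 * min(k, n)/n after k biased results
  sodium <- rep(140, 600)
  cfg_na <- ma_config("simple", batch_size = 25)
  run <- run_single_simulation(sodium, cfg_na, control_limits(137, 142),
                               injection_index = 200, bias_percent = 4)
  k_simple <- min(which(140 + 140 * 0.04 * pmin(1:400, 25) / 25 > 142))
  expect_equal(run$n_to_detection, k_simple)
  expect_equal(run$n_to_detection, 9)
  expect_false(run$censored)

  # EWMA: z_k = c + c*b/100 * (1 - (1-lambda)^k)
  potass <- rep(4.3, 600)
  cfg_k <- ma_config("ewma", weighting_factor = 0.1)
  run_k <- run_single_simulation(potass, cfg_k, control_limits(3.9, 4.8),
                                 injection_index = 200, bias_percent = 18)
  k_ewma <- min(which(4.3 + 4.3 * 0.18 * (1 - 0.9^(1:400)) > 4.8))
  expect_equal(run_k$n_to_detection, k_ewma)
  expect_equal(run_k$n_to_detection, 10)
  expect_equal(run_k$n_accepted_to_detection, run_k$n_to_detection)
})

test_that("a truncation limit can block detection of a large bias entirely", {
  potass <- rep(4.3, 1000)
  cfg <- ma_config("ewma", weighting_factor = 0.1,
                   truncation = truncation_limits(upper = 6))
  lim <- derive_control_limits(compute_ma_series(potass, cfg))
  run <- run_single_simulation(potass, cfg, lim, injection_index = 500,
                               bias_percent = 50)
  expect_true(run$censored)  # every biased value 6.45 is rejected
  expect_true(is.na(run$n_to_detection))
})

test_that("run_single_simulation agrees with a full-replay oracle", {
  set.seed(31)
  values <- rnorm(1200, 100, 5)
  lim_tr <- truncation_limits(lower = 88, upper = 112)
  configs <- list(
    ma_config("simple", batch_size = 10, truncation = lim_tr),
    ma_config("simple", batch_size = 25),
    ma_config("ewma", weighting_factor = 0.1, truncation = lim_tr),
    ma_config("ewma", weighting_factor = 0.05)
  )
  for (cfg in configs) {
    lims <- derive_control_limits(compute_ma_series(values, cfg))
    for (bias in c(-20, -5, 3, 10, 40)) {
      for (inj in c(401, 801)) {
        run <- run_single_simulation(values, cfg, lims, inj, bias, window = 400)
        ref <- oracle_detection(values, cfg, lims, inj, bias, window = 400)
        expect_equal(run$n_to_detection, ref,
                     info = sprintf("%s bias %g inj %d", cfg$id, bias, inj))
        if (!run$censored)
          expect_lte(run$n_accepted_to_detection, run$n_to_detection)
      }
    }
  }
})

test_that("limits from a different procedure are rejected", {
  v <- rnorm(900, 100, 5)
  cfg_a <- ma_config("simple", batch_size = 10)
  cfg_b <- ma_config("simple", batch_size = 25)
  lim_a <- derive_control_limits(compute_ma_series(v, cfg_a))
  expect_error(run_single_simulation(v, cfg_b, lim_a, 500, 10),
               "derived under config")
})

test_that("simulate_bias_grid places one injection per block from the second block", {
  set.seed(32)
  v <- rnorm(6663, 100, 2)
  cfg <- ma_config("ewma", weighting_factor = 0.2)
  sim <- simulate_bias_grid(v, cfg, grid = c(-10, 10), block = 400)
  expect_equal(unique(sim$summaries$n_runs), floor(6663 / 400) - 1)  # 15
  expect_equal(sort(unique(sim$runs$injection_index)),
               400 * seq_len(15) + 1)
  expect_error(simulate_bias_grid(v[1:700], cfg, grid = c(10), block = 400),
               "2 \\* block")
})

test_that("zero bias on the limit-defining stream is always censored", {
  set.seed(33)
  v <- rlnorm(2000, 4.2, 0.2)
  for (cfg in list(ma_config("simple", batch_size = 10),
                   ma_config("ewma", weighting_factor = 0.1))) {
    sim <- simulate_bias_grid(v, cfg, grid = c(0), block = 400)
    expect_equal(sim$summaries$n_detected, 0L)
    expect_true(all(sim$runs$censored))
  }
})

test_that("summarize_runs aggregates detected runs only", {
  mk <- function(n_det, n_cens = 0) {
    data.frame(injection_index = seq_len(length(n_det) + n_cens),
               bias_percent = 10, window = 400,
               n_to_detection = c(n_det, rep(NA, n_cens)),
               n_accepted_to_detection = c(n_det, rep(NA, n_cens)),
               censored = c(rep(FALSE, length(n_det)), rep(TRUE, n_cens)))
  }
  s <- summarize_runs(mk(c(4, 8, 13)))
  expect_equal(c(s$median_n, s$min_n, s$max_n), c(8, 4, 13))
  expect_equal(s$n_detected, 3L)

  s_even <- summarize_runs(mk(c(4, 8, 13, 21)))
  expect_equal(s_even$median_n, (8 + 13) / 2)  # mean of the central pair

  s_cens <- summarize_runs(mk(integer(0), n_cens = 5))
  expect_equal(s_cens$n_detected, 0L)
  expect_true(is.na(s_cens$median_n) && is.na(s_cens$min_n) && is.na(s_cens$max_n))

  set.seed(34)
  counts <- sample(1:400, 100, replace = TRUE)
  s_big <- summarize_runs(mk(counts))
  sorted <- sort(counts)
  expect_equal(s_big$min_n, sorted[1])
  expect_equal(s_big$max_n, sorted[100])
  expect_equal(s_big$median_n, (sorted[50] + sorted[51]) / 2)
})
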