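test_that("truncation limits are inclusive and optional", {
  expect_equal(apply_truncation(c(4.3, 6.5, 4.1), truncation_limits(upper = 6)),
               c(TRUE, FALSE, TRUE))
  expect_true(all(apply_truncation(c(-5, 0, 1e6), truncation_limits())))
  # boundary values are in range on both sides
  lim <- truncation_limits(lower = 130, upper = 145)
  expect_equal(apply_truncation(c(130, 145, 129.999, 145.001), lim),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_error(truncation_limits(lower = 10, upper = 5), "lower < upper")
})

test_that("ma_config enforces the algorithm/parameter pairing", {
  expect_error(ma_config("simple"), "batch_size")
  expect_error(ma_config("ewma", weighting_factor = 1.2), "0, 1")
  expect_error(ma_config("simple", batch_size = 5, weighting_factor = 0.1),
               "must not be set")
  cfg <- ma_config("ewma", weighting_factor = 0.1,
                   truncation = truncation_limits(upper = 6))
  expect_equal(cfg$id, "ewma_w0.1_up6")
  expect_equal(ma_config("simple", batch_size = 25)$id, "simple_n25")
})

test_that("simple MA matches hand examples and the windowed-mean oracle", {
  full <- rep(TRUE, 5)
  s <- compute_simple_ma(1:5, full, 5)
  expect_equal(s$ma_value, c(NA, NA, NA, NA, 3))
  s6 <- compute_simple_ma(1:6, rep(TRUE, 6), 5)
  expect_equal(s6$ma_value[6], 4)  # window slides

  set.seed(21)
  for (n in c(1, 7, 25)) {
    values <- rlnorm(200, 4, 0.3)
    mask <- runif(200) > 0.2
    got <- compute_simple_ma(values, mask, n)$ma_value
    expect_equal(got, oracle_simple_ma(values, mask, n), tolerance = 1e-12)
  }
})

test_that("EWMA matches the hand-expanded recursion and its explicit sum", {
  s <- compute_ewma(c(1, 1, 1), rep(TRUE, 3), lambda = 0.5, init = 0)
  expect_equal(s$ma_value, c(0.5, 0.75, 0.875))
  # constant stream at its own init is a fixed point
  cst <- compute_ewma(rep(7, 20), rep(TRUE, 20), 0.3, init = 7)
  expect_true(all(cst$ma_value == 7))

  set.seed(22)
  values <- rlnorm(200, 4, 0.3)
  mask <- runif(200) > 0.15
  got <- compute_ewma(values, mask, 0.1, init = 55)$ma_value
  ref <- oracle_ewma(values, mask, 0.1, init = 55)
  expect_lt(max(abs(got - ref) / abs(ref), na.rm = TRUE), 1e-9)
})

test_that("EWMA limiting behaviour: lambda = 1 is the raw data, lambda -> 0 stays at init", {
  set.seed(23)
  v <- runif(50, 100, 200)
  raw <- compute_ewma(v, rep(TRUE, 50), lambda = 1, init = 0)
  expect_equal(raw$ma_value, v)
  frozen <- compute_ewma(v, rep(TRUE, 50), lambda = 1e-8, init = 150)
  expect_true(all(abs(frozen$ma_value - 150) < 1e-4))
})

test_that("compute_ma_series orchestrates truncation, init and carry-forward", {
  s <- generate_stream(builtin_profiles()$sodium, n_days = 3, seed = 2)
  ser <- compute_ma_series(s, ma_config("simple", batch_size = 25))
  expect_true(all(is.na(ser$ma_value[1:24])))
  expect_false(anyNA(ser$ma_value[25:nrow(ser)]))

  # truncated results never change the EWMA value
  cfg <- ma_config("ewma", weighting_factor = 0.1,
                   truncation = truncation_limits(upper = 6))
  k <- generate_stream(builtin_profiles()$potassium, n_days = 10, seed = 3)
  serk <- compute_ma_series(k, cfg)
  rej <- which(!serk$accepted)
  rej <- rej[rej > 1]
  expect_equal(serk$ma_value[rej], serk$ma_value[rej - 1])

  # population-mean init equals the mean of accepted values
  init <- pbrtqc:::resolve_init(k$value, serk$accepted, cfg)
  expect_equal(init, mean(k$value[serk$accepted]))

  # single accepted value under EWMA with numeric init
  one <- compute_ma_series(c(5), ma_config("ewma", weighting_factor = 0.4,
                                           init_value = 5))
  expect_equal(one$ma_value, 5)

  expect_error(compute_ma_series(c(10, 12), ma_config("simple", batch_size = 2,
                                 truncation = truncation_limits(upper = 5))),
               "no results are accepted")
})

test_that("truncation invariance: out-of-limit insertions leave the accepted MA path unchanged", {
  set.seed(24)
  base <- runif(300, 4, 5)
  lim <- truncation_limits(lower = 3, upper = 6)
  with_out <- base
  pos <- sort(sample(300, 40))
  for (p in pos) {
    with_out <- append(with_out, sample(c(2, 8), 1), after = p)
  }
  for (cfg in list(ma_config("simple", batch_size = 10, truncation = lim),
                   ma_config("ewma", weighting_factor = 0.1, truncation = lim,
                             init_value = 4.5))) {
    a <- compute_ma_series(base, cfg)
    b <- compute_ma_series(with_out, cfg)
    expect_equal(b$ma_value[b$accepted], a$ma_value[a$accepted])
  }
})

test_that("control limits are the attained min/max and alarms are strict", {
  expect_error(control_limits(5, 4))
  lim <- control_limits(137, 142)
  expect_false(check_alarm(142.0, lim))  # equal to limit is not exceedance
  expect_true(check_alarm(142.1, lim))
  expect_true(check_alarm(136.9, lim))
  expect_false(check_alarm(140.0, lim))

  ser <- compute_ma_series(c(139, 140, 141), ma_config("simple", batch_size = 1))
  cl <- derive_control_limits(ser)
  expect_equal(c(cl$lower, cl$upper), c(139, 141))
  cst <- derive_control_limits(compute_ma_series(rep(5, 10),
                               ma_config("simple", batch_size = 3)))
  expect_equal(c(cst$lower, cst$upper), c(5, 5))

  set.seed(25)
  v <- rnorm(1000, 100, 5)
  s2 <- compute_ma_series(v, ma_config("ewma", weighting_factor = 0.2))
  cl2 <- derive_control_limits(s2)
  d <- s2$ma_value[!is.na(s2$ma_value)]
  expect_equal(cl2$lower, min(d))
  expect_equal(cl2$upper, max(d))
  # limits are attained by the series they came from
  expect_true(any(d == cl2$lower) && any(d == cl2$upper))
})

test_that("MA series export writes the documented CSV layout", {
  s <- generate_stream(builtin_profiles()$sodium, n_days = 2, seed = 4)
  ser <- compute_ma_series(s, ma_config("simple", batch_size = 10))
  lim <- derive_control_limits(ser)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ma_series(ser, path, limits = lim)
  out <- read.csv(path)
  expect_named(out, c("index", "timestamp", "value", "accepted", "ma_value",
                      "alarm"))
  expect_equal(nrow(out), nrow(ser))
  expect_true(all(is.na(out$ma_value[1:9])))
  expect_false(any(out$alarm == "TRUE", na.rm = TRUE))
})
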