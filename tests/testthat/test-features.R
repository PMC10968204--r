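test_that("SCL is the windowed mean of the tonic trace", {
  expect_equal(scl(rep(3, 960), 4)$scl, c(3, 3))
  ramp <- seq(2, 4, length.out = 480) # one 2-min window at 4 Hz
  expect_equal(scl(ramp, 4)$scl, 3, tolerance = 1e-9)
  two <- c(rep(1, 480), rep(2, 480))
  expect_equal(scl(two, 4)$scl, c(1, 2))
  expect_error(scl(rep(1, 100), 4), "longer")
})

test_that("NSSCR counts planted SCRs and respects the amplitude threshold", {
  rate <- 4
  t <- (0:(60 * rate - 1)) / rate
  onsets <- seq(2, 57, length.out = 12)
  ph <- rep(0, length(t))
  for (o in onsets) ph <- ph + 0.3 * biexp_shape(t - o)
  res <- nsscr(ph, rate, window_s = 60, min_amplitude = 0.01)
  expect_equal(res$nsscr, 12, tolerance = 1)
  expect_equal(nsscr(ph, rate, 60, min_amplitude = 0.5)$nsscr, 0)
  expect_equal(nsscr(rep(0, 240), rate, 60)$nsscr, 0)
})

test_that("the pipeline NSSCR recovers injected Poisson rates within 2 per minute", {
  # events are counted from an 8 Hz decomposition: close Poisson event
  # pairs (< 0.5 s) are frequent at 18/min and unresolvable at 4 Hz
  for (target in c(2, 8, 18)) {
    g <- generate_eda(window_rates = target, window_s = 300,
                      rate = 10, noise_sd = 0.005, seed = 100 + target)
    d <- cvxeda_decompose(g$conductance,
                          cvxeda_params(solver_tolerance = 1e-4),
                          decompose_rate = 8)
    stream <- eda_feature_stream(d, window_s = 300, min_distance_s = 0.25)
    realized <- nrow(g$truth$events) / 5 # events per minute over 5 min
    expect_lt(abs(stream$NSSCR[1] - realized), 2)
  }
})

test_that("dphEDA matches analytic derivatives", {
  expect_equal(dpheda(rep(2, 50), 4), rep(0, 50))
  ramp <- seq(0, 10, by = 0.025) # slope 0.1 uS/s at 4 Hz
  d <- dpheda(ramp, 4)
  expect_equal(d, rep(0.1, length(ramp)), tolerance = 1e-9)
  t <- (0:999) / 4
  tone <- sin(2 * pi * 0.1 * t)
  dt <- dpheda(tone, 4)
  expect_equal(max(abs(dt[10:990])), 2 * pi * 0.1, tolerance = 0.01)
})

test_that("synchronization joins streams without losing EDA rows", {
  eda <- tibble::tibble(time = (0:239) / 2, SCL = rnorm(120)[rep(1:120, each = 2)])
  env <- tibble::tibble(time = 0:119)
  for (v in env_variables()) env[[v]] <- rnorm(120)
  joined <- sync_features(eda, env)
  expect_equal(nrow(joined), sum(eda$time <= 119))
  expect_true(all(env_variables() %in% names(joined)))
  expect_false(any(duplicated(joined$time)))
  # offset env: values are carried forward from the most recent sample
  env_off <- env
  env_off$time <- env$time + 0.4
  j2 <- sync_features(eda, env_off)
  k <- which(j2$time == 10.0)
  expect_equal(j2$Temperature[k], env_off$Temperature[env_off$time == 9.4])
  # disjoint ranges fail
  env_far <- env
  env_far$time <- env$time + 1e5
  expect_error(sync_features(eda, env_far), "disjoint")
})

test_that("stale environment samples beyond the gap limit become NA", {
  eda <- tibble::tibble(time = (0:99) / 2)
  env <- tibble::tibble(time = c(0, 1, 2, 30))
  for (v in env_variables()) env[[v]] <- 1:4
  j <- sync_features(eda, env, max_gap_s = 2)
  expect_true(all(is.na(j$CO2[j$time > 4 & j$time < 30])))
  expect_false(anyNA(j$CO2[j$time <= 4]))
})

test_that("window aggregation means all numeric columns per protocol window", {
  tab <- tibble::tibble(
    time = (0:3599) / 2, # 30 min
    SCL = rep(c(1, 2), each = 1800),
    Temperature = rep(c(20, 30), each = 1800)
  )
  w <- window_features(tab, window_s = 900)
  expect_equal(nrow(w), 2)
  expect_equal(w$SCL, c(1, 2))
  expect_equal(w$Temperature, c(20, 30))
})
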