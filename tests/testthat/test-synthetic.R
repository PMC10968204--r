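test_that("the EDA generator is deterministic and sized correctly", {
  a <- generate_eda(window_rates = c(8, 8), window_s = 300, rate = 10, seed = 7)
  b <- generate_eda(window_rates = c(8, 8), window_s = 300, rate = 10, seed = 7)
  expect_identical(a$wristband, b$wristband)
  expect_equal(nrow(a$wristband), 6000)
  expect_true(all(a$wristband$vout >= 0 & a$wristband$vout < 3.3 / 2))
  # the full two-hour default at 10 Hz
  full <- generate_eda(seed = 7)
  expect_equal(nrow(full$wristband), 72000)
})

test_that("realized event counts stay within Poisson bounds per window", {
  set.seed(1)
  rates <- c(18, 8, 18, 8)
  g <- generate_eda(window_rates = rates, window_s = 900, seed = 21)
  counts <- table(factor(g$truth$events$window, levels = 1:4))
  lam <- rates * 15 # per 15-min window
  for (w in 1:4) {
    expect_gte(counts[w], qpois(0.025, lam[w]))
    expect_lte(counts[w], qpois(0.975, lam[w]))
  }
})

test_that("a noiseless event-free recording is pure tonic through the pipeline", {
  g <- generate_eda(window_rates = c(0, 0), window_s = 300, rate = 4,
                    noise_sd = 0, seed = 3)
  d <- cvxeda_decompose(g$conductance)
  expect_lt(sum(d$phasic^2), 1e-4)
  expect_equal(d$tonic, g$truth$tonic, tolerance = 0.02)
})

test_that("voltage round trip matches the generator's conductance", {
  g <- generate_eda(window_rates = c(8, 8), window_s = 150, rate = 10, seed = 5)
  sig <- ingest_wristband(g$wristband)
  expect_equal(sig$value, g$conductance$value, tolerance = 1e-9)
})

test_that("parameters outside the divider's range are refused", {
  expect_error(
    generate_eda(window_rates = c(8, 8), window_s = 150,
                 tonic_base = 0.5, seed = 1), # below the 1.21 uS floor
    "range"
  )
})

test_that("environment generator emits setpoints with AR(1) fluctuation", {
  d <- session_design(n_windows = 8, window_s = 900, seed = 5)
  env0 <- generate_environment(d, fluct_sd = 0, seed = 2)
  expect_equal(nrow(env0), 7200)
  expect_equal(names(env0), c("time", env_variables()))
  # zero fluctuation: stepwise-constant traces equal to the setpoints
  win <- pmin(floor(env0$time / 900) + 1, 8)
  expect_equal(as.vector(tapply(env0$Temperature, win, mean)),
               d$setpoints$Temperature, tolerance = 1e-9)
  expect_equal(length(unique(env0$CO2)), 8)
  # with fluctuation, well-separated setpoints are recoverable by window
  # means in their exact order
  sp <- d$setpoints
  sp$CO2 <- seq(400, 1800, length.out = 8)[c(3, 1, 7, 5, 8, 2, 4, 6)]
  d2 <- session_design(n_windows = 8, window_s = 900, setpoints = sp, seed = 5)
  env1 <- generate_environment(d2, fluct_sd = 0.05, seed = 2)
  m <- as.vector(tapply(env1$CO2, win, mean))
  expect_equal(order(m), order(sp$CO2))
})

test_that("session triplet is deterministic and internally consistent", {
  d <- session_design(seed = 9)
  a <- generate_session(d, seed = 4)
  b <- generate_session(d, seed = 4)
  expect_identical(a$wristband, b$wristband)
  expect_identical(a$environment, b$environment)
  expect_identical(a$reports, b$reports)
  expect_equal(nrow(a$reports), 8)
  expect_true(all(a$reports$stress %in% 1:7))
  expect_true(all(a$reports$difficulty %in% 1:10))
  # SCR rate and tonic level are monotone in latent stress
  lat <- a$truth$latent_stress
  expect_equal(order(a$truth$window_rates), order(lat))
})

test_that("zero effect weights give null feature-environment association", {
  # with no link, pooled (setpoint, realized SCR count) pairs across many
  # independent short sessions show no association
  pairs <- purrr::map_dfr(1:30, function(i) {
    d <- session_design(n_windows = 4, window_s = 300, seed = 300 + i)
    s <- generate_session(d, weights = c(temperature = 0, co2 = 0,
                                         difficulty = 0),
                          eda_rate = 4, seed = 600 + i)
    counts <- as.numeric(table(factor(s$truth$events$window, levels = 1:4)))
    tibble::tibble(co2 = d$setpoints$CO2, temp = d$setpoints$Temperature,
                   count = counts)
  })
  expect_lt(abs(spearman_rho(pairs$co2, pairs$count)), 0.1)
  # and at the 2 Hz row level of a full default session, a fast-varying
  # feature (dphEDA from the true phasic) is uncorrelated with the
  # environment
  d <- session_design(seed = 31)
  s <- generate_session(d, weights = c(temperature = 0, co2 = 0,
                                       difficulty = 0),
                        eda_rate = 4, seed = 8)
  ph2 <- eda_resample(eda_signal(s$truth$phasic, 4), 2)
  stream <- tibble::tibble(time = ph2$time, dphEDA = dpheda(ph2$value, 2))
  joined <- sync_features(stream, s$environment)
  expect_gte(nrow(joined), 7200 * 2 - 10)
  expect_lt(abs(spearman_rho(joined$dphEDA, joined$Temperature)), 0.1)
  expect_lt(abs(spearman_rho(joined$dphEDA, joined$CO2)), 0.1)
})

test_that("a strong CO2 weight induces an association of the configured sign", {
  d <- session_design(n_windows = 8, window_s = 900, seed = 33)
  s <- generate_session(d, weights = c(temperature = 0, co2 = 3,
                                       difficulty = 0), seed = 12)
  lat <- s$truth$latent_stress
  expect_gt(spearman_rho(d$setpoints$CO2, lat), 0.9)
  counts <- table(factor(s$truth$events$window, levels = 1:8))
  expect_gt(spearman_rho(d$setpoints$CO2, as.numeric(counts)), 0.5)
})

test_that("the device pair reaches its designed correlation and lag", {
  g <- generate_eda(window_rates = rep(8, 2), window_s = 150, seed = 3)
  # identity transform, no noise: perfect agreement
  p0 <- generate_device_pair(g$conductance, seed = 1)
  v0 <- validate_devices(p0$device_a, p0$device_b, decompose = FALSE)
  expect_equal(v0$rho_raw, 1, tolerance = 1e-6)
  # uncorrelated noise swamps the copy
  pn <- generate_device_pair(g$conductance,
                             noise_sd = 50 * sd(g$conductance$value), seed = 2)
  vn <- validate_devices(pn$device_a, pn$device_b, decompose = FALSE)
  expect_lt(abs(vn$rho_raw), 0.1)
  # pure 1 s lag is recovered and correlation restored
  pl <- generate_device_pair(g$conductance, lag_s = 1, seed = 4)
  vl <- validate_devices(pl$device_a, pl$device_b, decompose = FALSE)
  expect_equal(vl$lag_s, 1, tolerance = 0.26)
  expect_gt(vl$rho_raw, 0.95)
})
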