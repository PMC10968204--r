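test_that("low-pass keeps DC, attenuates the cutoff to half power, kills the stopband", {
  n <- 4096
  t <- (0:(n - 1)) / 10
  const <- eda_signal(rep(2, n), 10)
  expect_equal(eda_lowpass(const)$value, rep(2, n), tolerance = 1e-9)

  tone <- eda_signal(sin(2 * pi * 1.5 * t), 10)
  out <- eda_lowpass(tone, 1.5, 32)
  i <- 500:3500
  expect_equal(rms(out$value[i]) / rms(tone$value[i]), 1 / sqrt(2),
               tolerance = 0.05)

  mix <- eda_signal(sin(2 * pi * 0.1 * t) + sin(2 * pi * 3 * t), 10)
  fo <- eda_lowpass(mix, 1.5, 32)
  X <- Mod(stats::fft(fo$value))
  Xi <- Mod(stats::fft(mix$value))
  k3 <- round(3 * n / 10) + 1 # exact bin of the 3 Hz line
  expect_lt(20 * log10(X[k3] / Xi[k3]), -60)
})

test_that("high-pass removes DC and trend but passes the 0.1 Hz band", {
  n <- 6000
  t <- (0:(n - 1)) / 10
  const <- eda_signal(rep(5, n), 10)
  expect_lt(max(abs(eda_highpass(const)$value)), 1e-9)

  ramp <- eda_signal(seq(0, 1, length.out = n), 10)
  expect_lt(abs(mean(eda_highpass(ramp)$value)), 0.01)

  tone <- eda_signal(sin(2 * pi * 0.1 * t), 10)
  hp <- eda_highpass(tone)
  expect_equal(rms(hp$value) / rms(tone$value), 1, tolerance = 0.05)
})

test_that("32nd-order filtering is numerically stable on long noise", {
  set.seed(11)
  noise <- eda_signal(rnorm(1e5), 10)
  out <- eda_lowpass(noise)
  expect_true(all(is.finite(out$value)))
  expect_lt(sum(out$value^2), sum(noise$value^2)) # energy cannot grow
})

test_that("resampling preserves duration, constants and band-limited content", {
  n <- 1200
  t <- (0:(n - 1)) / 10
  const <- eda_signal(rep(2, 600), 10)
  rc <- eda_resample(const, 4)
  expect_equal(rc$value, rep(2, nrow(rc)), tolerance = 1e-12)
  expect_equal(signal_rate(rc), 4)

  tone <- eda_signal(sin(2 * pi * 0.1 * t), 10)
  r2 <- eda_resample(tone, 2)
  expect_equal(nrow(r2), 240, tolerance = 1)
  expect_equal(max(abs(r2$value - sin(2 * pi * 0.1 * r2$time))), 0,
               tolerance = 0.01)

  # 600 samples at 10 Hz -> ~120 samples at 2 Hz
  short <- eda_resample(eda_signal(sin(2 * pi * 0.3 * (0:599) / 10), 10), 2)
  expect_true(abs(nrow(short) - 120) <= 1)

  # round trip of a band-limited signal within 1% RMS
  bl <- eda_signal(sin(2 * pi * 0.5 * t), 10)
  rt <- eda_resample(eda_resample(bl, 4), 10)
  ref <- sin(2 * pi * 0.5 * rt$time)
  expect_lt(rms(rt$value - ref) / rms(ref), 0.01)

  expect_error(eda_resample(eda_signal(2, 10), 4), "short")
})

test_that("normalization is a monotone map with the stated range", {
  s <- eda_signal(c(1, 2, 3), 1)
  expect_equal(eda_normalize(s)$value, c(0, 0.5, 1))
  set.seed(2)
  x <- eda_signal(rnorm(200), 4)
  nx <- eda_normalize(x)
  expect_equal(range(nx$value), c(0, 1))
  expect_equal(spearman_rho(x$value, nx$value), 1)
  expect_error(eda_normalize(eda_signal(rep(1, 10), 1)), "constant")
  z <- eda_normalize(x, "zscore")
  expect_equal(mean(z$value), 0, tolerance = 1e-12)
  expect_equal(sd(z$value), 1, tolerance = 1e-12)
})

test_that("moving average keeps constants, shrinks noise variance, spreads impulses", {
  const <- eda_signal(rep(3, 100), 4)
  expect_equal(eda_moving_average(const, 2)$value, rep(3, 100))
  set.seed(7)
  noise <- eda_signal(rnorm(8000), 4)
  sm <- eda_moving_average(noise, 2) # 8-sample window
  expect_equal(var(sm$value) / var(noise$value), 1 / 8, tolerance = 0.25)
  imp <- eda_signal(c(rep(0, 50), 1, rep(0, 50)), 4)
  mi <- eda_moving_average(imp, 2)
  expect_equal(sum(mi$value > 0), 8)
  expect_equal(max(mi$value), 1 / 8, tolerance = 1e-12)
})

test_that("z-score outlier mask flags exactly the planted point", {
  set.seed(5)
  x <- runif(500, -2, 2) # bounded, so no natural 3-sigma points
  x[123] <- 10 * sd(x)
  res <- remove_outliers_zscore(x, 3)
  expect_true(res$is_outlier[123])
  expect_equal(sum(res$is_outlier), 1)
  expect_equal(remove_outliers_zscore(rep(4, 50), 3)$is_outlier, rep(FALSE, 50))
  expect_equal(remove_outliers_zscore(x, Inf)$cleaned, x)
})

test_that("provenance accumulates across transforms", {
  s <- eda_signal(rnorm(100) + 5, 10)
  out <- eda_moving_average(eda_normalize(eda_lowpass(s)), 1)
  expect_length(signal_provenance(out), 3)
  expect_match(signal_provenance(out)[1], "lowpass")
})
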