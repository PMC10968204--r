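# shared fixtures, built in code

# biexponential SCR shape used to synthesize conductance by hand,
# peak-normalized like the decomposition kernel
biexp_shape <- function(tt, tau0 = 2, tau1 = 0.7) {
  h <- ifelse(tt < 0, 0, exp(-tt / tau0) - exp(-tt / tau1))
  tpk <- log(tau0 / tau1) * tau0 * tau1 / (tau0 - tau1)
  h / (exp(-tpk / tau0) - exp(-tpk / tau1))
}

# conductance trace with known SCR onsets on a drifting baseline
make_scr_trace <- function(onsets, amplitude = 0.5, dur = 600, rate = 4,
                           baseline = 2, drift = 0.0005, noise_sd = 0.01,
                           seed = 42) {
  set.seed(seed)
  tt <- (seq_len(dur * rate) - 1) / rate
  y <- baseline + drift * tt
  for (o in onsets) y <- y + amplitude * biexp_shape(tt - o)
  y <- y + rnorm(length(tt), 0, noise_sd)
  eda_signal(y, rate)
}

# brute-force Spearman oracle: explicit average ranks + explicit Pearson
spearman_oracle <- function(x, y) {
  avg_rank <- function(v) {
    n <- length(v)
    r <- numeric(n)
    for (i in seq_len(n)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  mx <- sum(rx) / length(rx)
  my <- sum(ry) / length(ry)
  sum((rx - mx) * (ry - my)) / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

rms <- function(v) sqrt(mean(v^2))
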