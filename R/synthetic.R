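#' Design of a synthetic experimental session
#'
#' Encodes the session protocol: contiguous equal-length windows (eight
#' 15-minute windows by default, a two-hour session), each with its own
#' randomized microclimate setpoints and task difficulty. A few windows
#' carry easy tasks and serve as baseline / low-stress periods; the rest
#' carry hard tasks. Setpoints are drawn uniformly within realistic indoor
#' ranges recorded in the `setpoints` tibble, one row per window.
#'
#' @param n_windows Number of protocol windows.
#' @param window_s Window length in seconds.
#' @param baseline_windows Indices of baseline (easy-task) windows.
#' @param difficulty Optional integer vector (1-10) per window; defaults
#'   to 1-2 on baseline windows and 7-9 elsewhere.
#' @param setpoints Optional tibble (one row per window) with the twelve
#'   environmental columns; randomized when omitted.
#' @param seed Seed for the randomized design.
#' @return A list of class `session_design`.
#' @export
session_design <- function(n_windows = 8, window_s = 900,
                           baseline_windows = c(1, 5),
                           difficulty = NULL, setpoints = NULL, seed = 1L) {
  stopifnot(n_windows >= 1, window_s > 0)
  set.seed(seed)
  is_base <- seq_len(n_windows) %in% baseline_windows
  if (is.null(difficulty)) {
    difficulty <- ifelse(is_base,
                         sample(1:2, n_windows, replace = TRUE),
                         sample(7:9, n_windows, replace = TRUE))
  }
  stopifnot(length(difficulty) == n_windows,
            all(difficulty >= 1 & difficulty <= 10))
  if (is.null(setpoints)) {
    setpoints <- tibble::tibble(
      Sound = stats::runif(n_windows, 30, 70),
      Visible = stats::runif(n_windows, 100, 500),
      IR = stats::runif(n_windows, 50, 300),
      UV = stats::runif(n_windows, 0, 5),
      Temperature = stats::runif(n_windows, 20, 32),
      Humid = stats::runif(n_windows, 40, 85),
      Pressure = stats::runif(n_windows, 1000, 1020),
      CO2 = stats::runif(n_windows, 400, 1800),
      PM1 = stats::runif(n_windows, 2, 25),
      PM2.5 = stats::runif(n_windows, 5, 40),
      PM10 = stats::runif(n_windows, 10, 60),
      Wind = stats::runif(n_windows, 0, 2)
    )
  }
  stopifnot(nrow(setpoints) == n_windows,
            all(env_variables() %in% names(setpoints)))
  structure(
    list(n_windows = n_windows, window_s = window_s,
         is_baseline = is_base, difficulty = as.integer(difficulty),
         setpoints = setpoints[env_variables()], seed = as.integer(seed)),
    class = "session_design"
  )
}

# peak-normalized biexponential SCR kernel sampled at `rate`
scr_kernel <- function(rate, tau0 = 2, tau1 = 0.7, length_s = 30) {
  tt <- seq(0, length_s, by = 1 / rate)
  h <- exp(-tt / tau0) - exp(-tt / tau1)
  h / max(h)
}

#' Generate a synthetic EDA recording with known ground truth
#'
#' Conductance is built as tonic (baseline + linear drift + slow
#' thermoregulatory sinusoid below 0.05 Hz) plus a train of SCRs with
#' biexponential shape (`tau0` = 2 s, `tau1` = 0.7 s, peak amplitudes
#' LogNormal(meanlog -1.2, sdlog 0.4) microsiemens) at Poisson event times
#' with a per-window rate, plus Gaussian noise; the conductance is then
#' pushed back through the wristband divider equations to produce voltage
#' samples in `[0, Vdd/2)`.
#'
#' @param window_rates SCR rates per window, events/minute (length =
#'   number of windows).
#' @param window_s Window length in seconds.
#' @param rate Sampling rate in Hz (>= 4).
#' @param tonic_base Baseline conductance in microsiemens per window
#'   (scalar or per window).
#' @param drift_per_hour Linear tonic drift, microsiemens/hour.
#' @param slow_wave_amp,slow_wave_freq Amplitude (uS) and frequency (Hz,
#'   < 0.05) of the slow tonic oscillation.
#' @param noise_sd Gaussian noise SD in microsiemens.
#' @param amp_meanlog,amp_sdlog Log-normal SCR amplitude parameters.
#' @param tau0,tau1 SCR kernel time constants in seconds.
#' @param device A [device_config()] for the voltage conversion.
#' @param seed Seed; the generator is a pure function of (arguments, seed).
#' @param subject_id Label stored with the recording.
#' @return A list: `wristband` (tibble `time`, `vout`), `conductance`
#'   (the noiseless-inverse [eda_signal()] actually sampled, uS), `truth`
#'   (list: `events` tibble with `time`, `amplitude`, `window`; `tonic`
#'   numeric; `window_rates`; parameters).
#' @export
generate_eda <- function(window_rates = c(2, 18, 8, 18, 2, 18, 8, 18),
                         window_s = 900, rate = 10,
                         tonic_base = 2.0, drift_per_hour = 0.3,
                         slow_wave_amp = 0.1, slow_wave_freq = 0.01,
                         noise_sd = 0.01,
                         amp_meanlog = -1.2, amp_sdlog = 0.4,
                         tau0 = 2, tau1 = 0.7,
                         device = device_config(), seed = 1L,
                         subject_id = "S1") {
  stopifnot(rate >= 4, window_s > 0, slow_wave_freq < 0.05)
  set.seed(seed)
  n_win <- length(window_rates)
  dur <- n_win * window_s
  n <- round(dur * rate)
  tt <- (seq_len(n) - 1) / rate
  win_of <- pmin(floor(tt / window_s) + 1L, n_win)
  base_w <- rep_len(tonic_base, n_win)

  tonic <- base_w[win_of] + drift_per_hour * tt / 3600 +
    slow_wave_amp * sin(2 * pi * slow_wave_freq * tt)

  events <- purrr::map_dfr(seq_len(n_win), function(w) {
    lam <- window_rates[w] / 60 # events per second
    n_ev <- stats::rpois(1, lam * window_s)
    if (n_ev == 0) return(tibble::tibble(time = numeric(), amplitude = numeric(),
                                         window = integer()))
    tibble::tibble(
      time = sort(stats::runif(n_ev, (w - 1) * window_s, w * window_s)),
      amplitude = stats::rlnorm(n_ev, amp_meanlog, amp_sdlog),
      window = w
    )
  })

  phasic <- numeric(n)
  if (nrow(events)) {
    kern <- scr_kernel(rate, tau0, tau1)
    spikes <- numeric(n)
    idx <- pmin(n, floor(events$time * rate) + 1L)
    for (i in seq_along(idx)) {
      spikes[idx[i]] <- spikes[idx[i]] + events$amplitude[i]
    }
    conv <- stats::convolve(spikes, rev(kern), type = "open")[seq_len(n)]
    phasic <- conv
  }

  g <- tonic + phasic + stats::rnorm(n, 0, noise_sd)
  rskin <- 1e6 / g
  vout <- resistance_to_voltage(rskin, device)
  if (any(vout < 0 | vout >= device$supply_voltage / 2)) {
    rlang::abort(paste(
      "generated conductance leaves the measurable range of the divider;",
      "lower the tonic/noise parameters or raise the reference resistance"
    ))
  }
  wristband <- tibble::tibble(time = tt, vout = vout)
  attr(wristband, "device") <- device
  attr(wristband, "subject_id") <- subject_id
  list(
    wristband = wristband,
    conductance = eda_signal(g, rate, units = "uS",
                             provenance = "synthetic:generate_eda"),
    truth = list(
      events = events, tonic = tonic, phasic = phasic,
      window_rates = window_rates, window_s = window_s,
      noise_sd = noise_sd, seed = seed, subject_id = subject_id
    )
  )
}

#' Generate a synthetic environmental log
#'
#' Per-window setpoints with stationary AR(1) within-window fluctuation
#' (`x_t = setpoint + phi (x_{t-1} - setpoint) + eps`), emitted for all
#' twelve environmental variables at ~1 Hz.
#'
#' @param design A [session_design()].
#' @param rate Sampling rate in Hz.
#' @param fluct_sd Stationary fluctuation SD as a fraction of each
#'   variable's setpoint range across windows (0 disables fluctuation).
#' @param phi AR(1) coefficient.
#' @param seed Seed.
#' @return A tibble: `time` plus the twelve environmental columns.
#' @export
generate_environment <- function(design, rate = 1, fluct_sd = 0.05,
                                 phi = 0.95, seed = 1L) {
  stopifnot(inherits(design, "session_design"))
  set.seed(seed)
  n <- round(design$n_windows * design$window_s * rate)
  tt <- (seq_len(n) - 1) / rate
  win_of <- pmin(floor(tt / design$window_s) + 1L, design$n_windows)
  out <- tibble::tibble(time = tt)
  for (v in env_variables()) {
    sp <- design$setpoints[[v]][win_of]
    spread <- diff(range(design$setpoints[[v]]))
    sd_st <- fluct_sd * max(spread, 1e-12)
    if (sd_st > 0) {
      innov_sd <- sd_st * sqrt(1 - phi^2)
      ar <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                                     method = "recursive"))
      out[[v]] <- sp + ar
    } else {
      out[[v]] <- sp
    }
  }
  out
}

#' Generate a full synthetic session with a latent-stress link
#'
#' Ties the three streams together: each window's latent stress is a
#' logistic function of its standardized temperature and CO2 setpoints and
#' task difficulty. SCR rate, tonic level, and the self-reported stress,
#' arousal and valence are monotone in latent stress, so hard windows in
#' adverse microclimates produce dense SCR trains, elevated tonic levels
#' and high-stress self-reports. The default weights put most of the
#' latent-stress variance on task difficulty (as in the protocol, where
#' hard tasks are the stressor and the microclimate modulates), which
#' makes hard windows earn the high-stress label with probability above
#' 0.9 while keeping the environmental effects detectable.
#'
#' @param design A [session_design()].
#' @param weights Named numeric: effect weights `temperature`, `co2`,
#'   `difficulty` on the latent-stress logit.
#' @param rate_range SCR events/minute at latent stress 0 and 1.
#' @param tonic_range Tonic baseline (uS) at latent stress 0 and 1.
#' @param eda_rate Wristband sampling rate in Hz.
#' @param env_rate Environmental sampling rate in Hz.
#' @param report_noise_sd Logistic noise SD on the discretized
#'   self-report scores.
#' @param noise_sd Conductance noise SD (uS), passed to [generate_eda()].
#' @param seed Seed for the whole triplet.
#' @param subject_id Subject label.
#' @return A list: `wristband`, `environment`, `reports` (one row per
#'   window: `subject`, `window`, `difficulty`, `stress`, `valence`,
#'   `arousal`, `dominance`, `is_baseline`), `conductance`, and `truth`
#'   (adds `latent_stress` per window to the [generate_eda()] truth).
#' @export
generate_session <- function(design = session_design(),
                             weights = c(temperature = 0.5, co2 = 0.5,
                                         difficulty = 4),
                             rate_range = c(4, 20),
                             tonic_range = c(2, 4),
                             eda_rate = 10, env_rate = 1,
                             report_noise_sd = 0.4,
                             noise_sd = 0.01,
                             seed = 1L, subject_id = "S1") {
  stopifnot(inherits(design, "session_design"))
  zs <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  zT <- zs(design$setpoints$Temperature)
  zC <- zs(design$setpoints$CO2)
  zD <- zs(design$difficulty)
  logit <- weights[["temperature"]] * zT + weights[["co2"]] * zC +
    weights[["difficulty"]] * zD
  latent <- stats::plogis(logit)

  window_rates <- rate_range[1] + (rate_range[2] - rate_range[1]) * latent
  tonic_levels <- tonic_range[1] + (tonic_range[2] - tonic_range[1]) * latent

  eda <- generate_eda(
    window_rates = window_rates, window_s = design$window_s,
    rate = eda_rate, tonic_base = tonic_levels, noise_sd = noise_sd,
    seed = seed, subject_id = subject_id
  )
  env <- generate_environment(design, rate = env_rate, seed = seed + 1L)

  set.seed(seed + 2L)
  n_win <- design$n_windows
  jitter <- stats::rlogis(n_win, 0, report_noise_sd)
  clip <- function(x, lo, hi) pmin(hi, pmax(lo, round(x)))
  stress_score <- clip(1 + 7 * latent + jitter, 1, 7)
  arousal <- clip(1 + 8 * latent + stats::rlogis(n_win, 0, report_noise_sd), 1, 9)
  valence <- clip(9 - 8 * latent + stats::rlogis(n_win, 0, report_noise_sd), 1, 9)
  dominance <- clip(9 - 6 * latent + stats::rlogis(n_win, 0, report_noise_sd), 1, 9)
  reports <- tibble::tibble(
    subject = subject_id,
    window = seq_len(n_win),
    difficulty = design$difficulty,
    stress = as.integer(stress_score),
    valence = as.integer(valence),
    arousal = as.integer(arousal),
    dominance = as.integer(dominance),
    is_baseline = design$is_baseline
  )
  truth <- eda$truth
  truth$latent_stress <- latent
  truth$design <- design
  list(
    wristband = eda$wristband,
    environment = env,
    reports = reports,
    conductance = eda$conductance,
    truth = truth
  )
}

#' Generate a paired recording emulating a second (reference) device
#'
#' The second stream is an affine-transformed (`gain`, `offset`), lagged
#' and independently noised copy of the base conductance, resampled to the
#' reference device rate (4 Hz): the standard two-wrists validation setup
#' where a reference-grade sensor runs beside the DIY wristband. Setting
#' `noise_sd = sd(x) * sqrt(1 / rho^2 - 1)` targets a Pearson correlation
#' of about `rho` between the pair.
#'
#' @param base An [eda_signal()] (the DIY-device conductance).
#' @param gain,offset Affine map applied to the copy.
#' @param noise_sd Independent Gaussian noise SD added to the copy (uS).
#' @param lag_s Lag of the copy in seconds (positive = copy delayed).
#' @param ref_rate Reference device sampling rate in Hz.
#' @param seed Seed.
#' @return A list of two [eda_signal()]s: `device_a` (base resampled to
#'   `ref_rate`) and `device_b` (the transformed copy).
#' @export
generate_device_pair <- function(base, gain = 1, offset = 0, noise_sd = 0,
                                 lag_s = 0, ref_rate = 4, seed = 1L) {
  stopifnot(inherits(base, "eda_signal"))
  a <- eda_resample(base, ref_rate)
  set.seed(seed)
  shifted <- if (abs(lag_s) > 0) {
    k <- round(lag_s * ref_rate)
    v <- a$value
    if (k > 0) c(rep(v[1], k), v[seq_len(length(v) - k)])
    else c(v[(-k + 1):length(v)], rep(v[length(v)], -k))
  } else {
    a$value
  }
  b <- gain * shifted + offset + stats::rnorm(nrow(a), 0, noise_sd)
  list(
    device_a = a,
    device_b = eda_signal(b, ref_rate, start_time = a$time[1], units = "uS",
                          provenance = "synthetic:device_pair")
  )
}
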