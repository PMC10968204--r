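#' Configuration of the frequency-domain EDA indices
#'
#' @param analysis_rate Working rate in Hz (the indices are defined on
#'   2 Hz EDA).
#' @param edasymp_band Frequency band (Hz) integrated for EDASymp.
#' @param tvsymp_band Frequency band (Hz) whose time-varying amplitude
#'   defines TVSymp.
#' @param fft_window_length Segment length in samples for the windowed
#'   periodogram (Blackman window).
#' @param segment_overlap Fractional overlap between consecutive segments.
#'   A literal one-sample overlap can be requested with
#'   `segment_overlap = "one_sample"`.
#' @param mtvsymp_lookback Lookback in seconds for the MTVSymp rolling
#'   baseline.
#' @param vfcdm_spacing Center-frequency grid spacing (and demodulation
#'   bandwidth) in Hz for the variable-frequency complex demodulation.
#' @param vfcdm_order Order of the low-pass used to extract each
#'   demodulated component.
#' @return A list of class `spectral_config`.
#' @export
spectral_config <- function(analysis_rate = 2,
                            edasymp_band = c(0.045, 0.25),
                            tvsymp_band = c(0.08, 0.24),
                            fft_window_length = 128,
                            segment_overlap = 0.5,
                            mtvsymp_lookback = 5,
                            vfcdm_spacing = 0.03,
                            vfcdm_order = 6) {
  stopifnot(
    analysis_rate > 0, fft_window_length >= 8,
    all(edasymp_band > 0), all(edasymp_band < analysis_rate / 2),
    all(tvsymp_band > 0), all(tvsymp_band < analysis_rate / 2),
    mtvsymp_lookback > 0, vfcdm_spacing > 0
  )
  structure(
    list(analysis_rate = analysis_rate, edasymp_band = edasymp_band,
         tvsymp_band = tvsymp_band, fft_window_length = fft_window_length,
         segment_overlap = segment_overlap,
         mtvsymp_lookback = mtvsymp_lookback,
         vfcdm_spacing = vfcdm_spacing, vfcdm_order = vfcdm_order),
    class = "spectral_config"
  )
}

# Blackman window of length n
blackman_win <- function(n) {
  k <- seq_len(n) - 1
  0.42 - 0.5 * cos(2 * pi * k / (n - 1)) + 0.08 * cos(4 * pi * k / (n - 1))
}

#' Spectral sympathetic index (EDASymp)
#'
#' Averaged windowed periodogram of 2 Hz EDA: the series is cut into
#' `fft_window_length`-sample segments (Blackman window, 50% overlap by
#' default), the periodogram of each segment is averaged, and the power in
#' `edasymp_band` is reported both as absolute power and normalized by the
#' total power above DC.
#'
#' @param x An [eda_signal()] at the analysis rate, already detrended
#'   (see [eda_highpass()]).
#' @param cfg A [spectral_config()].
#' @return A one-row tibble with columns `power` (band power, uS^2) and
#'   `normalized` (fraction of total above-DC power, in `[0, 1]`).
#' @export
edasymp <- function(x, cfg = spectral_config()) {
  rate <- signal_rate(x)
  if (abs(rate - cfg$analysis_rate) > 1e-9) {
    rlang::abort(sprintf("edasymp expects a %g Hz signal; resample first",
                         cfg$analysis_rate))
  }
  nw <- cfg$fft_window_length
  v <- x$value
  if (length(v) < nw) rlang::abort("signal shorter than one analysis window")
  step <- if (identical(cfg$segment_overlap, "one_sample")) {
    nw - 1L
  } else {
    max(1L, round(nw * (1 - cfg$segment_overlap)))
  }
  starts <- seq(1L, length(v) - nw + 1L, by = step)
  win <- blackman_win(nw)
  wnorm <- sum(win^2)
  psd <- rowMeans(vapply(starts, function(s0) {
    seg <- v[s0 + seq_len(nw) - 1L]
    seg <- seg - mean(seg)
    Mod(stats::fft(seg * win))^2 / (wnorm * rate)
  }, numeric(nw)))
  freq <- (seq_len(nw) - 1) * rate / nw
  half <- which(freq > 0 & freq <= rate / 2)
  in_band <- half[freq[half] >= cfg$edasymp_band[1] &
                    freq[half] <= cfg$edasymp_band[2]]
  df <- rate / nw
  band_power <- sum(psd[in_band]) * df
  total_power <- sum(psd[half]) * df
  tibble::tibble(
    power = band_power,
    normalized = if (total_power > 0) band_power / total_power else NA_real_
  )
}

# analytic signal via FFT (Hilbert transform)
analytic_signal <- function(v) {
  n <- length(v)
  V <- stats::fft(v)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(V * h, inverse = TRUE) / n
}

# Variable-frequency complex demodulation. First stage: fixed-band
# demodulation at a grid of center frequencies with low-pass component
# extraction. Refinement stage: each component is re-demodulated at its
# own (smoothed) instantaneous frequency, sharpening components whose
# content drifts within the band.
vfcdm_components <- function(v, rate, spacing = 0.03, order = 6,
                             refine = TRUE) {
  n <- length(v)
  tt <- (seq_len(n) - 1) / rate
  centers <- seq(spacing, rate / 2 - spacing / 2, by = spacing)
  lp <- butter_sos(order, spacing / 2, rate, "low")
  comps <- lapply(centers, function(fc) {
    z <- v * exp(-2i * pi * fc * tt)
    zlp <- complex(
      real = sos_filtfilt(lp, Re(z)),
      imaginary = sos_filtfilt(lp, Im(z))
    )
    if (refine) {
      # instantaneous frequency of the demodulated component, smoothed and
      # bounded to the component band; the component itself (not the raw
      # signal) is re-centered at it, so content outside the band can
      # never be double-counted by a neighboring component
      phase <- atan2(Im(zlp), Re(zlp))
      finst <- fc + c(0, diff(unwrap_phase(phase))) * rate / (2 * pi)
      finst <- pmin(pmax(finst, fc - spacing / 2), fc + spacing / 2)
      finst <- stats::filter(finst, rep(1 / round(2 * rate), round(2 * rate)),
                             sides = 2)
      finst[is.na(finst)] <- fc
      dphi <- 2 * pi * cumsum(as.numeric(finst) - fc) / rate
      z2 <- zlp * exp(-1i * dphi) # residual demodulation within the band
      zlp <- complex(
        real = sos_filtfilt(lp, Re(z2)),
        imaginary = sos_filtfilt(lp, Im(z2))
      ) * exp(1i * dphi)
    }
    2 * Re(zlp * exp(2i * pi * fc * tt))
  })
  list(centers = centers, components = comps)
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1], p[1] + cumsum(dp))
}

#' Time-varying sympathetic index (TVSymp)
#'
#' Variable-frequency complex demodulation of 2 Hz EDA: the signal is
#' demodulated on a grid of center frequencies, each component extracted
#' with a low-pass and refined at its instantaneous frequency; components
#' whose center frequencies fall in `tvsymp_band` are summed and the
#' magnitude of the analytic signal of that sum gives the instantaneous
#' amplitude. The conventional summary statistic is the mean of the
#' unit-variance-normalized amplitude series.
#'
#' @param x An [eda_signal()] at the analysis rate, detrended.
#' @param cfg A [spectral_config()].
#' @param refine Run the variable-frequency refinement stage.
#' @return A tibble of class `tvsymp_series` with columns `time`,
#'   `amplitude` (instantaneous in-band amplitude, input units) and
#'   `tvsymp` (the amplitude normalized to unit variance). The mean of
#'   `tvsymp` is the windowed summary feature.
#' @export
tvsymp <- function(x, cfg = spectral_config(), refine = TRUE) {
  rate <- signal_rate(x)
  if (abs(rate - cfg$analysis_rate) > 1e-9) {
    rlang::abort(sprintf("tvsymp expects a %g Hz signal; resample first",
                         cfg$analysis_rate))
  }
  if (nrow(x) < 60 * rate) rlang::abort("signal shorter than 60 s")
  v <- x$value
  if (all(v == 0)) {
    return(structure(
      tibble::tibble(time = x$time, amplitude = 0, tvsymp = 0),
      class = c("tvsymp_series", class(tibble::tibble()))
    ))
  }
  dec <- vfcdm_components(v, rate, cfg$vfcdm_spacing, cfg$vfcdm_order,
                          refine = refine)
  in_band <- dec$centers >= cfg$tvsymp_band[1] &
    dec$centers <= cfg$tvsymp_band[2]
  band_sum <- Reduce(`+`, dec$components[in_band])
  amp <- Mod(analytic_signal(band_sum))
  s <- stats::sd(amp)
  structure(
    tibble::tibble(
      time = x$time,
      amplitude = amp,
      tvsymp = if (s > 0) amp / s else amp * 0
    ),
    class = c("tvsymp_series", class(tibble::tibble()))
  )
}

#' Modified TVSymp (MTVSymp)
#'
#' The excess of the current TVSymp value over the mean TVSymp of the
#' preceding `lookback` seconds, clipped at zero: a detector of abrupt
#' sympathetic surges. The first `lookback` seconds use the partial
#' history available.
#'
#' @param tvs Numeric TVSymp series (or the `tvsymp` column of
#'   [tvsymp()] output).
#' @param rate Sampling rate of `tvs` in Hz.
#' @param lookback Rolling-baseline window in seconds.
#' @return Non-negative numeric series, same length as `tvs`.
#' @export
mtvsymp <- function(tvs, rate, lookback = 5) {
  if (length(tvs) == 0) rlang::abort("empty input")
  w <- max(1L, round(lookback * rate))
  cs <- cumsum(c(0, tvs))
  n <- length(tvs)
  i <- seq_len(n)
  lo <- pmax(1L, i - w)
  cnt <- i - lo
  prev_mean <- ifelse(cnt > 0, (cs[i] - cs[lo]) / pmax(cnt, 1L), tvs)
  pmax(0, tvs - prev_mean)
}
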