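#' Skin conductance level (SCL) per window
#'
#' Mean of the tonic component over contiguous fixed-length windows
#' (2 minutes by default).
#'
#' @param tonic Numeric tonic series in microsiemens.
#' @param rate Sampling rate in Hz.
#' @param window_s Window length in seconds.
#' @return A tibble with columns `window`, `t_start`, `t_end`, `scl`.
#' @export
scl <- function(tonic, rate, window_s = 120) {
  wlen <- round(window_s * rate)
  if (wlen < 2) rlang::abort("window too short: need window_s * rate >= 2")
  if (length(tonic) < wlen) rlang::abort("window longer than the signal")
  nwin <- floor(length(tonic) / wlen)
  idx <- rep(seq_len(nwin), each = wlen)
  means <- as.numeric(tapply(tonic[seq_len(nwin * wlen)], idx, mean))
  tibble::tibble(
    window = seq_len(nwin),
    t_start = (seq_len(nwin) - 1) * window_s,
    t_end = seq_len(nwin) * window_s,
    scl = means
  )
}

# prominence-based local maxima: a peak's prominence is its height above
# the higher of the two minima separating it from taller neighbors
find_scr_peaks <- function(v, rate, min_prominence, min_distance_s = 1) {
  n <- length(v)
  if (n < 3) return(integer())
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  if (!length(cand)) return(integer())
  prom <- vapply(cand, function(i) {
    h <- v[i]
    lhs <- v[seq_len(i - 1)]
    higher_l <- which(lhs > h)
    left_min <- min(v[(if (length(higher_l)) max(higher_l) else 1):i])
    rhs <- v[i:n]
    higher_r <- which(rhs > h)
    right_min <- min(v[i:(if (length(higher_r)) i + min(higher_r) - 1 else n)])
    h - max(left_min, right_min)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  promk <- prom[prom >= min_prominence]
  if (!length(keep)) return(integer())
  # enforce minimum inter-peak distance, keeping the more prominent peak
  ord <- order(promk, decreasing = TRUE)
  sel <- logical(length(keep))
  taken <- rep(FALSE, n)
  # peaks separated by exactly min_distance_s are still distinct events
  min_d <- max(1L, round(min_distance_s * rate) - 1L)
  for (j in ord) {
    i <- keep[j]
    lo <- max(1, i - min_d)
    hi <- min(n, i + min_d)
    if (!any(taken[lo:hi])) {
      sel[j] <- TRUE
      taken[i] <- TRUE
    }
  }
  sort(keep[sel])
}

#' Non-specific SCR rate (NSSCR)
#'
#' Counts rapid transient events in the phasic component as local maxima
#' with prominence at least `min_amplitude` and at least 1 s apart,
#' reported as responses per minute per window.
#'
#' @param phasic Numeric phasic (or driver) series in microsiemens.
#' @param rate Sampling rate in Hz.
#' @param window_s Window length in seconds.
#' @param min_amplitude Minimum peak prominence in microsiemens.
#' @param min_distance_s Minimum separation between counted peaks.
#' @return A tibble with columns `window`, `t_start`, `t_end`, `n_scr`,
#'   `nsscr` (responses per minute).
#' @export
nsscr <- function(phasic, rate, window_s = 120, min_amplitude = 0.01,
                  min_distance_s = 1) {
  if (rate < 2) rlang::abort("nsscr needs a sampling rate of at least 2 Hz")
  wlen <- round(window_s * rate)
  nwin <- max(1L, floor(length(phasic) / wlen))
  purrr::map_dfr(seq_len(nwin), function(w) {
    idx <- ((w - 1) * wlen + 1):min(w * wlen, length(phasic))
    pk <- find_scr_peaks(phasic[idx], rate, min_amplitude, min_distance_s)
    tibble::tibble(
      window = w,
      t_start = (w - 1) * window_s,
      t_end = (w - 1) * window_s + length(idx) / rate,
      n_scr = length(pk),
      nsscr = length(pk) / (length(idx) / rate) * 60
    )
  })
}

#' Derivative of the phasic component (dphEDA)
#'
#' Central differences with one-sided differences at the boundaries;
#' length is preserved.
#'
#' @param phasic Numeric phasic series in microsiemens.
#' @param rate Sampling rate in Hz.
#' @return Numeric derivative series in microsiemens per second.
#' @export
dpheda <- function(phasic, rate) {
  n <- length(phasic)
  if (n < 2) rlang::abort("need at least two samples")
  d <- numeric(n)
  d[2:(n - 1)] <- (phasic[3:n] - phasic[1:(n - 2)]) * rate / 2
  d[1] <- (phasic[2] - phasic[1]) * rate
  d[n] <- (phasic[n] - phasic[n - 1]) * rate
  d
}

#' Build the 2 Hz per-sample feature stream from a decomposition
#'
#' Computes the instantaneous feature channels on the 2 Hz grid: tonic
#' (SCL carrier), phasic, dphEDA, TVSymp and MTVSymp series, plus a
#' windowed EDASymp/NSSCR broadcast per `window_s` window. SCR events are
#' taken from the sparse driver ([driver_events()]), which separates
#' responses that overlap into a single peak in the phasic trace; the
#' event indicator is kept as a `scr_event` column so coarser windowings
#' can recount exactly.
#'
#' @param decomp An `eda_decomposition` (any rate; resampled internally).
#' @param cfg A [spectral_config()].
#' @param window_s Feature window length in seconds for the windowed
#'   channels.
#' @param min_amplitude Minimum driver peak for SCR counting,
#'   microsiemens.
#' @param min_distance_s Minimum separation between counted SCR events.
#'   At NS-SCR rates above roughly 12 per minute, a 4 Hz working rate
#'   merges closely spaced responses; decompose at 8 Hz and lower this to
#'   0.25 s to resolve them.
#' @return A tibble at 2 Hz with columns `time`, `tonic`, `phasic`,
#'   `SCL`, `dphEDA`, `TVSymp`, `MTVSymp`, `EDASymp`, `NSSCR`,
#'   `scr_event` (the windowed columns constant within each window).
#' @export
eda_feature_stream <- function(decomp, cfg = spectral_config(),
                               window_s = 120, min_amplitude = 0.1,
                               min_distance_s = 0.5) {
  rate0 <- attr(decomp, "rate")
  target <- cfg$analysis_rate
  res <- function(v) {
    if (abs(rate0 - target) < 1e-9) return(v)
    eda_resample(eda_signal(v, rate0, start_time = decomp$time[1]), target)$value
  }
  tonic2 <- res(decomp$tonic)
  phasic2 <- res(decomp$phasic)
  raw2 <- res(decomp$raw)
  n <- length(tonic2)
  tt <- decomp$time[1] + (seq_len(n) - 1) / target

  detr <- eda_highpass(eda_signal(raw2, target, start_time = tt[1]))
  tv <- tvsymp(detr, cfg)
  mtv <- mtvsymp(tv$tvsymp, target, cfg$mtvsymp_lookback)

  wlen <- round(window_s * target)
  win_id <- pmin(ceiling(seq_len(n) / wlen), max(1L, floor(n / wlen)))
  scl_w <- tapply(tonic2, win_id, mean)
  ev <- driver_events(decomp, min_amplitude, min_distance_s)
  scr_event <- integer(n)
  if (nrow(ev)) {
    pos <- pmin(n, pmax(1L, round((ev$onset - tt[1]) * target) + 1L))
    for (k in pos) scr_event[k] <- scr_event[k] + 1L
  }
  nss_w <- tapply(scr_event, win_id, function(e) sum(e) / (length(e) / target) * 60)
  eda_w <- vapply(split(seq_len(n), win_id), function(idx) {
    if (length(idx) >= cfg$fft_window_length) {
      edasymp(eda_signal(detr$value[idx], target), cfg)$power
    } else {
      NA_real_
    }
  }, numeric(1))

  tibble::tibble(
    time = tt,
    tonic = tonic2,
    phasic = phasic2,
    SCL = as.numeric(scl_w[win_id]),
    dphEDA = dpheda(phasic2, target),
    TVSymp = tv$tvsymp,
    MTVSymp = mtv,
    EDASymp = as.numeric(eda_w[win_id]),
    NSSCR = as.numeric(nss_w[win_id]),
    scr_event = scr_event
  )
}

#' Synchronize EDA features with the environmental stream
#'
#' Joins a 2 Hz EDA feature table with a ~1 Hz environmental log on the
#' 2 Hz grid: each environmental variable is carried forward from its most
#' recent observation (at most `max_gap_s` old); rows outside the
#' overlapping time range are dropped; no EDA row inside the overlap is
#' dropped or duplicated.
#'
#' @param eda_feats Tibble with a `time` column at 2 Hz (e.g.
#'   [eda_feature_stream()] output).
#' @param env Tibble with a `time` column and environmental variables
#'   (e.g. [read_environment_csv()] output).
#' @param max_gap_s Maximum staleness of a carried-forward environment
#'   sample; larger gaps leave `NA`.
#' @return The joined tibble, one row per in-overlap EDA sample.
#' @export
sync_features <- function(eda_feats, env, max_gap_s = 2) {
  stopifnot("time" %in% names(eda_feats), "time" %in% names(env))
  lo <- max(min(eda_feats$time), min(env$time))
  hi <- min(max(eda_feats$time), max(env$time))
  if (lo > hi) rlang::abort("disjoint time ranges: nothing to synchronize")
  out <- dplyr::filter(eda_feats, .data$time >= lo, .data$time <= hi)
  env <- dplyr::arrange(env, .data$time)
  pos <- findInterval(out$time + 1e-9, env$time)
  pos[pos == 0] <- NA_integer_
  stale <- !is.na(pos) & (out$time - env$time[pmax(pos, 1)]) > max_gap_s
  pos[stale] <- NA_integer_
  envcols <- setdiff(names(env), "time")
  for (cl in envcols) {
    out[[cl]] <- env[[cl]][pos]
  }
  out
}

#' Aggregate a synchronized feature table per protocol window
#'
#' Cuts the 2 Hz stream into contiguous protocol windows (15 minutes by
#' default) and aggregates every numeric column by its mean, except
#' `NSSCR`, which is recounted exactly from the `scr_event` indicator
#' when present.
#'
#' @param table A synchronized 2 Hz table ([sync_features()] output).
#' @param window_s Protocol window length in seconds.
#' @param rate Sampling rate of `table` in Hz.
#' @return One row per window: `window`, `t_start`, `t_end`, aggregated
#'   features and environmental variables.
#' @export
window_features <- function(table, window_s = 900, rate = 2) {
  t0 <- min(table$time)
  win <- floor((table$time - t0) / window_s) + 1L
  out <- table |>
    dplyr::mutate(window = win) |>
    dplyr::group_by(.data$window) |>
    dplyr::summarise(
      t_start = min(.data$time),
      t_end = max(.data$time),
      dplyr::across(dplyr::where(is.numeric) & !dplyr::any_of(c("time", "window")),
                    ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
  if ("scr_event" %in% names(table)) {
    recount <- vapply(sort(unique(win)), function(w) {
      e <- table$scr_event[win == w]
      sum(e) / (length(e) / rate) * 60
    }, numeric(1))
    out$NSSCR <- recount
    out$scr_event <- NULL
  }
  out
}
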