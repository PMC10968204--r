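#' Configuration of an end-to-end pipeline run
#'
#' Collects every tunable of the full analysis in one serializable list:
#' simulation settings (when no recorded sessions are supplied), device
#' constants, preprocessing choices, decomposition parameters, spectral
#' configuration, the labeling rule, and the modeling stage.
#'
#' @param n_subjects Number of synthetic subjects to simulate when no
#'   sessions are given.
#' @param design_kwargs Arguments passed to [session_design()] (the seed
#'   is varied per subject).
#' @param device A [device_config()].
#' @param decompose_params A [cvxeda_params()]. The pipeline default
#'   relaxes the solver tolerance to 1e-4: the derived indices are
#'   insensitive to driver perturbations below that level, and
#'   session-scale batches favor throughput (the exact active-set polish
#'   grows cubically with the driver support).
#' @param spectral_cfg A [spectral_config()].
#' @param labeling_rule `"threshold"` or `"strict"`, see
#'   [label_windows()].
#' @param outlier_threshold z-score threshold for the per-window outlier
#'   mask.
#' @param window_s Protocol window length in seconds.
#' @param do_models Run the model-comparison and reverse-model stage.
#' @param model_seed Seed for the modeling stage.
#' @param seed Master seed for simulation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 5, design_kwargs = list(),
                            device = device_config(),
                            decompose_params = cvxeda_params(solver_tolerance = 1e-4),
                            spectral_cfg = spectral_config(),
                            labeling_rule = "threshold",
                            outlier_threshold = 3,
                            window_s = 900,
                            do_models = TRUE, model_seed = 1L, seed = 1L) {
  structure(
    list(n_subjects = n_subjects, design_kwargs = design_kwargs,
         device = device, decompose_params = decompose_params,
         spectral_cfg = spectral_cfg, labeling_rule = labeling_rule,
         outlier_threshold = outlier_threshold, window_s = window_s,
         do_models = do_models, model_seed = as.integer(model_seed),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# z-score outlier masking per protocol window, masked samples interpolated
mask_outliers_windowed <- function(x, window_s, threshold) {
  rate <- signal_rate(x)
  wlen <- round(window_s * rate)
  v <- x$value
  win <- pmin(ceiling(seq_along(v) / wlen), max(1L, floor(length(v) / wlen)))
  for (w in unique(win)) {
    idx <- which(win == w)
    res <- remove_outliers_zscore(v[idx], threshold)
    v[idx] <- res$cleaned
  }
  if (anyNA(v)) {
    v <- stats::approx(seq_along(v)[!is.na(v)], v[!is.na(v)],
                       xout = seq_along(v), rule = 2)$y
  }
  signal_rewrap(x, v, sprintf("outlier_mask:z%g", threshold))
}

process_session <- function(session, config) {
  # the protocol window length travels with the session when simulated
  win_s <- session$truth$design$window_s %||% config$window_s
  config$window_s <- win_s
  sig <- ingest_wristband(session$wristband, config$device)
  sig <- mask_outliers_windowed(sig, config$window_s, config$outlier_threshold)
  sig <- eda_lowpass(sig)
  sig4 <- eda_resample(sig, 4)
  decomp <- cvxeda_decompose(sig4, config$decompose_params)
  stream <- eda_feature_stream(decomp, config$spectral_cfg)
  synced <- sync_features(stream, session$environment)
  synced$subject <- session$reports$subject[1]
  wins <- window_features(synced, window_s = config$window_s)
  wins$subject <- session$reports$subject[1]
  wins <- dplyr::left_join(wins, session$reports,
                           by = c("subject", "window"))
  wins <- label_windows(wins, rule = config$labeling_rule)
  win_lab <- wins[c("window", "label")]
  synced$window <- pmin(
    floor((synced$time - min(synced$time)) / config$window_s) + 1L,
    max(win_lab$window)
  )
  synced <- dplyr::left_join(synced, win_lab, by = "window")
  list(stream = synced, windows = wins, decomposition = decomp)
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a set of sessions and runs every stage in
#' order: ingest, outlier masking, filtering, resampling, tonic/phasic
#' decomposition, 2 Hz feature extraction, environmental synchronization,
#' window aggregation, stress labeling, the screening statistics, and
#' (optionally) the model comparison with Shapley attributions. Results
#' are returned and, when `out_dir` is given, written as plain CSV/JSON
#' report artifacts together with a run log carrying the seeds and stage
#' order.
#'
#' @param config A [pipeline_config()].
#' @param sessions Optional list of sessions (each as returned by
#'   [generate_session()]); simulated from `config` when omitted.
#' @param out_dir Optional report directory.
#' @return A list: `stream` (2 Hz synchronized rows, all subjects),
#'   `windows` (per-window features + labels), `class_summary`,
#'   `correlations` (list of the three correlation tables), `models`
#'   (comparison grid + reverse results, when enabled), `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), sessions = NULL,
                         out_dir = NULL) {
  t_start <- Sys.time()
  if (is.null(sessions)) {
    sessions <- lapply(seq_len(config$n_subjects), function(i) {
      design <- do.call(session_design, utils::modifyList(
        config$design_kwargs, list(seed = config$seed + 1000L * i)
      ))
      generate_session(design, seed = config$seed + i,
                       subject_id = sprintf("S%02d", i))
    })
  }
  processed <- lapply(sessions, process_session, config = config)
  stream <- dplyr::bind_rows(lapply(processed, `[[`, "stream"))
  windows <- dplyr::bind_rows(lapply(processed, `[[`, "windows"))

  class_summary <- feature_class_summary(windows)
  subj_vars <- c("difficulty", "stress", "dominance", "arousal", "valence")
  eda_vars <- intersect(c("MTVSymp", "TVSymp", "dphEDA", "NSSCR", "EDASymp", "SCL"),
                        names(stream))
  high_stream <- dplyr::filter(stream, .data$label == "high")
  high_windows <- dplyr::filter(windows, .data$label == "high")
  correlations <- list(
    subjective = correlation_matrix(windows, subj_vars),
    env_eda_high = correlation_matrix(
      if (nrow(high_stream)) high_stream else stream,
      env_variables(), eda_vars
    ),
    subjective_env_high = correlation_matrix(
      if (nrow(high_windows)) high_windows else windows,
      env_variables(), subj_vars
    )
  )

  models <- NULL
  if (isTRUE(config$do_models)) {
    grid <- model_comparison_grid(windows, seed = config$model_seed)
    rev <- reverse_models(windows, model_spec(seed = config$model_seed))
    models <- list(
      grid = grid$grid,
      ranking = rank_models(grid$results),
      reverse = purrr::map_dfr(rev$evaluations, glance),
      reverse_attributions = purrr::map(rev$attributions, `[[`, "summary")
    )
  }

  log <- list(
    package_version = as.character(utils::packageVersion("microeda")),
    seed = config$seed, model_seed = config$model_seed,
    n_subjects = length(sessions),
    stages = c("ingest", "outlier_mask", "lowpass", "resample", "decompose",
               "features", "sync", "window", "label", "stats",
               if (isTRUE(config$do_models)) "models"),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )

  result <- list(stream = stream, windows = windows,
                 class_summary = class_summary,
                 correlations = correlations, models = models, log = log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(stream, file.path(out_dir, "features_2hz.csv"))
    readr::write_csv(windows, file.path(out_dir, "windows.csv"))
    readr::write_csv(class_summary, file.path(out_dir, "class_summary.csv"))
    readr::write_csv(correlations$subjective,
                     file.path(out_dir, "corr_subjective.csv"))
    readr::write_csv(correlations$env_eda_high,
                     file.path(out_dir, "corr_env_eda_high.csv"))
    readr::write_csv(correlations$subjective_env_high,
                     file.path(out_dir, "corr_subjective_env_high.csv"))
    if (!is.null(models)) {
      readr::write_csv(models$grid, file.path(out_dir, "model_grid.csv"))
      readr::write_csv(models$ranking, file.path(out_dir, "model_ranking.csv"))
      readr::write_csv(models$reverse, file.path(out_dir, "reverse_models.csv"))
      for (tg in names(models$reverse_attributions)) {
        readr::write_csv(models$reverse_attributions[[tg]],
                         file.path(out_dir, sprintf("attribution_%s.csv", tg)))
      }
    }
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}

# align device_b to device_a by the lag maximizing cross-correlation
estimate_lag <- function(a, b, rate, max_lag_s = 5) {
  ml <- round(max_lag_s * rate)
  cc <- stats::ccf(a, b, lag.max = ml, plot = FALSE)
  as.numeric(cc$lag[which.max(cc$acf)])
}

#' Cross-device validation of two EDA recordings
#'
#' Runs both streams through the comparison pipeline — resampling to
#' 4 Hz, 1.5 Hz low-pass, min-max normalization, light moving-average
#' smoothing, lag alignment by cross-correlation, and tonic/phasic
#' decomposition — then reports the Spearman correlation of the raw
#' traces and of each component.
#'
#' @param rec_a,rec_b Two [eda_signal()]s covering the same period.
#' @param smooth_s Moving-average window in seconds (kept short so
#'   smoothing does not inflate the agreement).
#' @param align Estimate and remove the inter-device lag.
#' @param decompose Also decompose and compare tonic/phasic (slower).
#' @param params A [cvxeda_params()] for the component comparison.
#' @return A one-row tibble: `rho_raw`, `rho_tonic`, `rho_phasic`
#'   (Spearman; the latter two `NA` when `decompose = FALSE`),
#'   `pearson_raw` (for comparison against the linear attenuation
#'   formula, which is a Pearson statement), `lag_s` (estimated lag).
#' @export
validate_devices <- function(rec_a, rec_b, smooth_s = 0.25, align = TRUE,
                             decompose = TRUE, params = cvxeda_params()) {
  prep <- function(x) {
    x <- eda_resample(x, 4)
    x <- eda_lowpass(x)
    x <- eda_normalize(x)
    eda_moving_average(x, smooth_s)
  }
  a <- prep(rec_a)
  b <- prep(rec_b)
  n <- min(nrow(a), nrow(b))
  va <- a$value[seq_len(n)]
  vb <- b$value[seq_len(n)]
  lag <- 0
  if (align) {
    lag <- estimate_lag(va, vb, 4)
    if (lag > 0) {
      va <- va[-seq_len(lag)]
      vb <- vb[seq_len(length(va))]
    } else if (lag < 0) {
      vb <- vb[-seq_len(-lag)]
      va <- va[seq_len(length(vb))]
    }
  }
  rho_raw <- spearman_rho(va, vb)
  rho_tonic <- NA_real_
  rho_phasic <- NA_real_
  if (decompose) {
    da <- cvxeda_decompose(eda_signal(va, 4), params)
    db <- cvxeda_decompose(eda_signal(vb, 4), params)
    rho_tonic <- spearman_rho(da$tonic, db$tonic)
    rho_phasic <- tryCatch(spearman_rho(da$phasic, db$phasic),
                           error = function(e) NA_real_)
  }
  # positive lag_s: rec_b lags behind rec_a
  tibble::tibble(rho_raw = rho_raw, rho_tonic = rho_tonic,
                 rho_phasic = rho_phasic,
                 pearson_raw = stats::cor(va, vb), lag_s = -lag / 4)
}
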