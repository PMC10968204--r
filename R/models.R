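#' Specification of a regression model family
#'
#' @param family `"random_forest"` (ranger), `"support_vector"` (e1071
#'   radial-kernel epsilon-SVR on standardized inputs) or `"linear"`
#'   (ordinary least squares).
#' @param hyperparameters Named list overriding the family defaults
#'   (random forest: `num_trees = 500`; SVM: `cost = 1, epsilon = 0.1`).
#' @param seed Integer seed recorded with the spec and used for every
#'   stochastic step (forest growth, split shuffling, Shapley sampling).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family = c("random_forest", "support_vector", "linear"),
                       hyperparameters = list(), seed = 1L) {
  family <- match.arg(family)
  defaults <- switch(family,
    random_forest = list(num_trees = 500),
    support_vector = list(cost = 1, epsilon = 0.1),
    linear = list()
  )
  structure(
    list(family = family,
         hyperparameters = utils::modifyList(defaults, hyperparameters),
         seed = as.integer(seed)),
    class = "model_spec"
  )
}

#' Fit one regression model
#'
#' @param spec A [model_spec()].
#' @param data Training data (one row per observation).
#' @param target Response column name.
#' @param features Predictor column names.
#' @return An `eda_model` wrapper with a [predict()] method.
#' @export
fit_model <- function(spec, data, target, features) {
  df <- data[c(target, features)]
  names(df)[1] <- ".target"
  fit <- switch(spec$family,
    random_forest = ranger::ranger(
      dependent.variable.name = ".target", data = df,
      num.trees = spec$hyperparameters$num_trees,
      seed = spec$seed, num.threads = 1
    ),
    support_vector = e1071::svm(
      .target ~ ., data = df, kernel = "radial", scale = TRUE,
      cost = spec$hyperparameters$cost,
      epsilon = spec$hyperparameters$epsilon
    ),
    linear = stats::lm(.target ~ ., data = df)
  )
  structure(list(fit = fit, spec = spec, features = features, target = target),
            class = "eda_model")
}

#' @export
predict.eda_model <- function(object, newdata, ...) {
  nd <- newdata[object$features]
  switch(object$spec$family,
    random_forest = stats::predict(object$fit, data = nd,
                                   num.threads = 1)$predictions,
    support_vector = as.numeric(stats::predict(object$fit, newdata = nd)),
    linear = as.numeric(stats::predict(object$fit, newdata = nd))
  )
}

r_squared <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / sst
}

#' Evaluate a model family on a feature table
#'
#' Cross-validated held-out R-squared under one of two schemes:
#' leave-one-subject-out (`"loso"`; one fold per subject, the model never
#' sees the held-out subject's rows) or repeated seeded 70/30 splits
#' (`"split_70_30"`, mean over `n_repeats` shuffles). Negative R-squared
#' values are reported as-is.
#'
#' @param table Feature table (one row per observation).
#' @param target Name of the response column.
#' @param features Character vector of predictor column names.
#' @param spec A [model_spec()].
#' @param scheme `"loso"` or `"split_70_30"`.
#' @param subject_col Column naming the subject (required for loso).
#' @param n_repeats Repeats of the 70/30 split.
#' @param label_filter Optional label value(s); rows are restricted to
#'   those whose `label` column matches (e.g. `"high"` to model
#'   high-stress windows only).
#' @return An `eda_eval` object; see [tidy.eda_eval()] and
#'   [glance.eda_eval()].
#' @export
evaluate_model <- function(table, target, features,
                           spec = model_spec(), scheme = c("loso", "split_70_30"),
                           subject_col = "subject", n_repeats = 5,
                           label_filter = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(label_filter)) {
    table <- dplyr::filter(table, .data$label %in% label_filter)
  }
  table <- tidyr::drop_na(table, dplyr::all_of(c(target, features)))
  if (stats::var(table[[target]]) == 0) {
    rlang::abort("degenerate constant target")
  }
  if (scheme == "loso") {
    if (!subject_col %in% names(table)) {
      rlang::abort(sprintf("loso needs a `%s` column", subject_col))
    }
    subjects <- unique(table[[subject_col]])
    if (length(subjects) < 2) rlang::abort("loso needs at least 2 subjects")
    folds <- purrr::map_dfr(subjects, function(s) {
      held <- table[[subject_col]] == s
      fit <- fit_model(spec, table[!held, , drop = FALSE], target, features)
      pred <- predict(fit, table[held, , drop = FALSE])
      tibble::tibble(
        fold = as.character(s),
        n_train = sum(!held), n_test = sum(held),
        r2 = r_squared(table[[target]][held], pred)
      )
    })
  } else {
    folds <- purrr::map_dfr(seq_len(n_repeats), function(rep) {
      set.seed(spec$seed + rep - 1L)
      n <- nrow(table)
      train_idx <- sample.int(n, size = floor(0.7 * n))
      fit <- fit_model(spec, table[train_idx, , drop = FALSE], target, features)
      test <- setdiff(seq_len(n), train_idx)
      pred <- predict(fit, table[test, , drop = FALSE])
      tibble::tibble(
        fold = sprintf("split%02d", rep),
        n_train = length(train_idx), n_test = length(test),
        r2 = r_squared(table[[target]][test], pred)
      )
    })
  }
  final_fit <- fit_model(spec, table, target, features)
  structure(
    list(target = target, family = spec$family, scheme = scheme,
         folds = folds, mean_r2 = mean(folds$r2, na.rm = TRUE),
         spec = spec, model = final_fit, n = nrow(table)),
    class = "eda_eval"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-fold results of a model evaluation
#' @param x An `eda_eval`.
#' @param ... Unused.
#' @return A tibble with one row per fold: `fold`, `n_train`, `n_test`,
#'   `r2`, plus `target`, `family`, `scheme`.
#' @export
tidy.eda_eval <- function(x, ...) {
  dplyr::mutate(x$folds, target = x$target, family = x$family,
                scheme = x$scheme)
}

#' One-line summary of a model evaluation
#' @param x An `eda_eval`.
#' @param ... Unused.
#' @return A one-row tibble: `target`, `family`, `scheme`, `mean_r2`,
#'   `n_folds`, `n`.
#' @export
glance.eda_eval <- function(x, ...) {
  tibble::tibble(
    target = x$target, family = x$family, scheme = x$scheme,
    mean_r2 = x$mean_r2, n_folds = nrow(x$folds), n = x$n
  )
}

#' @export
print.eda_eval <- function(x, ...) {
  cat(sprintf("<eda_eval> %s ~ %s [%s]: mean held-out R2 = %.3f (%d folds)\n",
              x$target, x$family, x$scheme, x$mean_r2, nrow(x$folds)))
  invisible(x)
}

#' Rank model families by mean held-out R-squared
#'
#' @param results A list of `eda_eval` objects (possibly over several
#'   targets).
#' @return A tibble ordered best-first: `family`, `mean_r2` (averaged
#'   across the supplied results), `n_results`; ties broken
#'   alphabetically by family.
#' @export
rank_models <- function(results) {
  if (inherits(results, "eda_eval")) results <- list(results)
  tab <- purrr::map_dfr(results, glance)
  tab |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(mean_r2 = mean(.data$mean_r2), n_results = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_r2), .data$family)
}

#' Shapley-value attribution summary
#'
#' Per-instance feature attributions by antithetic permutation sampling
#' over a fixed background sample: for each sampled (permutation,
#' background row) pair the marginal contributions telescope, so the
#' attributions of every instance sum exactly to its prediction minus the
#' baseline (the mean prediction over the sampled background rows) —
#' local accuracy holds to numerical precision for every model family.
#'
#' @param model An `eda_model` (from [evaluate_model()]`$model` or
#'   [fit_model()]) or an `eda_eval`.
#' @param table Rows to explain (instances).
#' @param n_perm Number of sampled permutations per instance.
#' @param background Background sample size drawn from `table` (or a
#'   tibble of background rows).
#' @param seed Seed for permutation and background sampling.
#' @return An `eda_shapley` object: `values` (instances x features
#'   tibble), `baseline`, `prediction` per instance, and `summary`
#'   (features ordered by mean absolute attribution).
#' @export
shapley_summary <- function(model, table, n_perm = 64, background = 32,
                            seed = NULL) {
  if (inherits(model, "eda_eval")) model <- model$model
  if (!inherits(model, "eda_model")) rlang::abort("need a fitted eda_model")
  feats <- model$features
  d <- length(feats)
  X <- as.data.frame(table[feats])
  if (is.data.frame(background)) {
    bg <- as.data.frame(background[feats])
  } else {
    set.seed(seed %||% model$spec$seed)
    bg <- X[sample.int(nrow(X), size = min(background, nrow(X))), , drop = FALSE]
  }
  set.seed(seed %||% model$spec$seed)
  perms <- lapply(seq_len(n_perm), function(i) sample.int(d))
  bg_idx <- sample.int(nrow(bg), n_perm, replace = TRUE)

  n_inst <- nrow(X)
  phi <- matrix(0, n_inst, d, dimnames = list(NULL, feats))
  baseline_acc <- numeric(n_inst)
  # batch all hybrid rows of one permutation across instances
  for (k in seq_len(n_perm)) {
    pi_k <- perms[[k]]
    z <- bg[bg_idx[k], , drop = FALSE]
    hybrid <- X
    for (j in seq_len(d)) hybrid[[j]] <- rep(z[[j]], n_inst)
    prev <- predict(model, hybrid)
    baseline_acc <- baseline_acc + prev
    for (j in pi_k) {
      hybrid[[j]] <- X[[j]]
      cur <- predict(model, hybrid)
      phi[, feats[j]] <- phi[, feats[j]] + (cur - prev)
      prev <- cur
    }
  }
  phi <- phi / n_perm
  baseline <- baseline_acc / n_perm
  pred <- predict(model, X)
  summary_tab <- tibble::tibble(
    feature = feats,
    mean_abs_attribution = colMeans(abs(phi))
  ) |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_attribution)) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(
    list(values = tibble::as_tibble(as.data.frame(phi)),
         baseline = baseline, prediction = pred,
         feature_values = tibble::as_tibble(X),
         summary = summary_tab, target = model$target,
         family = model$spec$family, n_perm = n_perm),
    class = "eda_shapley"
  )
}

#' @export
print.eda_shapley <- function(x, ...) {
  cat(sprintf("<eda_shapley> %s (%s), %d instances, %d permutations\n",
              x$target, x$family, nrow(x$values), x$n_perm))
  print(x$summary)
  invisible(x)
}

#' Attribution beeswarm-style summary plot
#' @param object An `eda_shapley`.
#' @param ... Unused.
#' @return A ggplot object: per-instance attributions by feature, colored
#'   by the (min-max scaled) feature value, features ordered by global
#'   importance.
#' @export
autoplot.eda_shapley <- function(object, ...) {
  vals <- object$values |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    tidyr::pivot_longer(-".row", names_to = "feature",
                        values_to = "attribution")
  fvals <- object$feature_values |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    tidyr::pivot_longer(-".row", names_to = "feature", values_to = "fval") |>
    dplyr::group_by(.data$feature) |>
    dplyr::mutate(fval = if (diff(range(.data$fval)) > 0) {
      (.data$fval - min(.data$fval)) / diff(range(.data$fval))
    } else {
      0.5
    }) |>
    dplyr::ungroup()
  df <- dplyr::left_join(vals, fvals, by = c(".row", "feature"))
  df$feature <- factor(df$feature, levels = rev(object$summary$feature))
  ggplot2::ggplot(df, ggplot2::aes(.data$attribution, .data$feature,
                                   color = .data$fval)) +
    ggplot2::geom_jitter(height = 0.2, size = 0.7, alpha = 0.7) +
    ggplot2::scale_color_gradient(low = "#3b4cc0", high = "#b40426",
                                  name = "feature value\n(scaled)") +
    ggplot2::labs(x = "Shapley attribution", y = NULL,
                  title = sprintf("%s (%s)", object$target, object$family))
}

#' Reverse-direction models: EDA features predict the environment
#'
#' Fits and evaluates models with the six EDA indices as inputs and the
#' four environmental targets (temperature, CO2, humidity, infrared) as
#' outputs, mirroring the forward analysis, with a Shapley summary per
#' target.
#'
#' @param table Feature table containing the EDA indices and
#'   environmental columns.
#' @param spec A [model_spec()].
#' @param scheme Evaluation scheme, see [evaluate_model()].
#' @param targets Environmental target columns.
#' @param features EDA feature columns used as inputs.
#' @param ... Passed to [evaluate_model()].
#' @return A list with `evaluations` (named list of `eda_eval`) and
#'   `attributions` (named list of `eda_shapley`).
#' @export
reverse_models <- function(table, spec = model_spec(),
                           scheme = "split_70_30",
                           targets = c("Temperature", "CO2", "Humid", "IR"),
                           features = c("SCL", "NSSCR", "TVSymp", "MTVSymp",
                                        "EDASymp", "dphEDA"),
                           ...) {
  targets <- intersect(targets, names(table))
  evaluations <- purrr::map(targets, function(tg) {
    evaluate_model(table, tg, features, spec = spec, scheme = scheme, ...)
  })
  names(evaluations) <- targets
  attributions <- purrr::map(evaluations, function(ev) {
    shapley_summary(ev$model, tidyr::drop_na(
      table, dplyr::all_of(c(ev$target, features))
    ))
  })
  list(evaluations = evaluations, attributions = attributions)
}

#' Model-comparison grid over EDA feature targets
#'
#' Evaluates every family under both schemes for each EDA feature target,
#' producing the standard comparison grid (rows: scheme x family;
#' columns: targets) of mean cross-validated R-squared.
#'
#' @param table Feature table with environmental inputs and EDA targets.
#' @param targets EDA feature columns to predict.
#' @param features Environmental predictor columns.
#' @param families Model families to compare.
#' @param schemes Evaluation schemes.
#' @param seed Seed stored in each [model_spec()].
#' @param ... Passed to [evaluate_model()].
#' @return A list: `results` (list of `eda_eval`) and `grid` (tibble,
#'   one row per scheme x family, one column per target).
#' @export
model_comparison_grid <- function(table,
                                  targets = c("MTVSymp", "TVSymp", "dphEDA",
                                              "NSSCR", "EDASymp", "SCL"),
                                  features = env_variables(),
                                  families = c("random_forest",
                                               "support_vector", "linear"),
                                  schemes = c("loso", "split_70_30"),
                                  seed = 1L, ...) {
  targets <- intersect(targets, names(table))
  features <- intersect(features, names(table))
  combos <- tidyr::expand_grid(scheme = schemes, family = families,
                               target = targets)
  results <- purrr::pmap(combos, function(scheme, family, target) {
    evaluate_model(table, target, features,
                   spec = model_spec(family, seed = seed),
                   scheme = scheme, ...)
  })
  grid <- purrr::map_dfr(results, glance) |>
    tidyr::pivot_wider(id_cols = c("scheme", "family"),
                       names_from = "target", values_from = "mean_r2")
  list(results = results, grid = grid)
}
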