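#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic of `x` against a normal distribution with mean
#' and standard deviation estimated from `x` itself. Because the reference
#' parameters are estimated, the p-value is approximate (no Lilliefors
#' correction); the statistic is used descriptively to gate the choice of
#' rank-based association measures.
#'
#' @param x Numeric vector, at least 8 observations, non-constant.
#' @return A one-row tibble: `statistic` (D), `p_value` (approximate),
#'   `n`, `method`.
#' @export
ks_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 8) rlang::abort("need at least 8 observations")
  s <- stats::sd(x)
  if (s == 0) rlang::abort("constant series: normality test undefined")
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean = mean(x), sd = s))
  tibble::tibble(
    statistic = unname(kt$statistic),
    p_value = kt$p.value,
    n = length(x),
    method = "one-sample KS vs fitted normal (approximate p)"
  )
}

#' Fisher's ratio of class separability
#'
#' `(mean(high) - mean(low))^2 / (var(high) + var(low))` with unbiased
#' (n-1) variances. Invariant to adding a common constant to both groups.
#'
#' @param x_high,x_low Numeric vectors for the two classes (n >= 2 each).
#' @return The ratio (scalar).
#' @examples
#' fishers_ratio(c(0.5, 1.5), c(-0.5, 0.5)) # means 1, 0; vars 0.5 each -> 1
#' @export
fishers_ratio <- function(x_high, x_low) {
  if (length(x_high) < 2 || length(x_low) < 2) {
    rlang::abort("both groups need at least 2 observations")
  }
  v <- stats::var(x_high) + stats::var(x_low)
  if (v == 0) rlang::abort("both group variances are zero")
  (mean(x_high) - mean(x_low))^2 / v
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties share their mean
#' rank) — the definition itself, kept explicit so rank handling is
#' auditable against a brute-force oracle.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, neither constant.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) rlang::abort("need at least 3 complete pairs")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    rlang::abort("constant input: rank correlation undefined")
  }
  stats::cor(rx, ry)
}

#' Per-feature class summary (high vs low stress)
#'
#' For each feature column: mean and SD within each label class, plus the
#' mean and max of Fisher's ratio computed per subject (falling back to
#' the pooled ratio when no `subject` column is present).
#'
#' @param table A labeled feature table (must contain `label`; optionally
#'   `subject`).
#' @param features Character vector of feature column names; defaults to
#'   the six EDA indices present in the table.
#' @return A tibble, one row per feature: `feature`, `mean_high`,
#'   `sd_high`, `mean_low`, `sd_low`, `fisher_mean`, `fisher_max`, class
#'   sample sizes.
#' @export
feature_class_summary <- function(table, features = NULL) {
  stopifnot("label" %in% names(table))
  if (is.null(features)) {
    features <- intersect(
      c("MTVSymp", "TVSymp", "dphEDA", "NSSCR", "EDASymp", "SCL"),
      names(table)
    )
  }
  labeled <- dplyr::filter(table, .data$label %in% c("high", "low"))
  if (!nrow(labeled)) {
    rlang::warn("no labeled rows: returning empty summary")
    return(tibble::tibble(feature = character()))
  }
  groups <- if ("subject" %in% names(labeled)) {
    split(labeled, labeled$subject)
  } else {
    list(labeled)
  }
  purrr::map_dfr(features, function(f) {
    hi <- labeled[[f]][labeled$label == "high"]
    lo <- labeled[[f]][labeled$label == "low"]
    fr <- purrr::map_dbl(groups, function(g) {
      gh <- g[[f]][g$label == "high"]
      gl <- g[[f]][g$label == "low"]
      if (length(gh) < 2 || length(gl) < 2) return(NA_real_)
      v <- stats::var(gh) + stats::var(gl)
      if (!is.finite(v) || v == 0) return(NA_real_)
      (mean(gh) - mean(gl))^2 / v
    })
    fr <- fr[is.finite(fr)]
    tibble::tibble(
      feature = f,
      mean_high = mean(hi, na.rm = TRUE), sd_high = stats::sd(hi),
      mean_low = mean(lo, na.rm = TRUE), sd_low = stats::sd(lo),
      fisher_mean = if (length(fr)) mean(fr) else NA_real_,
      fisher_max = if (length(fr)) max(fr) else NA_real_,
      n_high = length(hi), n_low = length(lo)
    )
  })
}

#' Spearman correlation matrix between two variable sets
#'
#' Rows are `row_vars`, columns `col_vars`; the matrix layout follows the
#' declared variable orders. Self-correlations are exactly 1.
#'
#' @param table A feature table.
#' @param row_vars,col_vars Character vectors of column names.
#' @return A tibble with a `variable` column (rows) and one column per
#'   `col_vars` entry holding Spearman rho.
#' @export
correlation_matrix <- function(table, row_vars, col_vars = row_vars) {
  stopifnot(all(row_vars %in% names(table)), all(col_vars %in% names(table)))
  out <- purrr::map_dfr(row_vars, function(rv) {
    vals <- purrr::map_dbl(col_vars, function(cv) {
      if (identical(rv, cv)) return(1)
      tryCatch(spearman_rho(table[[rv]], table[[cv]]),
               error = function(e) NA_real_)
    })
    tibble::as_tibble(stats::setNames(as.list(vals), col_vars)) |>
      dplyr::mutate(variable = rv, .before = 1)
  })
  out
}
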