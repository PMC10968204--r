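#' Label experiment windows from self-reports
#'
#' The operational rule: a window is **high** stress when task difficulty
#' is rated at least 7 (on 1-10) and stress at least 5 (on 1-7); **low**
#' when both difficulty and stress are at most 2, or the window is a
#' baseline window; otherwise **unlabeled**. A strict-inequality variant
#' (difficulty > 6 and stress > 4 for high; both < 3 for low) is available
#' as `rule = "strict"`.
#'
#' @param reports A tibble with columns `difficulty` (integer 1-10),
#'   `stress` (integer 1-7) and optionally `is_baseline` (logical); any
#'   other columns (subject, window, SAM ratings, raw questionnaire
#'   items) are carried through.
#' @param rule `"threshold"` (default, >=7 / >=5 / <=2) or `"strict"`
#'   (>6 / >4 / <3).
#' @return The input with a `label` factor column
#'   (`high`/`low`/`unlabeled`).
#' @examples
#' label_windows(tibble::tibble(difficulty = c(8, 2, 5), stress = c(6, 2, 4)))
#' @export
label_windows <- function(reports, rule = c("threshold", "strict")) {
  rule <- match.arg(rule)
  stopifnot(all(c("difficulty", "stress") %in% names(reports)))
  d <- reports$difficulty
  s <- reports$stress
  if (any(d < 1 | d > 10, na.rm = TRUE)) {
    rlang::abort("`difficulty` out of range 1-10")
  }
  if (any(s < 1 | s > 7, na.rm = TRUE)) {
    rlang::abort("`stress` out of range 1-7")
  }
  base <- if ("is_baseline" %in% names(reports)) {
    isTRUE_v(reports$is_baseline)
  } else {
    rep(FALSE, nrow(reports))
  }
  if (rule == "threshold") {
    high <- d >= 7 & s >= 5
    low <- (d <= 2 & s <= 2) | base
  } else {
    high <- d > 6 & s > 4
    low <- (d < 3 & s < 3) | base
  }
  lab <- dplyr::case_when(
    high & !base ~ "high",
    low ~ "low",
    .default = "unlabeled"
  )
  dplyr::mutate(reports,
                label = factor(lab, levels = c("high", "low", "unlabeled")))
}

isTRUE_v <- function(x) !is.na(x) & as.logical(x)

#' Label a single window report
#'
#' Scalar convenience wrapper around [label_windows()].
#'
#' @param difficulty Task difficulty, integer 1-10.
#' @param stress Stress rating, integer 1-7.
#' @param is_baseline Whether the window is a baseline/break window.
#' @param rule Labeling rule, see [label_windows()].
#' @return `"high"`, `"low"` or `"unlabeled"`.
#' @export
label_window <- function(difficulty, stress, is_baseline = FALSE,
                         rule = c("threshold", "strict")) {
  out <- label_windows(
    tibble::tibble(difficulty = difficulty, stress = stress,
                   is_baseline = is_baseline),
    rule = match.arg(rule)
  )
  as.character(out$label)
}
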