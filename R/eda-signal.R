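#' Uniformly sampled EDA signal
#'
#' The central container of the package: a tibble with columns `time`
#' (seconds from session start) and `value` (skin conductance in
#' microsiemens, or normalized units after [eda_normalize()]), carrying the
#' sampling rate and an ordered provenance of the transforms applied to it.
#' All preprocessing verbs take an `eda_signal` first and return one, so
#' calls chain with the pipe.
#'
#' @param values Numeric vector of samples. All values must be finite.
#' @param rate Sampling rate in Hz (> 0).
#' @param start_time Time of the first sample in seconds (default 0).
#' @param units Unit label, `"uS"` for microsiemens or `"n.u."` after
#'   normalization.
#' @param provenance Character vector of transform labels already applied.
#'
#' @return A tibble of class `eda_signal` with columns `time` and `value`.
#' @examples
#' s <- eda_signal(2 + 0.1 * sin(2 * pi * 0.1 * seq(0, 60, by = 0.25)), rate = 4)
#' s
#' @export
eda_signal <- function(values, rate, start_time = 0, units = "uS",
                       provenance = character()) {
  stopifnot(is.numeric(values), length(values) >= 1)
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    rlang::abort("`rate` must be a single positive number (Hz).")
  }
  if (!all(is.finite(values))) {
    rlang::abort("`values` must be finite; mask or interpolate gaps first.")
  }
  out <- tibble::tibble(
    time = start_time + (seq_along(values) - 1) / rate,
    value = as.numeric(values)
  )
  structure(out,
    class = c("eda_signal", class(out)),
    rate = rate, units = units, provenance = provenance
  )
}

#' @export
print.eda_signal <- function(x, ...) {
  cat(sprintf(
    "<eda_signal> %d samples @ %g Hz (%.1f s), units: %s\n",
    nrow(x), signal_rate(x), nrow(x) / signal_rate(x), attr(x, "units")
  ))
  prov <- attr(x, "provenance")
  if (length(prov)) cat("  provenance:", paste(prov, collapse = " -> "), "\n")
  NextMethod()
}

#' Sampling rate of an EDA signal
#' @param x An [eda_signal()].
#' @return Sampling rate in Hz.
#' @export
signal_rate <- function(x) {
  r <- attr(x, "rate")
  if (is.null(r)) rlang::abort("not an `eda_signal`: missing rate attribute")
  r
}

#' Provenance of an EDA signal
#' @param x An [eda_signal()].
#' @return Character vector of transform labels, oldest first.
#' @export
signal_provenance <- function(x) attr(x, "provenance") %||% character()

# rebuild a signal from transformed values, appending one provenance entry
signal_rewrap <- function(x, values, step, rate = signal_rate(x),
                          units = attr(x, "units")) {
  eda_signal(values, rate,
    start_time = x$time[1], units = units,
    provenance = c(signal_provenance(x), step)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an EDA signal trace
#' @param object An [eda_signal()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eda_signal <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time [s]",
      y = sprintf("conductance [%s]", attr(object, "units"))
    )
}

#' @importFrom rlang %||% .data
NULL
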