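#' Device configuration for the exosomatic EDA wristband
#'
#' Constants of the DIY measurement chain: a voltage divider driven at
#' `supply_voltage` through a `reference_resistance`, read by an ADC at
#' `adc_sampling_rate`, with dry Ag/AgCl electrodes of the given diameter
#' passing `electrode_current` through the skin. Defaults are the published
#' build: 3.3 V supply, 826 kOhm reference, 10 Hz sampling, 0.80 cm
#' electrodes at 1.50 uA.
#'
#' @param supply_voltage Supply voltage Vdd in volts.
#' @param reference_resistance Reference resistor in ohms.
#' @param adc_sampling_rate ADC sampling rate in Hz.
#' @param electrode_diameter Electrode diameter in cm.
#' @param electrode_current Current through the skin in uA.
#' @return A list of class `device_config`.
#' @examples
#' device_config()
#' @export
device_config <- function(supply_voltage = 3.3,
                          reference_resistance = 826000,
                          adc_sampling_rate = 10,
                          electrode_diameter = 0.80,
                          electrode_current = 1.50) {
  stopifnot(
    supply_voltage > 0, reference_resistance > 0,
    adc_sampling_rate > 0, electrode_diameter > 0, electrode_current >= 0
  )
  structure(
    list(
      supply_voltage = supply_voltage,
      reference_resistance = reference_resistance,
      adc_sampling_rate = adc_sampling_rate,
      electrode_diameter = electrode_diameter,
      electrode_current = electrode_current
    ),
    class = "device_config"
  )
}

#' @export
print.device_config <- function(x, ...) {
  cat(sprintf(
    "<device_config> Vdd=%g V, Rref=%g Ohm, %g Hz, electrode %g cm @ %g uA\n",
    x$supply_voltage, x$reference_resistance, x$adc_sampling_rate,
    x$electrode_diameter, x$electrode_current
  ))
  invisible(x)
}

#' Convert divider output voltage to skin resistance
#'
#' The wristband measures skin resistance through a symmetric voltage
#' divider, so `Rskin = (1 - 2 * Vout / Vdd) * Rref`. Readings at or above
#' `Vdd / 2` would give zero or negative resistance and are non-physical;
#' they produce `NA` with a warning (the ingest path masks them instead of
#' clipping).
#'
#' @param vout Output voltage in volts (vectorized).
#' @param device A [device_config()].
#' @return Skin resistance in ohms; `NA` where the reading is invalid.
#' @examples
#' voltage_to_resistance(0.825, device_config()) # 413000
#' @export
voltage_to_resistance <- function(vout, device = device_config()) {
  vdd <- device$supply_voltage
  if (any(vout < 0, na.rm = TRUE)) {
    rlang::abort("negative `vout`: invalid sample(s) below 0 V")
  }
  bad <- !is.na(vout) & vout >= vdd / 2
  r <- (1 - 2 * vout / vdd) * device$reference_resistance
  if (any(bad)) {
    rlang::warn(sprintf(
      "%d sample(s) at or above Vdd/2 give non-positive resistance; set to NA",
      sum(bad)
    ))
    r[bad] <- NA_real_
  }
  r
}

#' Convert skin resistance to conductance
#'
#' `Gskin [uS] = 1e6 / Rskin [Ohm]`.
#'
#' @param rskin Skin resistance in ohms (vectorized).
#' @return Conductance in microsiemens.
#' @examples
#' resistance_to_conductance(1e6) # 1 uS
#' @export
resistance_to_conductance <- function(rskin) {
  if (any(rskin <= 0, na.rm = TRUE)) {
    rlang::abort("`rskin` must be strictly positive")
  }
  1e6 / rskin
}

#' Convert conductance back to skin resistance
#' @param gskin Conductance in microsiemens.
#' @return Resistance in ohms.
#' @export
conductance_to_resistance <- function(gskin) {
  if (any(gskin <= 0, na.rm = TRUE)) {
    rlang::abort("`gskin` must be strictly positive")
  }
  1e6 / gskin
}

# inverse of voltage_to_resistance; used by the synthetic generator
resistance_to_voltage <- function(rskin, device = device_config()) {
  (1 - rskin / device$reference_resistance) * device$supply_voltage / 2
}

#' Electrode geometry and current density
#'
#' Contact area of a circular electrode and the resulting current density,
#' for comparison against the 10 uA/cm^2 safety recommendation.
#'
#' @param device A [device_config()].
#' @return A tibble with columns `area_cm2` and `current_density_uA_cm2`.
#' @examples
#' electrode_geometry(device_config()) # 0.50 cm^2, ~2.98 uA/cm^2
#' @export
electrode_geometry <- function(device = device_config()) {
  area <- pi * (device$electrode_diameter / 2)^2
  tibble::tibble(
    area_cm2 = area,
    current_density_uA_cm2 = device$electrode_current / area
  )
}

#' Read a wristband voltage log
#'
#' Expects columns `timestamp_iso8601` and either `vout_volts` or a raw
#' 16-bit `adc_code` (converted as `code * 2.048 / 32768`, the ADS1115
#' +/-2.048 V full-scale setting).
#'
#' @param path CSV file path.
#' @return A tibble with columns `time` (seconds from first sample) and
#'   `vout` (volts), plus `timestamp` (POSIXct).
#' @export
read_wristband_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"timestamp_iso8601" %in% names(df)) {
    rlang::abort(sprintf("%s: missing `timestamp_iso8601` column", path))
  }
  ts <- as.POSIXct(df$timestamp_iso8601, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  vout <- if ("vout_volts" %in% names(df)) {
    df$vout_volts
  } else if ("adc_code" %in% names(df)) {
    df$adc_code * 2.048 / 32768
  } else {
    rlang::abort(sprintf("%s: need `vout_volts` or `adc_code`", path))
  }
  if (is.unsorted(as.numeric(ts))) {
    rlang::abort(sprintf("%s: timestamps must be non-decreasing", path))
  }
  tibble::tibble(
    timestamp = ts,
    time = as.numeric(ts) - as.numeric(ts[1]),
    vout = vout
  )
}

#' Read an environmental sensor log
#'
#' Expects `timestamp_iso8601` plus the twelve microclimate columns
#' `Sound, Visible, IR, UV, Temperature, Humid, Pressure, CO2, PM1, PM2.5,
#' PM10, Wind` (a.u. x4, degC, %RH, hPa, ppm, ug/m^3 x3, m/s).
#'
#' @param path CSV file path.
#' @return A tibble with a `time` column (seconds from first sample) and
#'   the twelve environmental columns.
#' @export
read_environment_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("timestamp_iso8601", env_variables()), names(df))
  if (length(missing)) {
    rlang::abort(sprintf(
      "%s: missing environment column(s): %s", path,
      paste(missing, collapse = ", ")
    ))
  }
  ts <- as.POSIXct(df$timestamp_iso8601, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  dplyr::bind_cols(
    tibble::tibble(time = as.numeric(ts) - as.numeric(ts[1])),
    df[env_variables()]
  )
}

#' Names of the twelve environmental variables
#' @return Character vector in the canonical column order.
#' @export
env_variables <- function() {
  c("Sound", "Visible", "IR", "UV", "Temperature", "Humid",
    "Pressure", "CO2", "PM1", "PM2.5", "PM10", "Wind")
}

#' Ingest a wristband voltage log into a conductance signal
#'
#' Converts output voltage to conductance via the divider equations,
#' masking non-physical readings (`vout >= Vdd/2` or `vout < 0` treated as
#' invalid) and linearly interpolating masked gaps up to `max_gap_s`
#' seconds; longer gaps raise an error since downstream filters require a
#' complete uniform series. Slightly irregular timestamps are accepted and
#' snapped to the nominal rate.
#'
#' @param log A tibble from [read_wristband_csv()], or any tibble with
#'   `time` and `vout` columns.
#' @param device A [device_config()].
#' @param max_gap_s Longest invalid-data gap to bridge by interpolation.
#' @return An [eda_signal()] in microsiemens at the device rate.
#' @export
ingest_wristband <- function(log, device = device_config(), max_gap_s = 1) {
  stopifnot(all(c("time", "vout") %in% names(log)))
  vout <- log$vout
  vdd <- device$supply_voltage
  valid <- !is.na(vout) & vout >= 0 & vout < vdd / 2
  r <- rep(NA_real_, length(vout))
  r[valid] <- (1 - 2 * vout[valid] / vdd) * device$reference_resistance
  g <- rep(NA_real_, length(vout))
  g[valid] <- 1e6 / r[valid]
  rate <- device$adc_sampling_rate
  if (anyNA(g)) {
    runs <- rle(is.na(g))
    if (any(runs$lengths[runs$values] > max_gap_s * rate)) {
      rlang::abort(sprintf(
        "invalid-sample gap longer than %g s; cannot interpolate", max_gap_s
      ))
    }
    g <- stats::approx(seq_along(g)[!is.na(g)], g[!is.na(g)],
                       xout = seq_along(g), rule = 2)$y
  }
  eda_signal(g, rate,
    start_time = log$time[1], units = "uS",
    provenance = "ingest:voltage_to_conductance"
  )
}
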