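# Ratiometric SpO2 from the red / near-IR extinction contrast of oxy- and
# deoxy-haemoglobin, evaluated at pulse peaks of the bandpassed grey
# waveform.

#' Load the haemoglobin extinction table
#'
#' Molar extinction coefficients of oxy- and deoxy-haemoglobin: the
#' 860 nm row for the near-IR band and the arithmetic mean over the
#' 600-700 nm rows for the red band. The shipped table
#' (`inst/extdata/hb_molar_extinction_synthetic.csv`) is a coarse,
#' clearly-labelled synthetic reconstruction of the standard public
#' compilation; swap in exact rows via `path` if you have them. The
#' physical orderings the method needs always hold: `ir_oxy > ir_deoxy`
#' (oxyhaemoglobin absorbs more above the ~800 nm isosbestic point) and
#' `red_deoxy > red_oxy` (deoxyhaemoglobin dominates in the red band).
#'
#' @param path optional CSV with columns
#'   `wavelength_nm,hbo2_cm1_M,hb_cm1_M` including rows spanning
#'   600-700 nm and one at 860 nm.
#' @return an object of class `extinction_table` with fields `ir_oxy`,
#'   `ir_deoxy`, `red_oxy`, `red_deoxy` (cm^-1/M) and `source`.
#' @export
load_extinction_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hb_molar_extinction_synthetic.csv",
                        package = "rppgvitals", mustWork = TRUE)
  }
  tab <- read.csv(path, comment.char = "#")
  red <- tab[tab$wavelength_nm >= 600 & tab$wavelength_nm <= 700, ]
  ir <- tab[tab$wavelength_nm == 860, ]
  if (nrow(red) == 0L || nrow(ir) != 1L) {
    stop_format("extinction table must cover 600-700 nm and 860 nm")
  }
  out <- structure(list(ir_oxy = ir$hbo2_cm1_M, ir_deoxy = ir$hb_cm1_M,
                        red_oxy = mean(red$hbo2_cm1_M),
                        red_deoxy = mean(red$hb_cm1_M),
                        source = path),
                   class = "extinction_table")
  if (out$ir_oxy <= out$ir_deoxy || out$red_deoxy <= out$red_oxy ||
      any(unlist(out[1:4]) <= 0)) {
    stop_validation("extinction table violates physical ordering")
  }
  out
}

#' SpO2 calculation parameters
#'
#' @param scaling IR/red scaling factor (default 52).
#' @param offset_c constant offset in percentage points subtracted from
#'   the final oxygen level (default 6).
#' @return an object of class `spo2_params`.
#' @export
spo2_params <- function(scaling = 52, offset_c = 6) {
  if (scaling <= 0) stop_validation("scaling must be positive")
  structure(list(scaling = scaling, offset_c = offset_c),
            class = "spo2_params")
}

#' IR-to-red ratio at one pulse peak
#'
#' `(red_oxy / ir_oxy) * (ir_value * dist / red_value) / scaling`: the
#' raw near-IR intensity, corrected for face-to-camera distance and for
#' the extinction contrast of oxyhaemoglobin between the two bands,
#' relative to the raw red intensity.
#'
#' @param ir_value raw pooled IR intensity at the peak.
#' @param red_value raw pooled red intensity at the peak (> 0).
#' @param dist face-to-camera distance in metres (> 0).
#' @param table an [load_extinction_table()] result.
#' @param params a [spo2_params()].
#' @return dimensionless ratio (vectorised over peaks).
#' @export
ir_to_red_ratio <- function(ir_value, red_value, dist, table,
                            params = spo2_params()) {
  stopifnot(inherits(table, "extinction_table"),
            inherits(params, "spo2_params"))
  if (any(red_value <= 0)) stop_validation("red_value must be positive")
  if (any(dist <= 0)) stop_validation("distance must be positive")
  (table$red_oxy / table$ir_oxy) * (ir_value * dist / red_value) /
    params$scaling
}

#' Oxygen saturation from the IR-to-red ratio
#'
#' `100 * (red_deoxy - r * ir_deoxy) / (ir_oxy + red_deoxy - ir_deoxy -
#' red_oxy) - offset_c`, clipped to \[0, 100\] %. Affine and strictly
#' decreasing in `r`.
#'
#' @param r ratio from [ir_to_red_ratio()] (vectorised).
#' @param table an `extinction_table`.
#' @param params a [spo2_params()].
#' @return SpO2 in percent.
#' @export
spo2_from_ratio <- function(r, table, params = spo2_params()) {
  stopifnot(inherits(table, "extinction_table"),
            inherits(params, "spo2_params"))
  denom <- table$ir_oxy + table$red_deoxy - table$ir_deoxy - table$red_oxy
  if (denom == 0) stop_validation("degenerate extinction configuration")
  s <- 100 * (table$red_deoxy - r * table$ir_deoxy) / denom -
    params$offset_c
  pmin(pmax(s, 0), 100)
}

#' Ratio that maps to a target SpO2 (algebraic inverse)
#'
#' Inverts [spo2_from_ratio()] before clipping. Used by the synthetic
#' generator to encode a configured SpO2 trajectory into channel DC
#' levels, and by tests of the inverse-consistency property.
#'
#' @param spo2_pct target SpO2 in percent.
#' @param table an `extinction_table`.
#' @param params a [spo2_params()].
#' @return the ratio `r` with `spo2_from_ratio(r) == spo2_pct`.
#' @export
ratio_for_spo2 <- function(spo2_pct, table, params = spo2_params()) {
  denom <- table$ir_oxy + table$red_deoxy - table$ir_deoxy - table$red_oxy
  if (denom == 0) stop_validation("degenerate extinction configuration")
  r <- (table$red_deoxy - (spo2_pct + params$offset_c) * denom / 100) /
    table$ir_deoxy
  if (any(r <= 0)) {
    stop_validation("target SpO2 outside the invertible range ",
                    "for this extinction table")
  }
  r
}

# Time-domain pulse waveform: full FFT, zero all bins outside the band
# (two-sided mask), inverse FFT.
bandpassed_waveform <- function(values, fs, band = c(0.66, 3.33)) {
  L <- length(values)
  X <- fft(as.numeric(values))
  k <- 0:(L - 1)
  f <- k * fs / L
  f_fold <- pmin(f, fs - f)            # analogue frequency of each bin
  X[f_fold < band[1] | f_fold > band[2]] <- 0
  Re(fft(X, inverse = TRUE)) / L
}

#' Per-window SpO2 from the grey pulse waveform and raw red/IR series
#'
#' The bandpassed grey signal is inverse-transformed to a time-domain
#' pulse waveform and its peaks located. At each peak time the
#' nearest-timestamp raw red sample, raw IR sample (both with only
#' spatial pooling applied) and distance sample are looked up; each peak
#' yields one SpO2 value through [ir_to_red_ratio()] and
#' [spo2_from_ratio()], and the window estimate is their mean.
#'
#' @param grey_values grey-channel series aligned on an even grid (raw,
#'   not pre-processed).
#' @param grey_timestamps its even grid, ms.
#' @param raw_red,raw_ir [channel_series()] with only spatial pooling
#'   applied.
#' @param distance list with `timestamps` (ms) and `metres`.
#' @param table an `extinction_table`.
#' @param params a [spo2_params()].
#' @param band cardiac band in Hz for the grey bandpass.
#' @return list with `spo2_pct` (mean over peaks), `per_peak` values and
#'   `peak_times_ms`.
#' @export
spo2_window <- function(grey_values, grey_timestamps, raw_red, raw_ir,
                        distance, table, params = spo2_params(),
                        band = c(0.66, 3.33)) {
  n <- length(grey_values)
  stopifnot(length(grey_timestamps) == n)
  if (n < 4L) stop_validation("window too short for SpO2")
  fs <- 1000 * (n - 1) / (grey_timestamps[n] - grey_timestamps[1])
  wave <- bandpassed_waveform(grey_values, fs, band)
  pk <- pracma::findpeaks(wave)
  if (is.null(pk) || nrow(pk) == 0L) {
    stop(structure(class = c("rppg_no_peak_error", "error", "condition"),
                   list(message = "no pulse peaks in grey waveform",
                        call = sys.call(-1))))
  }
  t_peaks <- grey_timestamps[pk[, 2]]
  red_v <- raw_red$values[nearest_index(t_peaks, raw_red$timestamps)]
  ir_v <- raw_ir$values[nearest_index(t_peaks, raw_ir$timestamps)]
  if (length(distance$metres) == 0L) {
    stop_validation("distance trace required for SpO2")
  }
  d_v <- distance$metres[nearest_index(t_peaks, distance$timestamps)]
  r <- ir_to_red_ratio(ir_v, red_v, d_v, table, params)
  per_peak <- spo2_from_ratio(r, table, params)
  list(spo2_pct = mean(per_peak), per_peak = per_peak,
       peak_times_ms = t_peaks)
}
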