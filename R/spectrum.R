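# Frequency-domain HR machinery: magnitude spectrum, cardiac bandpass,
# dominant-peak detection, SNR scoring and best-candidate selection.

#' One-sided FFT magnitude spectrum
#'
#' @param signal numeric vector, length >= 4.
#' @param fs sampling rate in Hz (> 0).
#' @return an object of class `rppg_spectrum`: list with `frequencies`
#'   (Hz, spacing `fs / length(signal)`), `magnitudes` (|DFT|), `fs` and
#'   `n` (original signal length).
#' @export
magnitude_spectrum <- function(signal, fs) {
  if (length(signal) < 4L) stop_validation("signal too short for FFT")
  assert_scalar_number(fs, "fs")
  if (fs <= 0) stop_validation("fs must be positive")
  L <- length(signal)
  X <- fft(as.numeric(signal))
  k <- seq_len(L %/% 2L + 1L)          # DC .. Nyquist
  structure(list(frequencies = (k - 1) * fs / L,
                 magnitudes = Mod(X[k]),
                 fs = fs, n = L, band = NULL),
            class = "rppg_spectrum")
}

#' Cardiac bandpass mask
#'
#' Zeroes all magnitudes outside `[low, high]` Hz. The default band
#' 0.66-3.33 Hz spans plausible heart rates (about 39-200 BPM). The band
#' is recorded on the spectrum so downstream SNR uses in-band bins.
#'
#' @param spec an `rppg_spectrum`.
#' @param low,high band edges in Hz, `low < high`.
#' @return the masked `rppg_spectrum`.
#' @export
bandpass <- function(spec, low = 0.66, high = 3.33) {
  stopifnot(inherits(spec, "rppg_spectrum"))
  if (!(low < high)) stop_validation("low must be < high")
  out <- spec$frequencies < low | spec$frequencies > high
  spec$magnitudes[out] <- 0
  spec$band <- c(low, high)
  spec
}

#' Dominant spectral peak
#'
#' Finds local maxima of the magnitude spectrum (neighbours outside the
#' array treated as -Inf) and returns the one with the largest magnitude;
#' ties break toward the lower frequency.
#'
#' @param spec an `rppg_spectrum` (typically after [bandpass()]).
#' @return list with `frequency` (Hz) and `magnitude`.
#' @export
dominant_peak <- function(spec) {
  stopifnot(inherits(spec, "rppg_spectrum"))
  m <- spec$magnitudes
  K <- length(m)
  left <- c(-Inf, m[-K])
  right <- c(m[-1], -Inf)
  is_peak <- m >= left & m >= right & m > 0
  if (!any(is_peak)) {
    stop(structure(class = c("rppg_no_peak_error", "error", "condition"),
                   list(message = "no positive spectral peak in band",
                        call = sys.call(-1))))
  }
  idx <- which(is_peak)
  best <- idx[which.max(m[idx])]       # which.max takes the first maximum,
                                       # i.e. the lower-frequency tie
  list(frequency = spec$frequencies[best], magnitude = m[best])
}

#' Spectral signal-to-noise ratio
#'
#' The quality score of a candidate: peak magnitude divided by the mean
#' magnitude of the spectrum's in-band bins (peak bin included). For an
#' unbandpassed spectrum the mean runs over all bins. Dimensionless; a
#' flat spectrum scores exactly 1.
#'
#' @param spec an `rppg_spectrum`.
#' @param peak_magnitude magnitude of the candidate peak.
#' @return SNR ratio (Inf if the mean magnitude is zero).
#' @export
snr <- function(spec, peak_magnitude) {
  stopifnot(inherits(spec, "rppg_spectrum"))
  m <- spec$magnitudes
  if (!is.null(spec$band)) {
    inband <- spec$frequencies >= spec$band[1] &
      spec$frequencies <= spec$band[2]
    m <- m[inband]
  }
  if (length(m) == 0L) stop_validation("empty spectrum")
  denom <- mean(m)
  if (denom == 0) return(Inf)
  peak_magnitude / denom
}

#' Convert a frequency to beats per minute
#'
#' @param frequency Hz, >= 0.
#' @return `frequency * 60` BPM.
#' @export
hr_bpm <- function(frequency) {
  if (any(frequency < 0)) stop_validation("frequency must be >= 0")
  frequency * 60
}

#' Build a vital-sign candidate record
#'
#' @param region region label.
#' @param provenance channel/component provenance string.
#' @param peak_frequency dominant peak frequency, Hz.
#' @param peak_magnitude its magnitude.
#' @param snr its SNR score.
#' @return an object of class `vital_candidate`; `hr_bpm` is derived as
#'   `60 * peak_frequency`.
#' @export
vital_candidate <- function(region, provenance, peak_frequency,
                            peak_magnitude, snr) {
  structure(list(region = region, provenance = provenance,
                 peak_frequency = peak_frequency,
                 peak_magnitude = peak_magnitude,
                 snr = snr, hr_bpm = hr_bpm(peak_frequency)),
            class = "vital_candidate")
}

#' Select the best candidate by SNR
#'
#' Across all regions and channels/components of one window, the
#' candidate with the maximal SNR wins; ties break toward the earliest
#' candidate in list order (callers list candidates in region, then
#' channel order).
#'
#' @param candidates non-empty list of `vital_candidate` objects.
#' @return the winning `vital_candidate`.
#' @export
select_best <- function(candidates) {
  if (length(candidates) == 0L) {
    stop(structure(class = c("rppg_no_candidate_error", "error",
                             "condition"),
                   list(message = "no candidates to select from",
                        call = sys.call(-1))))
  }
  snrs <- vapply(candidates, function(c) c$snr, numeric(1))
  candidates[[which.max(snrs)]]
}
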