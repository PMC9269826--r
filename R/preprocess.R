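# Signal pre-processing primitives and the seven-technique registry.
#
# Each primitive mirrors the conventional routine it names (linear-algebra
# norm, linear interpolation onto an even grid, Hamming taper, sliding
# median with zero-padded edges, least-squares detrend, Fourier-domain
# resampling, centred moving average). Techniques 1-7 compose them in a
# fixed order; technique selection is fps-adaptive.

#' L2-normalise a signal
#'
#' Divides the signal by its Euclidean norm so the output has unit energy.
#'
#' @param signal non-empty numeric vector, not all zero.
#' @return signal scaled to unit L2 norm.
#' @export
l2_normalise <- function(signal) {
  if (length(signal) == 0L) stop_validation("empty signal")
  nrm <- sqrt(sum(signal^2))
  if (nrm == 0) stop_validation("degenerate all-zero signal")
  signal / nrm
}

#' Linearly interpolate a signal onto an even time grid
#'
#' Resamples onto `length(signal)` evenly spaced points spanning the same
#' `[first, last]` timestamp range, so unevenly sampled camera frames
#' become a uniform series of identical length.
#'
#' @param signal numeric vector (length >= 2).
#' @param timestamps millisecond timestamps, strictly increasing, same
#'   length as `signal`.
#' @return interpolated values on the even grid.
#' @export
interpolate_even <- function(signal, timestamps) {
  n <- length(signal)
  if (n < 2L || length(timestamps) != n) {
    stop_validation("need >= 2 samples with matching timestamps")
  }
  if (any(diff(timestamps) <= 0)) {
    stop_validation("duplicate or decreasing timestamps")
  }
  grid <- seq(timestamps[1], timestamps[n], length.out = n)
  approx(x = timestamps, y = signal, xout = grid)$y
}

#' Apply a Hamming taper
#'
#' Pointwise product with the length-matched Hamming window
#' `w[n] = 0.54 - 0.46 cos(2*pi*n / (L - 1))`. Length-1 input is rejected
#' (the window formula is degenerate there).
#'
#' @param signal numeric vector, length >= 2.
#' @return tapered signal.
#' @export
apply_hamming <- function(signal) {
  L <- length(signal)
  if (L < 2L) stop_validation("Hamming window needs length >= 2")
  as.numeric(signal * signal::hamming(L))
}

#' Sliding median filter with zero-padded edges
#'
#' Each output sample is the median of the kernel-wide neighbourhood, with
#' the signal conceptually padded by zeros at both ends (so edges shrink
#' toward zero), matching the conventional one-dimensional median filter.
#'
#' @param signal numeric vector.
#' @param kernel odd window width (default 3).
#' @return filtered signal, same length.
#' @export
median_filter <- function(signal, kernel = 3L) {
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L) {
    stop_validation("kernel must be odd and >= 1")
  }
  if (kernel == 1L) return(as.numeric(signal))
  n <- length(signal)
  half <- kernel %/% 2L
  padded <- c(numeric(half), as.numeric(signal), numeric(half))
  vapply(seq_len(n),
         function(i) median(padded[i:(i + kernel - 1L)]),
         numeric(1))
}

#' Remove a least-squares linear trend
#'
#' Subtracts the best-fitting straight line (in the index), leaving a
#' series with zero mean and zero least-squares slope.
#'
#' @param signal numeric vector, length >= 2.
#' @return detrended signal.
#' @export
detrend_linear <- function(signal) {
  n <- length(signal)
  if (n < 2L) stop_validation("detrend needs length >= 2")
  idx <- seq_len(n)
  as.numeric(stats::lm.fit(cbind(1, idx), as.numeric(signal))$residuals)
}

#' Upsample a signal in the Fourier domain
#'
#' Resamples to `length * factor` samples by zero-padding the spectrum
#' (splitting the Nyquist bin for even lengths), the standard FFT
#' resampling scheme. Band-limited signals round-trip through
#' upsample/decimate unchanged.
#'
#' @param signal numeric vector, length >= 2.
#' @param factor integer upsampling factor >= 1 (default 2).
#' @return resampled signal of length `length(signal) * factor`.
#' @export
upsample_fft <- function(signal, factor = 2L) {
  factor <- as.integer(factor)
  if (factor < 1L) stop_validation("factor must be >= 1")
  n <- length(signal)
  if (n < 2L) stop_validation("upsample needs length >= 2")
  if (factor == 1L) return(as.numeric(signal))
  m <- n * factor
  X <- fft(as.numeric(signal))
  Y <- complex(m)
  nh <- n %/% 2L
  if (n %% 2L == 0L) {
    Y[1:nh] <- X[1:nh]
    Y[nh + 1L] <- X[nh + 1L] / 2
    Y[m - nh + 1L] <- X[nh + 1L] / 2
    if (nh >= 2L) Y[(m - nh + 2L):m] <- X[(nh + 2L):n]
  } else {
    Y[1:(nh + 1L)] <- X[1:(nh + 1L)]
    Y[(m - nh + 1L):m] <- X[(nh + 2L):n]
  }
  Re(fft(Y, inverse = TRUE)) / n
}

#' Centred moving average
#'
#' Each output sample is the mean of the window centred on it, truncated
#' at the signal edges (shorter one-sided windows near the ends).
#'
#' @param signal numeric vector.
#' @param window odd window width (default 5).
#' @return smoothed signal, same length.
#' @export
smooth_ma <- function(signal, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop_validation("window must be odd and >= 1")
  }
  n <- length(signal)
  half <- window %/% 2L
  vapply(seq_len(n), function(i) {
    mean(signal[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Apply one of the seven registered pre-processing techniques
#'
#' The registry (technique -> step list, applied left to right):
#' \describe{
#'   \item{1}{none (raw signal unchanged)}
#'   \item{2}{normalise}
#'   \item{3}{interpolate, Hamming, smooth, median filter, normalise}
#'   \item{4}{detrend, interpolate, Hamming, smooth, median filter,
#'     normalise}
#'   \item{5}{interpolate, Hamming, normalise}
#'   \item{6}{detrend, interpolate, Hamming, normalise}
#'   \item{7}{detrend, upsample x2, interpolate, Hamming, normalise}
#' }
#' Technique 7 doubles the sample count (its output lives on an even grid
#' of `2 * length(signal)` points over the same time span); all others
#' preserve length.
#'
#' @param signal numeric vector.
#' @param timestamps millisecond timestamps matching `signal`.
#' @param type_id integer 1-7.
#' @return processed numeric vector.
#' @export
apply_technique <- function(signal, timestamps, type_id) {
  if (!type_id %in% 1:7) stop_validation("unknown technique id: ", type_id)
  x <- as.numeric(signal)
  ts <- as.numeric(timestamps)
  switch(as.character(type_id),
    "1" = x,
    "2" = l2_normalise(x),
    "3" = l2_normalise(median_filter(smooth_ma(apply_hamming(
            interpolate_even(x, ts))))),
    "4" = l2_normalise(median_filter(smooth_ma(apply_hamming(
            interpolate_even(detrend_linear(x), ts))))),
    "5" = l2_normalise(apply_hamming(interpolate_even(x, ts))),
    "6" = l2_normalise(apply_hamming(interpolate_even(
            detrend_linear(x), ts))),
    "7" = {
      up <- upsample_fft(detrend_linear(x), 2L)
      ts2 <- seq(ts[1], ts[length(ts)], length.out = length(up))
      l2_normalise(apply_hamming(interpolate_even(up, ts2)))
    }
  )
}

#' fps-adaptive technique selection
#'
#' Low frame rates leave too few samples per window for a clean spectral
#' peak, so streams below 15 fps get technique 7 (which adds FFT
#' upsampling); 15 fps and above get technique 6.
#'
#' @param fps frames per second (> 0).
#' @return technique id: 7 if `fps < 15`, else 6.
#' @export
select_technique_auto <- function(fps) {
  assert_scalar_number(fps, "fps")
  if (fps <= 0) stop_validation("fps must be positive")
  if (fps < 15) 7L else 6L
}
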