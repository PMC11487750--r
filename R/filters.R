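# Linear-phase FIR filtering of EEG. The detection/spectral band is
# 0.5-35 Hz; the filter is a 2000-tap Hamming-window design applied
# forward-backward (zero net phase shift, squared magnitude response).

#' Design the 0.5-35 Hz bandpass FIR filter
#'
#' 2000-tap linear-phase finite impulse response bandpass, Hamming-window
#' design. Intended for application with [filter_zero_phase()] so the net
#' phase shift is zero.
#'
#' @param fs Sampling rate in Hz (>= 100 so the 35 Hz edge is well below
#'   Nyquist).
#' @param f_lo,f_hi Band edges in Hz (defaults 0.5 and 35).
#' @param n_taps Filter length (default 2000).
#' @return Numeric vector of filter coefficients.
#' @export
design_bandpass <- function(fs, f_lo = 0.5, f_hi = 35, n_taps = 2000) {
  if (fs < 2 * f_hi + 10) {
    abort(sprintf("fs = %g Hz is too low for a %g Hz band edge.", fs, f_hi))
  }
  signal::fir1(n_taps - 1, c(f_lo, f_hi) / (fs / 2), type = "pass",
               window = signal::hamming(n_taps))
}

# FFT-based full convolution; O(n log n), needed because 2000-tap direct
# filtering of whole-night 500 Hz signals is impractical in R.
fft_conv <- function(x, h) {
  m <- length(x) + length(h) - 1L
  nfft <- stats::nextn(m, 2)
  X <- fft(c(x, numeric(nfft - length(x))))
  H <- fft(c(h, numeric(nfft - length(h))))
  Re(fft(X * H, inverse = TRUE))[seq_len(m)] / nfft
}

#' Apply an FIR filter with zero phase shift
#'
#' Filters forward and backward (equivalently, convolves with the
#' autocorrelation of the taps), so the effective magnitude response is the
#' square of the single-pass response and the phase response is identically
#' zero. Edges are handled by zero extension.
#'
#' @param x Numeric signal.
#' @param h FIR coefficients from [design_bandpass()].
#' @param single_pass If `TRUE`, apply the filter once and compensate the
#'   group delay of the linear-phase design instead.
#' @return Filtered signal, same length as `x`.
#' @export
filter_zero_phase <- function(x, h, single_pass = FALSE) {
  n <- length(x)
  L <- length(h)
  if (single_pass) {
    # linear-phase group delay is (L-1)/2 samples; shift to align
    y <- fft_conv(x, h)
    d <- (L - 1) / 2
    lo <- floor(d) + 1L
    return(y[lo:(lo + n - 1L)])
  }
  g <- fft_conv(h, rev(h))                     # symmetric, length 2L-1, center at L
  y <- fft_conv(x, g)
  y[L:(L + n - 1L)]
}

#' Centered moving-average smoother
#'
#' Boxcar of `round(win_sec * fs)` samples (25 at 500 Hz for the default
#' 50 ms), centered, with the window shrinking at the signal edges. Applied to
#' the 0.5-35 Hz filtered signal before slow-wave detection.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param win_sec Window length in seconds (default 0.05).
#' @return Smoothed signal, same length.
#' @export
smooth_moving_average <- function(x, fs, win_sec = 0.05) {
  L <- max(1L, as.integer(round(win_sec * fs)))
  if (L == 1L) return(x)
  n <- length(x)
  left <- (L - 1L) %/% 2L
  right <- L - 1L - left
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - left)
  hi <- pmin(n, i + right)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Resample a signal to a target rate
#'
#' Polyphase rational-ratio resampling (via `signal::resample`). Used when a
#' recording's header rate differs from the 500 Hz grid the feature-extraction
#' defaults assume.
#'
#' @param x Numeric signal.
#' @param fs Current sampling rate in Hz.
#' @param target_fs Desired rate in Hz.
#' @return Resampled signal.
#' @export
resample_signal <- function(x, fs, target_fs) {
  if (fs == target_fs) return(x)
  scale <- 1000L                               # resolve rates to 1 mHz
  p <- as.integer(round(target_fs * scale))
  q <- as.integer(round(fs * scale))
  g <- gcd_int(p, q)
  as.numeric(signal::resample(x, p / g, q / g))
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)
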