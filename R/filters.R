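# Zero-phase IIR filtering.
#
# signal::filtfilt() leaves large startup transients on short or offset
# signals, so the forward-backward pass is implemented here with odd
# reflection padding and steady-state-like initial conditions (previous
# input/output samples set to the first padded value). DC gain is preserved
# to ~1e-10 and symmetric features keep their location.

# one causal IIR pass with constant-history initialisation
iir_pass <- function(b, a, x) {
  n <- length(a) - 1L
  as.numeric(signal::filter(b, a, x, init.x = rep(x[1], n), init.y = rep(x[1], n)))
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an `order`-th order Butterworth low-pass forward and backward
#' (squaring the magnitude response, cancelling the phase). The signal is
#' extended by odd reflection at both ends before filtering so edges carry no
#' startup transient.
#'
#' @param x numeric vector (or matrix, filtered per column).
#' @param fs sampling rate, Hz.
#' @param cutoff cutoff frequency, Hz (must be below `fs/2`).
#' @param order filter order of each pass (default 4).
#' @return filtered signal, same shape as `x`.
#' @export
butter_lowpass_zerophase <- function(x, fs, cutoff, order = 4L) {
  assert_scalar_number(fs, "fs", positive = TRUE)
  assert_scalar_number(cutoff, "cutoff", positive = TRUE)
  if (cutoff >= fs / 2) abort_invalid("cutoff must be below the Nyquist frequency")
  if (is.matrix(x)) return(apply(x, 2L, butter_lowpass_zerophase, fs = fs,
                                 cutoff = cutoff, order = order))
  n <- length(x)
  flt <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # pad long enough for the filter transient to die out; sharp (low relative
  # cutoff) filters ring longer
  pl <- min(n - 1L, max(3L * order, ceiling(2 * fs / cutoff)))
  if (pl < order + 1L)
    abort_invalid(sprintf("signal too short for zero-phase filtering (need > %d samples)",
                          order + 1L))
  head_pad <- 2 * x[1] - x[(pl + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - pl)]
  xp <- c(head_pad, x, tail_pad)
  y <- iir_pass(flt$b, flt$a, xp)
  y <- rev(iir_pass(flt$b, flt$a, rev(y)))
  y[(pl + 1L):(pl + n)]
}

#' Analytic amplitude gain of the zero-phase Butterworth filter
#'
#' One Butterworth pass has squared magnitude `1 / (1 + (f/fc)^(2*order))`;
#' the forward-backward (zero-phase) filter applies it twice, so the
#' amplitude gain is that expression itself. When `fs` is supplied the
#' bilinear-transform frequency warping of the digital design is applied
#' (`tan(pi f / fs)` ratio), making the oracle exact for the implemented
#' filter. Used as an independent oracle for attenuation checks.
#'
#' @param f frequency, Hz.
#' @param cutoff cutoff frequency, Hz.
#' @param order filter order of each pass.
#' @param fs sampling rate of the digital filter; `NULL` for the analog
#'   prototype response.
#' @export
butterworth_gain2 <- function(f, cutoff, order = 4L, fs = NULL) {
  r <- if (is.null(fs)) f / cutoff else tan(pi * f / fs) / tan(pi * cutoff / fs)
  1 / (1 + r^(2 * order))
}
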