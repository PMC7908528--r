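#' Second-order Butterworth low-pass coefficients
#'
#' Digital coefficients by bilinear transform of the analogue second-order
#' Butterworth prototype. The transfer function is
#' H(z) = (b0 + b1 z^-1 + b2 z^-2) / (1 + a1 z^-1 + a2 z^-2).
#'
#' @param cutoff_hz -3 dB cutoff frequency, Hz.
#' @param rate_hz Sampling rate, Hz; must exceed `2 * cutoff_hz`.
#' @return List with numeric vectors `b` (length 3) and `a` (length 3,
#'   `a[1] == 1`).
#' @keywords internal
butter2_lowpass <- function(cutoff_hz, rate_hz) {
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0) {
    stop("butter2_lowpass: cutoff must be > 0")
  }
  if (cutoff_hz >= rate_hz / 2) {
    stop("butter2_lowpass: cutoff ", cutoff_hz,
         " Hz is at or above the Nyquist frequency (", rate_hz / 2, " Hz)")
  }
  K <- tan(pi * cutoff_hz / rate_hz)
  norm <- 1 / (1 + sqrt(2) * K + K^2)
  b0 <- K^2 * norm
  list(b = c(b0, 2 * b0, b0),
       a = c(1, 2 * (K^2 - 1) * norm, (1 - sqrt(2) * K + K^2) * norm))
}

# One causal pass of the biquad. Warm-started at x[1] (steady state for the
# pre-trial baseline) so a quiet-standing offset does not produce a start-up
# transient; the recursion runs in C via stats::filter.
iir2_pass <- function(x, coef) {
  n <- length(x)
  if (n < 3L) return(x)
  xp <- c(x[1L], x[1L], x)
  u <- stats::filter(xp, coef$b, method = "convolution", sides = 1)
  u <- as.numeric(u)[3:(n + 2L)]
  y <- stats::filter(u, -coef$a[2:3], method = "recursive",
                     init = c(x[1L], x[1L]))
  as.numeric(y)
}

#' Causal second-order Butterworth low-pass
#'
#' Single forward (recursive) pass, as used for force-plate jump records.
#' Introduces the filter's group delay; DC gain is exactly 1.
#'
#' @param x Numeric signal.
#' @param rate_hz Sampling rate, Hz.
#' @param cutoff_hz Cutoff, Hz (default 10, the jump convention).
#' @return Filtered signal, same length as `x`.
#' @export
lowpass_causal <- function(x, rate_hz, cutoff_hz = 10) {
  iir2_pass(as.numeric(x), butter2_lowpass(cutoff_hz, rate_hz))
}

#' Zero-phase second-order Butterworth low-pass
#'
#' Forward-backward filtering: the second, time-reversed pass cancels the
#' phase of the first, so peaks keep their time index; the effective
#' magnitude response is the square of the single-pass response. Edges are
#' handled by reflecting one second of signal at each end before filtering
#' and trimming afterwards.
#'
#' @param x Numeric signal.
#' @param rate_hz Sampling rate, Hz.
#' @param cutoff_hz Cutoff, Hz (default 5, the isokinetic convention).
#' @param pad_s Reflection pad length at each end, seconds.
#' @return Filtered signal, same length as `x`.
#' @export
lowpass_zero_phase <- function(x, rate_hz, cutoff_hz = 5, pad_s = 1) {
  x <- as.numeric(x)
  coef <- butter2_lowpass(cutoff_hz, rate_hz)  # validates cutoff vs Nyquist
  n <- length(x)
  np <- min(max(round(pad_s * rate_hz), 1L), n - 1L)
  if (np >= 1L && n > 2L) {
    left <- rev(x[2:(np + 1L)])
    right <- rev(x[(n - np):(n - 1L)])
    xp <- c(left, x, right)
  } else {
    np <- 0L
    xp <- x
  }
  y <- iir2_pass(xp, coef)
  y <- rev(iir2_pass(rev(y), coef))
  y[(np + 1L):(np + n)]
}

#' Analytic Butterworth magnitude response
#'
#' |H(f)| of the order-2 analogue Butterworth low-pass,
#' 1 / sqrt(1 + (f/fc)^4); squared for the forward-backward (zero-phase)
#' filter. Used as the independent oracle for the filter contracts.
#'
#' @param f Frequency, Hz (vectorised).
#' @param cutoff_hz Cutoff, Hz.
#' @param passes 1 (causal) or 2 (zero-phase).
#' @return Magnitude gain(s).
#' @export
butterworth_gain <- function(f, cutoff_hz, passes = 1) {
  (1 / sqrt(1 + (f / cutoff_hz)^4))^passes
}
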