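#' Causal 4-pole Bessel low-pass filter
#'
#' Emulates the analog Bessel filtering applied by acquisition hardware and
#' the digitized Bessel filtering used for offline fluorescence analysis.
#' The analog prototype is the 4th-order Bessel filter (poles of the
#' reversed Bessel polynomial, frequency-scaled so the -3 dB point sits at
#' the requested cutoff), discretized by the bilinear transform with
#' prewarping and applied causally; DC gain is exactly 1. A zero-phase
#' variant (forward-backward filtering) is available but off by default
#' since real acquisition chains are causal.
#'
#' @param samples numeric vector to filter.
#' @param sample_rate sampling rate (kHz).
#' @param cutoff -3 dB cutoff frequency (kHz); must be below Nyquist.
#' @param zero_phase if `TRUE`, filter forward and backward (zero phase,
#'   squared magnitude response).
#' @return filtered vector, same length as `samples`.
#' @export
bessel_lowpass <- function(samples, sample_rate, cutoff, zero_phase = FALSE) {
  if (!is.finite(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be > 0")
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= sample_rate / 2)
    stop("cutoff must satisfy 0 < cutoff < sample_rate/2 (Nyquist)")
  flt <- .bessel4_design(sample_rate, cutoff)
  x <- as.numeric(samples)
  # prepend a settled start so the causal transient relaxes from the first
  # sample's level rather than from zero
  if (zero_phase) {
    y <- signal::filtfilt(flt, x)
  } else {
    pad <- rep(x[1], 4L * ceiling(sample_rate / cutoff))
    y <- signal::filter(flt, c(pad, x))
    y <- y[(length(pad) + 1L):(length(pad) + length(x))]
  }
  as.numeric(y)
}

# digital 4th-order Bessel low-pass as an Arma filter (sample_rate/cutoff kHz)
.bessel4_design <- function(sample_rate, cutoff) {
  # reversed Bessel polynomial theta_4(s) = s^4 + 10 s^3 + 45 s^2 + 105 s + 105
  p <- polyroot(c(105, 105, 45, 10, 1))
  # scale so the -3 dB point of the prototype sits at 1 rad/s
  w3 <- 2.113917675
  p <- p / w3
  T <- 1 / sample_rate
  wc <- (2 / T) * tan(pi * cutoff * T)   # prewarped analog cutoff (rad/ms)
  poles <- p * wc
  gain <- Re(prod(-poles))               # all-pole, DC gain 1
  zpg <- signal::bilinear(Sz = numeric(0), Sp = poles, Sg = gain, T = T)
  signal::as.Arma(signal::Zpg(zero = zpg$zero, pole = zpg$pole, gain = zpg$gain))
}
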