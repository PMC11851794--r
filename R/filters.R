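#' FIR filter design and zero-phase filtering
#'
#' All filters in the package are linear-phase windowed-sinc FIR designs with
#' an odd number of taps, applied with group-delay compensation (so the net
#' effect is zero-phase) and reflection padding at the edges.  The cleaning
#' band-pass/notch uses a Hamming window; the band-decomposition filter bank
#' uses a Hanning window.
#'
#' @name fir-filters
NULL

fir_window <- function(n, type = c("hamming", "hanning")) {
  type <- match.arg(type)
  k <- seq_len(n) - 1L
  switch(type,
         hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
         hanning = 0.5 - 0.5 * cos(2 * pi * k / (n - 1)))
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Design a windowed-sinc FIR filter
#'
#' Band edges are in Hz; `low_hz = NULL` gives a low-pass, `high_hz = NULL`
#' a high-pass, both set gives a band-pass, `type = "stop"` the band-stop
#' complement.  Coefficients are symmetric (linear phase).
#'
#' @param low_hz,high_hz band edges in Hz.
#' @param sampling_rate_hz sampling rate.
#' @param numtaps odd number of taps.
#' @param window `"hamming"` or `"hanning"`.
#' @param type `"pass"` or `"stop"`.
#' @return Numeric vector of `numtaps` coefficients.
#' @export
fir_design <- function(low_hz = NULL, high_hz = NULL, sampling_rate_hz,
                       numtaps, window = "hamming", type = c("pass", "stop")) {
  type <- match.arg(type)
  if (numtaps %% 2L == 0L) stop("numtaps must be odd for zero-phase use")
  nyq <- sampling_rate_hz / 2
  if (!is.null(high_hz) && high_hz >= nyq)
    stop("upper edge ", high_hz, " Hz is at or above Nyquist (", nyq, " Hz)")
  if (!is.null(low_hz) && !is.null(high_hz) && low_hz >= high_hz)
    stop("low_hz must be below high_hz")
  m <- (numtaps - 1) / 2
  n <- seq(-m, m)
  lowpass <- function(fc) {
    f <- fc / sampling_rate_hz
    2 * f * sinc(2 * f * n)
  }
  h <- if (is.null(low_hz) && is.null(high_hz)) {
    stop("at least one band edge is required")
  } else if (is.null(low_hz)) {
    lowpass(high_hz)
  } else if (is.null(high_hz)) {
    delta <- as.numeric(n == 0)
    delta - lowpass(low_hz)
  } else {
    lowpass(high_hz) - lowpass(low_hz)
  }
  h <- h * fir_window(numtaps, window)
  if (type == "stop") {
    delta <- as.numeric(n == 0)
    h <- delta - h
  }
  h
}

#' Evaluate the amplitude response of an FIR filter
#'
#' @param h coefficients.
#' @param freq_hz frequencies at which to evaluate.
#' @param sampling_rate_hz sampling rate.
#' @return `|H(f)|` at each frequency.
#' @export
fir_response <- function(h, freq_hz, sampling_rate_hz) {
  n <- seq_along(h) - 1L
  vapply(freq_hz, function(f) {
    Mod(sum(h * exp(-2i * pi * f * n / sampling_rate_hz)))
  }, numeric(1))
}

#' Zero-phase FIR filtering with reflection padding
#'
#' Applies a linear-phase FIR filter and removes its group delay, so the
#' output is time-aligned with the input.  The signal is extended on both
#' sides by reflection (up to `pad` samples, capped at the signal length)
#' before convolving.
#'
#' @param x numeric vector, or a matrix filtered row-wise.
#' @param h odd-length FIR coefficients.
#' @param pad reflection pad length per side; defaults to the group delay.
#' @return Filtered signal, same shape as `x`.
#' @export
fir_apply <- function(x, h, pad = NULL) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, fir_apply, h = h, pad = pad))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  nt <- length(h)
  if (nt %% 2L == 0L) stop("filter length must be odd")
  m <- (nt - 1L) / 2L
  n <- length(x)
  if (is.null(pad)) pad <- m
  pad <- min(pad, n - 1L)
  xp <- c(rev(x[seq_len(pad) + 1L]), x, rev(x[n - seq_len(pad)]))
  np <- length(xp)
  nfft <- nextn(np + nt - 1L, 2L)
  X <- stats::fft(c(xp, numeric(nfft - np)))
  H <- stats::fft(c(h, numeric(nfft - nt)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  # full convolution index of input sample k is k + m + pad
  y[pad + m + seq_len(n)]
}

#' Welch band power
#'
#' Average periodogram over Hann-windowed, half-overlapping chunks, summed
#' over the frequency bins inside `[low_hz, high_hz)`.
#'
#' @param x numeric vector.
#' @param sampling_rate_hz sampling rate.
#' @param low_hz,high_hz band of interest; defaults cover everything.
#' @param nperseg chunk length (power of two recommended).
#' @return Scalar band power (arbitrary but consistent units).
#' @export
band_power <- function(x, sampling_rate_hz, low_hz = 0,
                       high_hz = sampling_rate_hz / 2, nperseg = 512L) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- fir_window(nperseg, "hanning")
  wnorm <- sum(win^2)
  freqs <- (seq_len(nperseg %/% 2L + 1L) - 1L) * sampling_rate_hz / nperseg
  keep <- freqs >= low_hz & freqs < high_hz
  psd <- rowMeans(vapply(starts, function(s) {
    seg <- x[s:(s + nperseg - 1L)] * win
    p <- Mod(stats::fft(seg))^2 / wnorm
    p[seq_len(nperseg %/% 2L + 1L)]
  }, numeric(nperseg %/% 2L + 1L)))
  sum(psd[keep])
}
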