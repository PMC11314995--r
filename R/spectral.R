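# Shared spectral primitives: Welch PSD estimation and spectrum smoothing.

#' Welch power spectral density estimate
#'
#' Averaged-periodogram PSD with a Hamming window, density normalisation
#' (power per Hz), and explicit segment/step control. Used by the velocity
#' pipeline (512-sample segments, 50% overlap) and by the generic spectral
#' pipeline (120-sample segments advanced by 10 samples at 40 Hz).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param nperseg Segment length in samples; capped at `length(x)`.
#' @param step Segment advance in samples; default 50% overlap.
#' @param window Window samples of length `nperseg`; default Hamming.
#' @param sides `"one"` for a one-sided density (interior bins doubled) or
#'   `"two"` for the full circular spectrum of length `nperseg`.
#' @return List with `freq` (Hz), `psd` (power/Hz), and `enbw`, the window's
#'   equivalent noise bandwidth in Hz (used to convert a peak density into a
#'   sinusoid-equivalent amplitude).
#' @export
#' @examples
#' fs <- 120
#' x <- sin(2 * pi * 6 * seq(0, 10, by = 1 / fs))
#' w <- welch_psd(x, fs)
#' w$freq[which.max(w$psd)] # close to 6 Hz
welch_psd <- function(x, fs, nperseg = min(512L, length(x)),
                      step = max(1L, floor(nperseg / 2)),
                      window = signal::hamming(nperseg),
                      sides = c("one", "two")) {
  sides <- match.arg(sides)
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("signal contains non-finite values")
  n <- length(x)
  nperseg <- as.integer(nperseg)
  if (n < nperseg) stop("signal shorter than one Welch segment (", nperseg,
                        " samples)")
  if (length(window) != nperseg) stop("window length must equal `nperseg`")
  starts <- seq.int(1L, n - nperseg + 1L, by = as.integer(step))
  u <- sum(window^2) # window power normalisation
  acc <- numeric(nperseg)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * window
    acc <- acc + abs(fft(seg))^2
  }
  psd2 <- acc / (length(starts) * fs * u)
  if (sides == "two") {
    freq <- (seq_len(nperseg) - 1L) * fs / nperseg
    out <- list(freq = freq, psd = psd2)
  } else {
    nf <- floor(nperseg / 2) + 1L
    psd1 <- psd2[seq_len(nf)]
    dbl <- 2:(if (nperseg %% 2 == 0) nf - 1L else nf)
    psd1[dbl] <- 2 * psd1[dbl]
    out <- list(freq = (0:(nf - 1L)) * fs / nperseg, psd = psd1)
  }
  out$enbw <- fs * sum(window^2) / sum(window)^2
  out
}

# Savitzky-Golay smoothing of a spectrum on the log (dB) scale, returned on
# the linear scale; window shrinks for very short spectra.
smooth_log_psd <- function(psd, p = 3L, n = 9L) {
  n <- min(n, if (length(psd) %% 2 == 0) length(psd) - 1L else length(psd))
  if (n <= p + 1L) return(psd)
  if (n %% 2 == 0) n <- n - 1L
  floorv <- .Machine$double.xmin
  ldb <- 10 * log10(pmax(psd, floorv))
  10^(signal::sgolayfilt(ldb, p = p, n = n) / 10)
}

# Savitzky-Golay smoothing on the linear scale, clamped at zero (the filter's
# negative lobes can otherwise push spectrum edges below zero).
smooth_linear <- function(y, p = 3L, n = 9L) {
  n <- min(n, if (length(y) %% 2 == 0) length(y) - 1L else length(y))
  if (n <= p + 1L) return(pmax(y, 0))
  if (n %% 2 == 0) n <- n - 1L
  pmax(signal::sgolayfilt(y, p = p, n = n), 0)
}

# Discrete Gaussian smoothing kernel (unit sum) applied circularly, used on
# the two-sided PSD of the generic spectral pipeline.
gaussian_smooth_circular <- function(y, sigma_bins, half_width = ceiling(4 * sigma_bins)) {
  offs <- (-half_width):half_width
  k <- exp(-offs^2 / (2 * sigma_bins^2))
  k <- k / sum(k)
  n <- length(y)
  out <- numeric(n)
  for (j in seq_along(offs)) {
    idx <- ((seq_len(n) - 1L + offs[j]) %% n) + 1L
    out <- out + k[j] * y[idx]
  }
  out
}

# Zero-phase IIR filtering with odd-reflection end padding. Plain
# forward-backward filtering starts from zero state, which injects large
# edge transients whenever the signal has an offset or slope; reflecting
# `pad` samples about each endpoint (rotated, so value and slope are
# continuous) lets the transient decay inside the padding.
zerophase_filter <- function(bf, x, pad) {
  n <- length(x)
  pad <- min(n - 1L, as.integer(pad))
  if (pad < 1L) return(as.numeric(signal::filtfilt(bf, x)))
  left <- 2 * x[1L] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(bf, c(left, x, right))
  y[(pad + 1L):(pad + n)]
}

# Trapezoidal integral on an ordered grid.
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}
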