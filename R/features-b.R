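# Generic spectral pipeline ("B"): per-marker position magnitude, FIR
# bandpass (1-20 Hz, Hamming, order 80), decimation 120 -> 40 Hz, Welch PSD
# (120-sample Hamming windows advanced by 10 samples), circular Gaussian
# smoothing (sigma 1 Hz), 61-point one-sided feature vector averaged over
# the markers of an extremity.

#' Control parameters for the generic spectral pipeline
#'
#' @param band_hz FIR bandpass edges, Hz.
#' @param fir_order FIR order (order 80 -> 81 symmetric taps, linear phase).
#' @param decimate Integer decimation factor (120 Hz -> 40 Hz).
#' @param welch_nperseg Welch window, samples at the decimated rate (120
#'   samples = 3 s).
#' @param welch_step Window advance, samples (10 samples = 0.25 s, i.e.
#'   2.75 s overlap).
#' @param smooth_sigma_hz Gaussian spectral smoothing standard deviation, Hz.
#' @param n_features One-sided feature vector length (DC .. 20 Hz).
#' @return List of class `"b_control"`.
#' @export
b_control <- function(band_hz = c(1, 20), fir_order = 80L, decimate = 3L,
                      welch_nperseg = 120L, welch_step = 10L,
                      smooth_sigma_hz = 1, n_features = 61L) {
  structure(list(band_hz = band_hz, fir_order = fir_order,
                 decimate = as.integer(decimate),
                 welch_nperseg = as.integer(welch_nperseg),
                 welch_step = as.integer(welch_step),
                 smooth_sigma_hz = smooth_sigma_hz,
                 n_features = as.integer(n_features)),
            class = "b_control")
}

#' Marker position magnitude
#'
#' Euclidean norm of the x, y, z coordinates at each time instant: the
#' marker's instantaneous distance from the kinematic origin, reducing each
#' marker to a single signal. Note the documented origin sensitivity: a
#' tremor axis orthogonal to the marker's position vector contributes
#' little to the magnitude.
#'
#' @param trajectory_xyz Frames x 3 matrix, mm.
#' @return Numeric vector, mm.
#' @export
marker_magnitude <- function(trajectory_xyz) {
  x <- as.matrix(trajectory_xyz)
  if (ncol(x) != 3L) stop("expected a frames x 3 trajectory")
  sqrt(rowSums(x^2))
}

#' Linear-phase FIR bandpass and decimation
#'
#' Removes the signal mean, applies the order-80 Hamming-window FIR
#' bandpass (1--20 Hz), compensates the 40-sample group delay so the output
#' is zero-phase, and keeps every `decimate`-th sample. No extra
#' anti-aliasing filter is needed: the passband already ends at the new
#' Nyquist frequency. The mean is removed first because the finite filter
#' order leaves appreciable gain at DC, where the magnitude signal has a
#' large baseline offset.
#'
#' @param x Numeric signal at `frame_rate` Hz.
#' @param frame_rate Input rate, Hz (default 120).
#' @param control A [b_control()].
#' @return Numeric signal at `frame_rate / decimate` Hz.
#' @export
bandpass_decimate <- function(x, frame_rate = 120, control = b_control()) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("signal contains non-finite values")
  if (length(x) <= control$fir_order + 1L) {
    stop("signal shorter than the FIR filter (", control$fir_order + 1L,
         " taps)")
  }
  b <- signal::fir1(control$fir_order, control$band_hz / (frame_rate / 2),
                    type = "pass",
                    window = signal::hamming(control$fir_order + 1L))
  gd <- control$fir_order / 2L # symmetric FIR: constant group delay
  y <- signal::filter(b, c(x - mean(x), rep(0, gd)))
  y <- as.numeric(y)[(gd + 1L):(length(x) + gd)]
  y[seq.int(1L, length(y), by = control$decimate)]
}

#' Smoothed Welch PSD feature vector for one signal
#'
#' Welch PSD of the decimated signal (120-sample Hamming windows advanced
#' by 10 samples), Gaussian-smoothed circularly on the two-sided spectrum
#' (sigma 1 Hz = 3 bins at 0.333 Hz spacing), truncated to the 61 one-sided
#' values covering DC through 20 Hz.
#'
#' @param signal_dec Signal at the decimated rate.
#' @param fs_dec Decimated rate, Hz (default 40).
#' @param control A [b_control()].
#' @return List `freq` (61 values, 0..20 Hz), `psd` (61 nonnegative values).
#' @export
welch_psd_smoothed <- function(signal_dec, fs_dec = 40, control = b_control()) {
  if (length(signal_dec) < control$welch_nperseg) {
    stop("recording shorter than ", control$welch_nperseg / fs_dec,
         " s at the decimated rate; too short for spectral features")
  }
  w <- welch_psd(signal_dec, fs_dec, nperseg = control$welch_nperseg,
                 step = control$welch_step, sides = "two")
  df <- fs_dec / control$welch_nperseg
  sm <- gaussian_smooth_circular(w$psd, sigma_bins = control$smooth_sigma_hz / df)
  keep <- seq_len(control$n_features)
  list(freq = w$freq[keep], psd = sm[keep])
}

#' 61-point spectral feature vector of an extremity
#'
#' Arithmetic mean of the per-marker smoothed PSD feature vectors
#' (smoothing precedes averaging).
#'
#' @param er An [extremity_recording()] (>= 3 s long).
#' @param control A [b_control()].
#' @return Named numeric vector of length 61 (`f0.00` .. `f20.00`), with
#'   attributes `freq` and `n_markers_averaged`.
#' @export
extremity_feature_vector <- function(er, control = b_control()) {
  stopifnot(inherits(er, "extremity_recording"))
  fs_dec <- er$frame_rate / control$decimate
  per_marker <- lapply(seq_along(er$marker_names), function(i) {
    mag <- marker_magnitude(er$data[, marker_cols(i), drop = FALSE])
    dec <- bandpass_decimate(mag, er$frame_rate, control)
    welch_psd_smoothed(dec, fs_dec, control)
  })
  v <- Reduce(`+`, lapply(per_marker, `[[`, "psd")) / length(per_marker)
  names(v) <- sprintf("f%.2f", per_marker[[1L]]$freq)
  attr(v, "freq") <- per_marker[[1L]]$freq
  attr(v, "n_markers_averaged") <- length(per_marker)
  v
}
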