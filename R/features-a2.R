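# Displacement-amplitude spectral peak pipeline ("A2"): zero-phase 2 Hz
# high-pass, single-sided FFT amplitude spectra, cross-marker/axis max
# aggregation, Savitzky-Golay smoothing, dominant-peak rules.

#' Control parameters for the amplitude spectral peak pipeline
#'
#' @param highpass_hz Zero-phase Butterworth high-pass corner, Hz.
#' @param highpass_order Butterworth order (applied forward-backward).
#' @param smooth_window Savitzky-Golay smoothing window (bins, order 3) for
#'   the aggregate spectrum.
#' @param f_range Accepted dominant-peak frequency range, Hz (inclusive:
#'   peaks are discarded when *below* 3.5 or *above* 10 Hz).
#' @param amp_min_mm Minimum peak amplitude, mm (inclusive).
#' @return List of class `"a2_control"`.
#' @export
a2_control <- function(highpass_hz = 2, highpass_order = 4L,
                       smooth_window = 9L, f_range = c(3.5, 10),
                       amp_min_mm = 0.1) {
  structure(list(highpass_hz = highpass_hz, highpass_order = highpass_order,
                 smooth_window = smooth_window, f_range = f_range,
                 amp_min_mm = amp_min_mm),
            class = "a2_control")
}

#' Zero-phase high-pass filtering of displacement
#'
#' 4th-order Butterworth high-pass (corner 2 Hz) applied forward-backward,
#' removing DC offset and slow voluntary drift while preserving the tremor
#' band.
#'
#' @param trajectory Numeric vector or frames x axes matrix, mm.
#' @param frame_rate Hz.
#' @param control An [a2_control()].
#' @return Filtered signal, same shape.
#' @export
highpass_displacement <- function(trajectory, frame_rate,
                                  control = a2_control()) {
  x <- as.matrix(trajectory)
  if (any(!is.finite(x))) stop("trajectory contains non-finite values")
  if (nrow(x) <= 3L * control$highpass_order) stop("signal too short to filter")
  bf <- signal::butter(control$highpass_order,
                       control$highpass_hz / (frame_rate / 2), type = "high")
  pad <- ceiling(3 * frame_rate / control$highpass_hz)
  out <- apply(x, 2L, function(col) zerophase_filter(bf, col - mean(col), pad))
  if (is.null(dim(trajectory))) as.numeric(out) else out
}

#' Single-sided FFT amplitude spectrum
#'
#' Raw-length FFT (no zero padding, rectangular implicit window) converted
#' to the single-sided amplitude spectrum: `2 |X(f)| / N` for interior
#' bins, `|X| / N` at DC (and Nyquist for even lengths). For a bin-aligned
#' sinusoid of amplitude A this returns A at its frequency.
#'
#' @param x Numeric signal, mm.
#' @param frame_rate Hz.
#' @return List `freq` (Hz), `amplitude` (mm).
#' @export
single_sided_amplitude_spectrum <- function(x, frame_rate) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("signal contains non-finite values")
  n <- length(x)
  X <- abs(fft(x)) / n
  nf <- floor(n / 2) + 1L
  amp <- X[seq_len(nf)]
  dbl <- 2:(if (n %% 2 == 0) nf - 1L else nf)
  amp[dbl] <- 2 * amp[dbl]
  list(freq = (0:(nf - 1L)) * frame_rate / n, amplitude = amp)
}

#' Aggregate amplitude spectra by elementwise maximum
#'
#' Combines the single-sided spectra of every axis of every marker into one
#' aggregate representing the most severe tremor at each frequency, then
#' smooths with a 3rd-order Savitzky-Golay filter (clamped at zero).
#' Spectra on different frequency grids are linearly interpolated onto the
#' finest grid supplied.
#'
#' @param spectra List of `list(freq, amplitude)` spectra (>= 1).
#' @return List `freq`, `aggregate` (smoothed), `raw` (pre-smoothing
#'   aggregate).
#' @param control An [a2_control()].
#' @export
aggregate_max_spectrum <- function(spectra, control = a2_control()) {
  if (!length(spectra)) stop("no spectra supplied")
  lens <- vapply(spectra, function(s) length(s$freq), 0L)
  ref <- spectra[[which.max(lens)]]$freq
  mats <- vapply(spectra, function(s) {
    if (length(s$freq) == length(ref) && all(s$freq == ref)) s$amplitude
    else approx(s$freq, s$amplitude, xout = ref, rule = 2)$y
  }, numeric(length(ref)))
  raw <- apply(as.matrix(mats), 1L, max)
  list(freq = ref, aggregate = smooth_linear(raw, p = 3L,
                                             n = control$smooth_window),
       raw = raw)
}

#' Locate the dominant peak of an aggregate amplitude spectrum
#'
#' Local maxima (strictly above both neighbours; plateaus take their
#' leftmost point) are identified in the smoothed aggregate; the largest is
#' the dominant peak. Prominence is measured by the standard
#' highest-connecting-saddle definition, width at half prominence by linear
#' interpolation. `AMPLITUDE_MM` is read from the raw (pre-smoothing)
#' aggregate in the peak's neighbourhood so that the reported amplitude is
#' not biased low by smoothing of narrow spectral lines.
#'
#' @param freqs Frequency grid, Hz.
#' @param aggregate Smoothed aggregate amplitude spectrum, mm.
#' @param raw Optional pre-smoothing aggregate; defaults to `aggregate`.
#' @param control An [a2_control()].
#' @return One-row data frame: `F_CENTER` (Hz), `AMPLITUDE_MM`,
#'   `PROMINENCE` (mm), `WIDTH` (Hz), `valid_peak`.
#' @export
find_dominant_peak <- function(freqs, aggregate, raw = NULL,
                               control = a2_control()) {
  if (is.list(freqs) && !is.null(freqs$aggregate)) {
    raw <- freqs$raw
    aggregate <- freqs$aggregate
    freqs <- freqs$freq
  }
  if (is.null(raw)) raw <- aggregate
  y <- aggregate
  n <- length(y)
  invalid <- data.frame(F_CENTER = NA_real_, AMPLITUDE_MM = NA_real_,
                        PROMINENCE = NA_real_, WIDTH = NA_real_,
                        valid_peak = FALSE)
  if (n < 3L) return(invalid)
  # local maxima; plateaus contribute their leftmost sample
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L
      if (j < n && y[j + 1L] < y[j]) peaks <- c(peaks, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(peaks)) return(invalid)
  ipk <- peaks[which.max(y[peaks])]
  h <- y[ipk]
  # prominence: walk out until a higher sample (or the edge); base = minimum
  side_min <- function(dir) {
    j <- ipk
    lo <- h
    repeat {
      j <- j + dir
      if (j < 1L || j > n) break
      if (y[j] > h) break
      lo <- min(lo, y[j])
    }
    lo
  }
  prom <- h - max(side_min(-1L), side_min(+1L))
  ref <- h - prom / 2
  half_cross <- function(dir) {
    j <- ipk
    repeat {
      nxt <- j + dir
      if (nxt < 1L || nxt > n || y[nxt] > h) return(freqs[j])
      if (y[nxt] <= ref) {
        frac <- (y[j] - ref) / (y[j] - y[nxt])
        return(freqs[j] + frac * (freqs[nxt] - freqs[j]))
      }
      j <- nxt
    }
  }
  width <- half_cross(+1L) - half_cross(-1L)
  nb <- max(1L, (control$smooth_window - 1L) %/% 2L)
  win <- max(1L, ipk - nb):min(n, ipk + nb)
  data.frame(F_CENTER = freqs[ipk],
             AMPLITUDE_MM = max(h, max(raw[win])),
             PROMINENCE = prom, WIDTH = width, valid_peak = TRUE)
}

# Full A2 extraction for one extremity recording.
a2_features_extremity <- function(er, control = a2_control()) {
  stopifnot(inherits(er, "extremity_recording"))
  filt <- highpass_displacement(er$data, er$frame_rate, control)
  spectra <- lapply(seq_len(ncol(filt)), function(j) {
    single_sided_amplitude_spectrum(filt[, j], er$frame_rate)
  })
  agg <- aggregate_max_spectrum(spectra, control)
  find_dominant_peak(agg$freq, agg$aggregate, raw = agg$raw, control)
}

#' Rule-based amplitude-peak classification
#'
#' Tremor is declared present when the dominant aggregate-spectrum peak is
#' valid, centred within 3.5--10 Hz (inclusive; peaks strictly below
#' 3.5 Hz or above 10 Hz are considered non-neurologic), and at least
#' 0.1 mm in amplitude.
#'
#' @param features One-row data frame from [find_dominant_peak()], or an
#'   [extremity_recording()] to run the full extraction on.
#' @param control An [a2_control()].
#' @return `"present"` or `"absent"`.
#' @export
classify_a2r <- function(features, control = a2_control()) {
  if (inherits(features, "extremity_recording")) {
    features <- a2_features_extremity(features, control)
  }
  ok <- features$valid_peak &
    !is.na(features$F_CENTER) &
    features$F_CENTER >= control$f_range[1L] &
    features$F_CENTER <= control$f_range[2L] &
    features$AMPLITUDE_MM >= control$amp_min_mm
  ifelse(ok, "present", "absent")
}
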