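# Velocity spectral peak pipeline ("A1"): zero-phase low-pass, Savitzky-Golay
# differentiation, Welch PSD combined across axes by Euclidean norm, 3 dB
# peak descriptors, rule-based classification with winner-take-all
# aggregation across the markers of an extremity.

#' Control parameters for the velocity spectral peak pipeline
#'
#' @param lowpass_hz Zero-phase Butterworth low-pass corner (Hz) applied
#'   before differentiation.
#' @param lowpass_order Butterworth order (applied forward-backward).
#' @param sg_order,sg_window Savitzky-Golay derivative filter polynomial
#'   order and window length (samples; ~92 ms at 120 Hz).
#' @param welch_nperseg Welch segment length cap (samples, 50% overlap,
#'   Hamming window).
#' @param psd_smooth_window Savitzky-Golay window (bins, order 3) applied to
#'   the log-scaled combined PSD.
#' @param band Peak search band (Hz). The lower edge keeps voluntary
#'   movement energy (< 3 Hz) from ever forming the in-band maximum; the
#'   upper edge excludes marker-jitter-dominated frequencies.
#' @param bw_max_hz Widest acceptable 3 dB bandwidth (Hz); a neurologic
#'   tremor peak is narrow.
#' @param symmetry_tol_db Largest acceptable |left - right| border power
#'   difference (dB); a tremor peak is symmetric.
#' @param f_center_max_hz Highest plausible tremor center frequency (Hz).
#' @return List of class `"a1_control"`.
#' @export
a1_control <- function(lowpass_hz = 20, lowpass_order = 4L,
                       sg_order = 3L, sg_window = 11L,
                       welch_nperseg = 512L, psd_smooth_window = 9L,
                       band = c(3.5, 20), bw_max_hz = 2,
                       symmetry_tol_db = 3, f_center_max_hz = 10) {
  structure(list(lowpass_hz = lowpass_hz, lowpass_order = lowpass_order,
                 sg_order = sg_order, sg_window = sg_window,
                 welch_nperseg = welch_nperseg,
                 psd_smooth_window = psd_smooth_window, band = band,
                 bw_max_hz = bw_max_hz, symmetry_tol_db = symmetry_tol_db,
                 f_center_max_hz = f_center_max_hz),
            class = "a1_control")
}

#' Estimate smooth marker velocity
#'
#' Zero-phase (forward-backward) Butterworth low-pass at 20 Hz, mean
#' centring, then a Savitzky-Golay derivative filter, per axis. The
#' forward-backward filtering cancels phase delay, so velocity estimates
#' are not lagged relative to the trajectory.
#'
#' @param trajectory Numeric vector or frames x axes matrix of positions, mm.
#' @param frame_rate Hz.
#' @param control An [a1_control()].
#' @return Velocity in mm/s, same shape as the input.
#' @export
estimate_velocity <- function(trajectory, frame_rate, control = a1_control()) {
  x <- as.matrix(trajectory)
  if (any(!is.finite(x))) stop("trajectory contains non-finite values")
  if (nrow(x) < 3L * (control$lowpass_order + 1L) ||
      nrow(x) < control$sg_window) {
    stop("signal too short for velocity estimation")
  }
  bf <- signal::butter(control$lowpass_order,
                       control$lowpass_hz / (frame_rate / 2), type = "low")
  pad <- ceiling(3 * frame_rate / control$lowpass_hz)
  out <- apply(x, 2L, function(col) {
    m <- mean(col)
    sm <- zerophase_filter(bf, col - m, pad)
    sm <- sm - mean(sm)
    signal::sgolayfilt(sm, p = control$sg_order, n = control$sg_window,
                       m = 1L, ts = 1 / frame_rate)
  })
  if (is.null(dim(trajectory))) as.numeric(out) else out
}

#' Combined velocity power spectral density
#'
#' Welch PSD per axis (Hamming window, 50% overlap), combined across the
#' three axes by the Euclidean norm of the per-axis densities, then
#' log-scaled, Savitzky-Golay smoothed, and returned on the linear scale.
#'
#' @param velocity_xyz Frames x 3 matrix of axis velocities (mm/s).
#' @param frame_rate Hz.
#' @param control An [a1_control()].
#' @return List `freq` (Hz), `psd` (combined, smoothed, linear), `enbw`
#'   (window equivalent noise bandwidth, Hz).
#' @export
combined_velocity_psd <- function(velocity_xyz, frame_rate,
                                  control = a1_control()) {
  v <- as.matrix(velocity_xyz)
  if (ncol(v) != 3L) stop("expected three axis velocity signals")
  nseg <- min(control$welch_nperseg, nrow(v))
  per_axis <- lapply(seq_len(3L), function(a) {
    welch_psd(v[, a], frame_rate, nperseg = nseg)
  })
  p <- sqrt(Reduce(`+`, lapply(per_axis, function(w) w$psd^2)))
  p <- smooth_log_psd(p, p = 3L, n = control$psd_smooth_window)
  list(freq = per_axis[[1L]]$freq, psd = p, enbw = per_axis[[1L]]$enbw)
}

#' Extract velocity-domain spectral peak features
#'
#' Locates the maximum of the combined velocity PSD inside the analysis
#' band and measures the Table-style descriptor set: center frequency, 3 dB
#' borders and bandwidth, border power levels, fraction of total power
#' inside the 3 dB band, and a sinusoid-equivalent velocity amplitude
#' `sqrt(2 * P_peak * ENBW)`. The peak is invalid when either 3 dB crossing
#' does not exist (flat spectra, band-edge maxima, peaks shadowed by larger
#' out-of-band energy).
#'
#' `LO_POWER`/`HI_POWER` are the PSD levels (dB) at mirrored offsets of one
#' full 3 dB bandwidth below/above the interpolated band midpoint
#' `(LO_F + HI_F) / 2` (the midpoint tracks the true line centre even when
#' it falls between frequency bins). For a symmetric peak the two levels
#' match; a peak riding on a one-sided low-frequency shoulder shows a large
#' difference, which is what the symmetry rule penalises.
#'
#' @param freqs,psd Frequency grid (Hz) and linear PSD, e.g. from
#'   [combined_velocity_psd()].
#' @param enbw Equivalent noise bandwidth (Hz) of the PSD window; defaults
#'   to the grid spacing when unknown.
#' @param control An [a1_control()].
#' @return One-row data frame with columns `F_CENTER`, `AMPLITUDE_MM_P_S`,
#'   `BW`, `HI_F`, `LO_F`, `MAX_POWER`, `HI_POWER`, `LO_POWER`,
#'   `RELATIVE_POWER` (dB where noted), and `valid_peak`.
#' @export
extract_a1_features <- function(freqs, psd, enbw = NULL,
                                control = a1_control()) {
  if (is.list(freqs) && !is.null(freqs$psd)) {
    if (is.null(enbw)) enbw <- freqs$enbw
    psd <- freqs$psd
    freqs <- freqs$freq
  }
  if (is.null(enbw)) enbw <- median(diff(freqs))
  invalid <- data.frame(F_CENTER = NA_real_, AMPLITUDE_MM_P_S = NA_real_,
                        BW = NA_real_, HI_F = NA_real_, LO_F = NA_real_,
                        MAX_POWER = NA_real_, HI_POWER = NA_real_,
                        LO_POWER = NA_real_, RELATIVE_POWER = NA_real_,
                        valid_peak = FALSE)
  in_band <- which(freqs >= control$band[1L] & freqs <= control$band[2L])
  if (!length(in_band) || all(psd[in_band] <= 0)) return(invalid)
  ipk <- in_band[which.max(psd[in_band])]
  peak <- psd[ipk]
  thresh <- peak * 10^(-3 / 10) # 3 dB below the peak
  cross <- function(dir) {
    j <- ipk
    repeat {
      j <- j + dir
      if (j < 1L || j > length(psd)) return(NULL)
      if (psd[j] > peak) return(NULL) # shadowed by larger out-of-band energy
      if (psd[j] < thresh) {
        # interpolate the crossing frequency on the dB scale
        j0 <- j - dir
        l0 <- 10 * log10(max(psd[j0], .Machine$double.xmin))
        l1 <- 10 * log10(max(psd[j], .Machine$double.xmin))
        ltgt <- 10 * log10(thresh)
        frac <- (l0 - ltgt) / (l0 - l1)
        return(freqs[j0] + frac * (freqs[j] - freqs[j0]))
      }
    }
  }
  lo_f <- cross(-1L)
  hi_f <- cross(+1L)
  if (is.null(lo_f) || is.null(hi_f)) return(invalid)
  db <- 10 * log10(pmax(psd, .Machine$double.xmin))
  db_at <- function(f) {
    f <- min(max(f, freqs[1L]), freqs[length(freqs)])
    approx(freqs, db, xout = f)$y
  }
  f_mid <- (lo_f + hi_f) / 2
  d <- hi_f - lo_f
  seg <- freqs >= lo_f & freqs <= hi_f
  band_x <- c(lo_f, freqs[seg], hi_f)
  band_y <- c(thresh, psd[seg], thresh)
  rel <- trapz(band_x, band_y) / trapz(freqs, psd)
  data.frame(
    F_CENTER = freqs[ipk],
    AMPLITUDE_MM_P_S = sqrt(2 * peak * enbw),
    BW = hi_f - lo_f, HI_F = hi_f, LO_F = lo_f,
    MAX_POWER = 10 * log10(peak),
    HI_POWER = db_at(f_mid + d), LO_POWER = db_at(f_mid - d),
    RELATIVE_POWER = min(max(rel, 0), 1),
    valid_peak = TRUE)
}

# Per-marker A1 features for every marker of an extremity recording.
a1_marker_features <- function(er, control = a1_control()) {
  stopifnot(inherits(er, "extremity_recording"))
  rows <- lapply(seq_along(er$marker_names), function(i) {
    v <- estimate_velocity(er$data[, marker_cols(i), drop = FALSE],
                           er$frame_rate, control)
    w <- combined_velocity_psd(v, er$frame_rate, control)
    cbind(marker_name = er$marker_names[i],
          extract_a1_features(w$freq, w$psd, enbw = w$enbw, control))
  })
  do.call(rbind, rows)
}

# Rule applied to one or more feature rows; returns logical per row.
a1_rule_pass <- function(features, control = a1_control()) {
  with(features,
       valid_peak &
         !is.na(BW) & BW <= control$bw_max_hz &
         !is.na(HI_POWER) & abs(HI_POWER - LO_POWER) <= control$symmetry_tol_db &
         !is.na(F_CENTER) & F_CENTER <= control$f_center_max_hz)
}

#' Rule-based velocity-peak classification (winner-take-all)
#'
#' Applies the clinical rule set to each marker's features -- a valid,
#' narrow (3 dB bandwidth <= 2 Hz), symmetric (border powers within 3 dB)
#' peak centred at <= 10 Hz -- and declares the extremity tremor-present if
#' any marker passes. The features of the passing marker with the largest
#' tremor amplitude represent the extremity; on exact amplitude ties the
#' first marker wins.
#'
#' @param features Data frame of per-marker feature rows, e.g. from the
#'   extractor behind [tremor_features()], or an [extremity_recording()].
#' @param control An [a1_control()].
#' @return List with `label` (`"present"`/`"absent"`) and `representative`
#'   (one feature row).
#' @export
classify_a1r <- function(features, control = a1_control()) {
  if (inherits(features, "extremity_recording")) {
    features <- a1_marker_features(features, control)
  }
  if (!nrow(features)) stop("no marker features supplied")
  pass <- a1_rule_pass(features, control)
  pick <- function(rows) {
    amp <- features$AMPLITUDE_MM_P_S[rows]
    amp[is.na(amp)] <- -Inf
    rows[which.max(amp)] # which.max takes the first maximum: deterministic ties
  }
  if (any(pass)) {
    rep_row <- pick(which(pass))
    label <- "present"
  } else if (any(features$valid_peak)) {
    rep_row <- pick(which(features$valid_peak))
    label <- "absent"
  } else {
    rep_row <- 1L
    label <- "absent"
  }
  list(label = label, representative = features[rep_row, , drop = FALSE])
}
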