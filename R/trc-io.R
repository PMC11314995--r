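# TRC (tab-separated motion-capture export) and per-extremity CSV I/O.
#
# The TRC dialect implemented is the common optical motion-capture layout:
#   line 1  PathFileType <tab> 4 <tab> (X/Y/Z) <tab> <file name>
#   line 2  header keys  (DataRate CameraRate NumFrames NumMarkers Units ...)
#   line 3  header values
#   line 4  Frame# <tab> Time <tab> <marker name> <tab> <tab> <tab> ...
#   line 5  <tab> <tab> X1 Y1 Z1 X2 Y2 Z2 ...
#   line 6  blank
#   data    Frame# Time x y z x y z ... (positions in mm, or m converted on read)
# Trailing blank columns are tolerated; empty cells are read as gaps (NA).

#' Read a TRC motion-capture file
#'
#' Parses the tab-separated TRC layout described in the package vignette,
#' converts positions to mm (respecting the `Units` header), and optionally
#' fills short marker drop-out gaps by linear interpolation. Markers with a
#' gap longer than `max_gap_s` are dropped with a warning.
#'
#' @param path Path to a `.trc` file.
#' @param interpolate Fill gaps up to `max_gap_s` seconds (default `TRUE`).
#' @param max_gap_s Longest gap, in seconds, that is interpolated rather than
#'   causing the marker to be rejected. Default 0.25 s.
#' @return A [recording()].
#' @export
read_trc <- function(path, interpolate = TRUE, max_gap_s = 0.25) {
  if (!file.exists(path)) stop("file not found: ", path)
  head_lines <- readLines(path, n = 6L)
  if (length(head_lines) < 6L || !startsWith(head_lines[1L], "PathFileType")) {
    stop("malformed TRC header in ", path)
  }
  keys <- strsplit(head_lines[2L], "\t", fixed = TRUE)[[1L]]
  vals <- strsplit(head_lines[3L], "\t", fixed = TRUE)[[1L]]
  if (length(vals) < 5L || !("DataRate" %in% keys)) {
    stop("malformed TRC header: expected DataRate/.../Units line")
  }
  frame_rate <- as.numeric(vals[match("DataRate", keys)])
  n_markers <- as.integer(vals[match("NumMarkers", keys)])
  units <- vals[match("Units", keys)]
  if (!is.finite(frame_rate) || frame_rate <= 0) {
    stop("malformed TRC header: bad DataRate")
  }
  marker_row <- strsplit(head_lines[4L], "\t", fixed = TRUE)[[1L]]
  marker_names <- marker_row[-(1:2)]
  marker_names <- marker_names[nzchar(marker_names)]
  if (is.na(n_markers) || length(marker_names) != n_markers) {
    stop("malformed TRC header: NumMarkers disagrees with marker name row")
  }

  ncol_expect <- 2L + 3L * n_markers
  fields <- count.fields(path, sep = "\t", skip = 6L, blank.lines.skip = TRUE)
  if (any(fields < ncol_expect)) stop("ragged TRC data rows in ", path)
  dat <- read.table(path, sep = "\t", skip = 6L, header = FALSE,
                    blank.lines.skip = TRUE, fill = TRUE,
                    colClasses = "character")
  if (ncol(dat) > ncol_expect) {
    extra <- dat[, (ncol_expect + 1L):ncol(dat), drop = FALSE]
    if (any(nzchar(trimws(unlist(extra))))) {
      stop("ragged TRC data rows in ", path)
    }
    dat <- dat[, seq_len(ncol_expect), drop = FALSE]
  }
  num <- suppressWarnings(
    vapply(dat[, -(1:2), drop = FALSE],
           function(col) { col[!nzchar(col)] <- NA; as.numeric(col) },
           numeric(nrow(dat))))
  bad <- !is.na(as.matrix(dat[, -(1:2)])) & nzchar(as.matrix(dat[, -(1:2)])) & is.na(num)
  if (any(bad)) stop("non-numeric cell in TRC data block of ", path)
  num <- matrix(num, nrow = nrow(dat))
  if (!is.null(units) && !is.na(units) && tolower(units) == "m") {
    num <- num * 1000
  }
  rec <- recording(num, frame_rate, marker_names,
                   trial_id = sub("\\.trc$", "", basename(path),
                                  ignore.case = TRUE))
  message(sprintf("read_trc: %s: %d rows x %d kinematic columns at %g Hz",
                  basename(path), nrow(num), ncol(num), frame_rate))
  if (interpolate) rec <- interpolate_gaps(rec, max_gap_s = max_gap_s)
  else if (any(is.na(rec$data))) warning("recording contains unfilled gaps (NA)")
  rec
}

#' Write a recording to a TRC file
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @param digits Decimal digits for positions (default 8: roundtrip error
#'   well under the documented 1e-6 mm tolerance).
#' @return `path`, invisibly.
#' @export
write_trc <- function(rec, path, digits = 8L) {
  stopifnot(inherits(rec, "recording"))
  if (length(rec$marker_names) < 1L) stop("recording has no markers")
  n <- nrow(rec$data)
  m <- length(rec$marker_names)
  hdr <- c(
    paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t"),
    paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
          "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames", sep = "\t"),
    paste(format(rec$frame_rate), format(rec$frame_rate), n, m, "mm",
          format(rec$frame_rate), 1L, n, sep = "\t"),
    paste(c("Frame#", "Time",
            as.vector(rbind(rec$marker_names, "", ""))), collapse = "\t"),
    paste(c("", "", as.vector(t(outer(seq_len(m), c("X", "Y", "Z"),
                                      function(i, a) paste0(a, i))))),
          collapse = "\t"),
    "")
  t_col <- sprintf("%.5f", (seq_len(n) - 1L) / rec$frame_rate)
  coords <- matrix(formatC(rec$data, format = "f", digits = digits),
                   nrow = n)
  coords[is.na(rec$data)] <- ""
  body <- do.call(paste, c(list(seq_len(n), t_col),
                           as.data.frame(coords, stringsAsFactors = FALSE),
                           sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Fill short marker gaps by linear interpolation
#'
#' Gaps (NA runs) no longer than `max_gap_s` are filled linearly (edge gaps
#' by nearest-value extension); markers with any longer gap are removed from
#' the recording with a warning. Delivered clinical exports are assumed
#' complete; this guards synthetic or degraded inputs.
#'
#' @param rec A [recording()] or [extremity_recording()].
#' @param max_gap_s Maximum interpolatable gap in seconds.
#' @return The recording with gaps filled and/or markers dropped.
#' @export
interpolate_gaps <- function(rec, max_gap_s = 0.25) {
  max_gap <- max(1L, round(max_gap_s * rec$frame_rate))
  n <- nrow(rec$data)
  keep <- rep(TRUE, length(rec$marker_names))
  for (i in seq_along(rec$marker_names)) {
    cols <- marker_cols(i)
    for (j in cols) {
      x <- rec$data[, j]
      if (!anyNA(x)) next
      r <- rle(is.na(x))
      if (any(r$values & r$lengths > max_gap) || all(is.na(x))) {
        keep[i] <- FALSE
        break
      }
      ok <- which(!is.na(x))
      rec$data[, j] <- approx(ok, x[ok], xout = seq_len(n), rule = 2)$y
    }
  }
  if (!all(keep)) {
    warning("dropping marker(s) with gaps > ", max_gap_s, " s: ",
            paste(rec$marker_names[!keep], collapse = ", "))
    cols <- unlist(lapply(which(keep), marker_cols))
    rec$data <- rec$data[, cols, drop = FALSE]
    rec$marker_names <- rec$marker_names[keep]
    if (length(rec$marker_names) == 0L) stop("all markers rejected for gaps")
  }
  rec
}

#' Write an extremity recording to CSV
#'
#' Layout: `Frame`, `Time` (s), then `<marker>_X`, `<marker>_Y`,
#' `<marker>_Z` columns in mm.
#'
#' @param er An [extremity_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_extremity_csv <- function(er, path) {
  stopifnot(inherits(er, "extremity_recording"))
  n <- nrow(er$data)
  df <- data.frame(Frame = seq_len(n), Time = (seq_len(n) - 1L) / er$frame_rate)
  kin <- as.data.frame(er$data)
  names(kin) <- as.vector(t(outer(er$marker_names, c("X", "Y", "Z"), paste,
                                  sep = "_")))
  write.csv(cbind(df, kin), path, row.names = FALSE)
  invisible(path)
}

#' Read a per-extremity CSV
#'
#' Expects the layout written by [write_extremity_csv()]. The frame rate is
#' recovered from the `Time` column. The extremity name is taken from
#' `extremity`, or failing that from a `_<Extremity>.csv` file-name suffix.
#'
#' @param path Path to the CSV file.
#' @param extremity Extremity name; one of [tremor_extremities()].
#' @param label Optional `"present"`/`"absent"` annotation to attach.
#' @return An [extremity_recording()].
#' @export
read_extremity_csv <- function(path, extremity = NULL, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  if (!all(c("Frame", "Time") %in% names(df))) {
    stop("missing required Frame/Time columns in ", path)
  }
  kin_names <- setdiff(names(df), c("Frame", "Time"))
  if (length(kin_names) < 3L || length(kin_names) %% 3L != 0L) {
    stop("expected marker X/Y/Z column triplets in ", path)
  }
  kin <- df[, kin_names, drop = FALSE]
  if (!all(vapply(kin, is.numeric, logical(1L)))) {
    stop("non-numeric cell in kinematic columns of ", path)
  }
  dt <- median(diff(df$Time))
  if (!is.finite(dt) || dt <= 0) stop("cannot infer frame rate from Time column")
  marker_names <- unique(sub("_[XYZ]$", "", kin_names))
  if (length(marker_names) != length(kin_names) / 3L) {
    stop("marker columns of ", path, " are not _X/_Y/_Z triplets")
  }
  if (is.null(extremity)) {
    stem <- sub("\\.csv$", "", basename(path), ignore.case = TRUE)
    hit <- tremor_extremities()[vapply(
      tremor_extremities(),
      function(e) grepl(paste0("(^|_)", e, "$"), stem, ignore.case = TRUE),
      logical(1L))]
    if (length(hit) != 1L) {
      stop("cannot infer extremity from file name; pass `extremity`")
    }
    extremity <- hit
  }
  message(sprintf("read_extremity_csv: %s: %d rows x %d kinematic columns",
                  basename(path), nrow(kin), ncol(kin)))
  extremity_recording(as.matrix(kin), frame_rate = 1 / dt,
                      extremity = extremity,
                      marker_names = marker_names, label = label,
                      trial_id = sub("\\.csv$", "", basename(path),
                                     ignore.case = TRUE))
}
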