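# Container classes for full-body and per-extremity marker trajectories.
# Positions are millimetres throughout; time runs in frames at `frame_rate` Hz.

#' The 16 extremity names used for annotation and marker grouping
#'
#' Closed vocabulary of body extremities to which markers and tremor
#' annotations are assigned: head, shoulders, thorax, pelvis, and
#' left/right hand, distal/proximal arm, foot, distal/proximal leg.
#'
#' @return Character vector of length 16.
#' @export
#' @examples
#' tremor_extremities()
tremor_extremities <- function() {
  c("Head", "Shoulders", "Thorax", "Pelvis",
    "L_Dist_Arm", "R_Dist_Arm", "L_Hand", "R_Hand",
    "L_Prox_Arm", "R_Prox_Arm",
    "L_Dist_Leg", "R_Dist_Leg", "L_Foot", "R_Foot",
    "L_Prox_Leg", "R_Prox_Leg")
}

#' Construct a full-body recording
#'
#' A recording holds the trajectories of all markers of one motion-capture
#' trial: a numeric matrix with one row per frame and three columns
#' (x, y, z, in mm) per marker.
#'
#' @param data Numeric matrix, frames x (3 * number of markers), mm.
#' @param frame_rate Sampling rate in Hz (positive scalar).
#' @param marker_names Character vector of marker names, one per column
#'   triplet, in column order.
#' @param trial_id,task_code Identifier strings carried through to outputs.
#' @return An object of class `"recording"`.
#' @seealso [read_trc()], [split_by_extremity()], [simulate_recording()]
#' @export
recording <- function(data, frame_rate, marker_names,
                      trial_id = "trial", task_code = "") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (frame_rate <= 0) stop("`frame_rate` must be positive")
  if (length(marker_names) < 1L) stop("a recording needs at least one marker")
  if (ncol(data) != 3L * length(marker_names)) {
    stop("column count (", ncol(data), ") must equal 3 x marker count (",
         3L * length(marker_names), ")")
  }
  structure(
    list(data = data, frame_rate = as.numeric(frame_rate),
         marker_names = as.character(marker_names),
         trial_id = trial_id, task_code = task_code),
    class = "recording")
}

#' Construct a per-extremity recording
#'
#' The subset of marker trajectories belonging to one named extremity,
#' optionally carrying its binary tremor label.
#'
#' @inheritParams recording
#' @param extremity One of [tremor_extremities()].
#' @param label Optional `"present"` or `"absent"`.
#' @return An object of class `"extremity_recording"`.
#' @export
extremity_recording <- function(data, frame_rate, extremity, marker_names,
                                label = NULL, trial_id = "trial") {
  extremity <- match.arg(extremity, tremor_extremities())
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (frame_rate <= 0) stop("`frame_rate` must be positive")
  if (length(marker_names) < 1L) stop("an extremity needs at least one marker")
  if (ncol(data) != 3L * length(marker_names)) {
    stop("column count must equal 3 x marker count")
  }
  if (!is.null(label)) label <- match.arg(label, c("present", "absent"))
  structure(
    list(extremity = extremity, data = data,
         frame_rate = as.numeric(frame_rate),
         marker_names = as.character(marker_names),
         label = label, trial_id = trial_id),
    class = "extremity_recording")
}

# Column indices of marker i within a trajectory block.
marker_cols <- function(i) (3L * (i - 1L) + 1L):(3L * i)

#' @export
print.recording <- function(x, ...) {
  cat("<recording> ", x$trial_id,
      if (nzchar(x$task_code)) paste0(" (", x$task_code, ")"), "\n", sep = "")
  cat(sprintf("  %d frames at %g Hz (%.2f s), %d markers\n",
              nrow(x$data), x$frame_rate, nrow(x$data) / x$frame_rate,
              length(x$marker_names)))
  invisible(x)
}

#' @export
print.extremity_recording <- function(x, ...) {
  cat("<extremity_recording> ", x$extremity, ", trial ", x$trial_id, "\n",
      sep = "")
  cat(sprintf("  %d frames at %g Hz (%.2f s), %d marker(s): %s\n",
              nrow(x$data), x$frame_rate, nrow(x$data) / x$frame_rate,
              length(x$marker_names),
              paste(x$marker_names, collapse = ", ")))
  cat("  label:", if (is.null(x$label)) "<none>" else x$label, "\n")
  invisible(x)
}
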