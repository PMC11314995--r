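# Marker-to-extremity grouping and annotation label mapping.

#' Default 60-marker montage mapped to the 16 extremities
#'
#' The full clinical marker set is site-specific and not published; this
#' default is an illustrative full-body montage of 60 markers covering all
#' 16 extremities (it includes the documented hand markers `R.Wrist`,
#' `R.Thumb.M3`, `R.Finger3.M3`). Supply your own map (e.g. via
#' [read_marker_map()]) to match a local montage.
#'
#' @return Named character vector: names are marker names, values are
#'   extremity names from [tremor_extremities()].
#' @export
default_marker_map <- function() {
  side <- function(s) {
    c(setNames(rep(paste0(s, "_Prox_Arm"), 4L),
               paste0(s, c(".Bicep", ".Tricep", ".Elbow", ".Elbow.Med"))),
      setNames(rep(paste0(s, "_Dist_Arm"), 3L),
               paste0(s, c(".Forearm", ".Wrist.Lat", ".Wrist.Med"))),
      setNames(rep(paste0(s, "_Hand"), 4L),
               paste0(s, c(".Wrist", ".Thumb.M3", ".Finger3.M3", ".Finger5.M3"))),
      setNames(rep(paste0(s, "_Prox_Leg"), 4L),
               paste0(s, c(".Thigh", ".Thigh.Low", ".Knee", ".Knee.Med"))),
      setNames(rep(paste0(s, "_Dist_Leg"), 3L),
               paste0(s, c(".Shank", ".Ankle", ".Ankle.Med"))),
      setNames(rep(paste0(s, "_Foot"), 4L),
               paste0(s, c(".Heel", ".Toe", ".Foot.Lat", ".Foot.Med"))))
  }
  c(setNames(rep("Head", 4L), c("Top.Head", "Front.Head", "L.Head", "R.Head")),
    setNames(rep("Shoulders", 2L), c("L.Shoulder", "R.Shoulder")),
    setNames(rep("Thorax", 5L), c("C7", "T10", "Sternum", "L.Scapula", "R.Scapula")),
    setNames(rep("Pelvis", 5L), c("L.ASIS", "R.ASIS", "L.PSIS", "R.PSIS", "Sacrum")),
    side("L"), side("R"))
}

#' Read / write a marker map as YAML
#'
#' The YAML layout is one key per extremity with a list of marker names, as
#' shipped in `inst/extdata/marker_map.yaml`.
#'
#' @param path YAML file path.
#' @return `read_marker_map()`: a named character vector (marker ->
#'   extremity). `write_marker_map()`: `path`, invisibly.
#' @export
read_marker_map <- function(path) {
  y <- yaml::read_yaml(path)
  bad <- setdiff(names(y), tremor_extremities())
  if (length(bad)) stop("unknown extremity name(s) in marker map: ",
                        paste(bad, collapse = ", "))
  map <- unlist(lapply(names(y), function(e) setNames(rep(e, length(y[[e]])),
                                                      unlist(y[[e]]))))
  if (anyDuplicated(names(map))) {
    stop("marker assigned to more than one extremity: ",
         paste(unique(names(map)[duplicated(names(map))]), collapse = ", "))
  }
  map
}

#' @rdname read_marker_map
#' @param map Named character vector (marker -> extremity).
#' @export
write_marker_map <- function(map, path) {
  yaml::write_yaml(lapply(split(names(map), map), as.list)[
    intersect(tremor_extremities(), unique(map))], path)
  invisible(path)
}

#' Split a full-body recording into per-extremity recordings
#'
#' Groups the markers of a recording into extremities according to a marker
#' map. Markers without a mapping are excluded with a warning. Column order
#' within each extremity follows the input recording.
#'
#' @param rec A [recording()].
#' @param marker_map Named character vector (marker -> extremity); default
#'   [default_marker_map()].
#' @return Named list of [extremity_recording()] objects, one per extremity
#'   that received at least one marker.
#' @export
split_by_extremity <- function(rec, marker_map = default_marker_map()) {
  stopifnot(inherits(rec, "recording"))
  ext <- unname(marker_map[rec$marker_names])
  unmapped <- rec$marker_names[is.na(ext)]
  if (length(unmapped)) {
    warning("excluding unmapped marker(s): ", paste(unmapped, collapse = ", "))
  }
  groups <- intersect(tremor_extremities(), unique(ext[!is.na(ext)]))
  out <- lapply(groups, function(e) {
    idx <- which(!is.na(ext) & ext == e)
    extremity_recording(
      rec$data[, unlist(lapply(idx, marker_cols)), drop = FALSE],
      frame_rate = rec$frame_rate, extremity = e,
      marker_names = rec$marker_names[idx], trial_id = rec$trial_id)
  })
  names(out) <- groups
  out
}

# Clinician label vocabulary -> binary training label. Only "absent" and the
# dystonia/dyskinesia category dichotomise to absent; every size qualifier
# (including "other") indicates presence.
annotation_vocabulary <- function() {
  c("absent" = "absent",
    "dystonia, dyskinesia, or other abnormal posture or movement" = "absent",
    "present" = "present",
    "not much" = "present",
    "very slight or very trace" = "present",
    "slight or trace" = "present",
    "intermittent" = "present",
    "mild" = "present",
    "mild to moderate" = "present",
    "moderate" = "present",
    "moderate to severe" = "present",
    "significant" = "present",
    "severe" = "present",
    "other, or no indicator of size" = "present")
}

#' Map raw clinician annotations to binary tremor labels
#'
#' Deterministic, case-insensitive mapping from the closed 14-label clinical
#' vocabulary to `"present"`/`"absent"`. Dystonia/dyskinesia annotations map
#' to `"absent"`: those abnormal movements are explicitly not tremor.
#'
#' @param raw_label Character vector of raw annotation strings.
#' @return Character vector of `"present"`/`"absent"`.
#' @export
#' @examples
#' map_annotation(c("Absent", "Mild", "Severe"))
map_annotation <- function(raw_label) {
  vocab <- annotation_vocabulary()
  key <- tolower(trimws(gsub("\\s+", " ", raw_label)))
  hit <- vocab[key]
  if (anyNA(hit)) {
    stop("unrecognized annotation label(s): ",
         paste(unique(raw_label[is.na(hit)]), collapse = ", "),
         "\nValid labels: ", paste(names(vocab), collapse = "; "))
  }
  unname(hit)
}
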