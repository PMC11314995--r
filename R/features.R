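# Feature-matrix assembly shared by the trainable classifiers.

#' Engineered feature column names
#'
#' The engineered spectral descriptor sets of the velocity ("a1") and
#' amplitude ("a2") pipelines, in export order.
#'
#' @return Character vector of column names.
#' @export
a1_feature_names <- function() {
  c("F_CENTER", "AMPLITUDE_MM_P_S", "BW", "HI_F", "LO_F",
    "MAX_POWER", "HI_POWER", "LO_POWER", "RELATIVE_POWER")
}

#' @rdname a1_feature_names
#' @export
a2_feature_names <- function() {
  c("F_CENTER", "AMPLITUDE_MM", "PROMINENCE", "WIDTH")
}

feature_family <- function(pipeline) {
  switch(tolower(pipeline),
         a1r = , a1s = "a1",
         a2r = , a2s = "a2",
         b1 = , b2 = "b",
         stop("unknown pipeline: ", pipeline))
}

family_feature_names <- function(family) {
  switch(family,
         a1 = c(a1_feature_names(), "NO_PEAK"),
         a2 = c(a2_feature_names(), "NO_PEAK"),
         b = sprintf("f%.2f", (0:60) / 3),
         stop("unknown feature family: ", family))
}

#' Impute rows whose peak extraction failed
#'
#' Recordings in which no valid spectral peak exists still need a numeric
#' feature row for the SVM classifiers. Policy: undefined descriptor fields
#' become 0 and an indicator column `NO_PEAK` is set to 1, preserving the
#' rule information ("no peak found") without dropping rows.
#'
#' @param features Data frame containing engineered feature columns and a
#'   logical `valid_peak` column (or already-imputed rows).
#' @return The data frame with no missing values, a `NO_PEAK` column, and
#'   `valid_peak` removed.
#' @export
handle_invalid_features <- function(features) {
  if ("valid_peak" %in% names(features)) {
    features$NO_PEAK <- as.numeric(!features$valid_peak)
    features$valid_peak <- NULL
  } else if (!"NO_PEAK" %in% names(features)) {
    features$NO_PEAK <- 0
  }
  num <- vapply(features, is.numeric, logical(1L))
  features[num] <- lapply(features[num], function(col) {
    col[!is.finite(col)] <- 0
    col
  })
  features
}

#' Extract a feature matrix from recordings
#'
#' Runs one feature family over every recording of a dataset (or a plain
#' list of extremity recordings) and assembles the classifier input table.
#'
#' * family `"a1"`: the extremity's winner-take-all representative velocity
#'   peak descriptors (9 columns), a `NO_PEAK` indicator, and the
#'   rule verdict in `RULE_LABEL`.
#' * family `"a2"`: the dominant aggregate-spectrum peak descriptors
#'   (4 columns), `NO_PEAK`, and `RULE_LABEL`.
#' * family `"b"`: the 61-point smoothed PSD vector (`f0.00` .. `f20.00`).
#'
#' @param x A `"tremor_dataset"`, a list of [extremity_recording()]s, or a
#'   single [extremity_recording()].
#' @param family `"a1"`, `"a2"`, or `"b"` (a pipeline id such as `"a1s"`
#'   is also accepted).
#' @param control Optional [a1_control()] / [a2_control()] / [b_control()].
#' @return Data frame with `trial_id`, `extremity`, `label` (factor, may be
#'   all `NA` for unlabeled input), the feature columns, and for the
#'   engineered families `RULE_LABEL`.
#' @export
tremor_features <- function(x, family = c("a1", "a2", "b"), control = NULL) {
  if (length(family) == 1L && !family %in% c("a1", "a2", "b")) {
    family <- feature_family(family)
  }
  family <- match.arg(family)
  recs <- if (inherits(x, "tremor_dataset")) x$recordings
          else if (inherits(x, "extremity_recording")) list(x)
          else x
  stopifnot(length(recs) >= 1L,
            all(vapply(recs, inherits, TRUE, "extremity_recording")))
  if (is.null(control)) {
    control <- switch(family, a1 = a1_control(), a2 = a2_control(),
                      b = b_control())
  }
  rows <- lapply(recs, function(er) {
    if (family == "a1") {
      cl <- classify_a1r(er, control)
      feat <- cl$representative
      feat$marker_name <- NULL
      cbind(handle_invalid_features(feat), RULE_LABEL = cl$label)
    } else if (family == "a2") {
      feat <- a2_features_extremity(er, control)
      lab <- classify_a2r(feat, control)
      cbind(handle_invalid_features(feat), RULE_LABEL = lab)
    } else {
      as.data.frame(t(extremity_feature_vector(er, control)))
    }
  })
  out <- do.call(rbind, rows)
  meta <- data.frame(
    trial_id = vapply(recs, `[[`, "", "trial_id"),
    extremity = vapply(recs, `[[`, "", "extremity"),
    label = factor(vapply(recs, function(r) {
      if (is.null(r$label)) NA_character_ else r$label
    }, ""), levels = c("absent", "present")),
    stringsAsFactors = FALSE)
  out <- cbind(meta, out)
  rownames(out) <- NULL
  attr(out, "family") <- family
  out
}
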