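# The model-fitting surface: six pipelines behind one classed interface.

PIPELINES <- c("a1r", "a2r", "a1s", "a2s", "b1", "b2")

#' Fit a tremor detection pipeline
#'
#' The single entry point for all six pipelines:
#'
#' | id    | features                     | classifier                  |
#' |-------|------------------------------|-----------------------------|
#' | `a1r` | velocity peak (engineered)   | fixed clinical rules        |
#' | `a2r` | amplitude peak (engineered)  | fixed clinical rules        |
#' | `a1s` | velocity peak (engineered)   | SVM, RBF kernel             |
#' | `a2s` | amplitude peak (engineered)  | SVM, RBF kernel             |
#' | `b1`  | 61-point smoothed Welch PSD  | SVM (RBF; linear available) |
#' | `b2`  | 61-point smoothed Welch PSD  | XGBoost, logloss metric     |
#'
#' Rule pipelines need no training: fitting stores only the thresholds.
#' For the SVM pipelines, amplitude- and power-valued features are first
#' compressed to the log scale (the conventional dB representation --
#' spectral magnitudes span orders of magnitude and otherwise underfit an
#' RBF kernel at default cost), then all features are standardized with
#' training-set mean/sd (constant columns keep scale 1); hyperparameters
#' are library defaults (cost 1, `gamma = 1/d` on standardized features)
#' -- no tuning is performed.
#' XGBoost runs 100 rounds of depth-6 trees with the logloss evaluation
#' metric on a single thread, so refits are reproducible.
#'
#' @param data A `"tremor_dataset"`, a list of labeled
#'   [extremity_recording()]s, or a feature data frame from
#'   [tremor_features()] containing a `label` column.
#' @param pipeline One of `"a1r"`, `"a2r"`, `"a1s"`, `"a2s"`, `"b1"`, `"b2"`.
#' @param control Optional pipeline control object ([a1_control()],
#'   [a2_control()], [b_control()]).
#' @param kernel SVM kernel for `"b1"` (`"radial"` or `"linear"`).
#' @param threshold Decision threshold on the positive-class score.
#' @param seed Integer seed governing classifier randomness.
#' @return An object of class `"tremor_model"`.
#' @seealso [predict.tremor_model()], [cross_validate()]
#' @export
#' @examples
#' \donttest{
#' ds <- simulate_dataset(40, seed = 7)
#' fit <- tremor_fit(ds, "a2r")
#' table(predict(fit, ds), ds$labels)
#' }
tremor_fit <- function(data, pipeline = PIPELINES, control = NULL,
                       kernel = c("radial", "linear"), threshold = 0.5,
                       seed = 1L) {
  pipeline <- match.arg(tolower(pipeline[1L]), PIPELINES)
  kernel <- match.arg(kernel)
  family <- feature_family(pipeline)
  features <- if (is.data.frame(data)) data else tremor_features(data, family)
  if (!"label" %in% names(features) && !pipeline %in% c("a1r", "a2r")) {
    stop("training data must carry a `label` column")
  }
  if (is.null(control)) {
    control <- switch(family, a1 = a1_control(), a2 = a2_control(),
                      b = b_control())
  }
  feat_cols <- setdiff(family_feature_names(family), character(0))
  missing_cols <- setdiff(feat_cols, names(features))
  if (length(missing_cols)) {
    stop("feature schema mismatch; missing: ",
         paste(missing_cols, collapse = ", "))
  }
  model <- structure(
    list(pipeline = pipeline, family = family,
         model_kind = switch(pipeline,
                             a1r = "rule_a1r", a2r = "rule_a2r",
                             a1s = , a2s = "svm_rbf",
                             b1 = paste0("svm_", kernel), b2 = "xgboost"),
         control = control, feature_names = feat_cols,
         threshold = threshold, seed = as.integer(seed),
         standardize = NULL, fit = NULL),
    class = "tremor_model")
  if (pipeline %in% c("a1r", "a2r")) return(model)

  y <- droplevels(factor(features$label, levels = c("absent", "present")))
  if (nlevels(y) < 2L) stop("training labels contain a single class")
  y <- factor(features$label, levels = c("absent", "present"))
  X <- as.matrix(features[, feat_cols, drop = FALSE])
  if (any(!is.finite(X))) stop("non-finite features after imputation")
  if (pipeline %in% c("a1s", "a2s", "b1")) {
    model$log_cols <- switch(family,
                             a1 = "AMPLITUDE_MM_P_S",
                             a2 = c("AMPLITUDE_MM", "PROMINENCE"),
                             b = feat_cols)
    model$log_eps <- if (family == "b") 1e-12 else 1e-6
    X <- apply_log_cols(X, model$log_cols, model$log_eps)
  }
  mu <- colMeans(X)
  sig <- apply(X, 2L, sd)
  sig[sig == 0 | !is.finite(sig)] <- 1
  Xs <- scale(X, center = mu, scale = sig)
  model$standardize <- list(center = mu, scale = sig)
  set.seed(seed)
  if (pipeline == "b2") {
    dtrain <- xgboost::xgb.DMatrix(Xs, label = as.numeric(y == "present"))
    model$fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", eval_metric = "logloss",
                    max_depth = 6L, eta = 0.3, nthread = 1L,
                    seed = seed),
      data = dtrain, nrounds = 100L, verbose = 0L)
  } else {
    model$fit <- e1071::svm(
      Xs, y, kernel = if (pipeline == "b1") kernel else "radial",
      cost = 1, scale = FALSE)
  }
  model
}

#' Predict tremor presence
#'
#' @param object A `"tremor_model"`.
#' @param newdata A `"tremor_dataset"`, list of [extremity_recording()]s,
#'   single recording, or a feature data frame matching the training
#'   schema.
#' @param type `"class"` for `"present"`/`"absent"` labels (score >=
#'   threshold), `"prob"` for positive-class scores in \[0, 1\]. Rule models
#'   emit degenerate scores in \{0, 1\}.
#' @param ... Unused.
#' @return Factor of labels, or numeric score vector.
#' @export
predict.tremor_model <- function(object, newdata, type = c("class", "prob"),
                                 ...) {
  type <- match.arg(type)
  features <- if (is.data.frame(newdata)) newdata
              else tremor_features(newdata, object$family,
                                   control = object$control)
  missing_cols <- setdiff(object$feature_names, names(features))
  if (length(missing_cols)) {
    stop("feature schema mismatch; missing: ",
         paste(missing_cols, collapse = ", "))
  }
  if (object$pipeline %in% c("a1r", "a2r")) {
    score <- rule_scores(object, features)
  } else {
    X <- as.matrix(features[, object$feature_names, drop = FALSE])
    if (!is.null(object$log_cols)) {
      X <- apply_log_cols(X, object$log_cols, object$log_eps)
    }
    Xs <- scale(X, center = object$standardize$center,
                scale = object$standardize$scale)
    if (object$pipeline == "b2") {
      score <- as.numeric(predict(object$fit, Xs))
    } else {
      # logistic squash of the signed margin distance: monotone in the
      # decision value, so score >= 0.5 iff the SVM predicts "present"
      dv <- attr(predict(object$fit, Xs, decision.values = TRUE),
                 "decision.values")
      sgn <- if (grepl("^present", colnames(dv)[1L])) 1 else -1
      score <- stats::plogis(sgn * as.numeric(dv[, 1L]))
    }
  }
  if (type == "prob") return(score)
  factor(ifelse(score >= object$threshold, "present", "absent"),
         levels = c("absent", "present"))
}

# Log-compress nonnegative magnitude columns (dB-style representation).
apply_log_cols <- function(X, cols, eps) {
  X[, cols] <- log10(pmax(X[, cols, drop = FALSE], 0) + eps)
  X
}

# {0,1} scores from the fixed rule sets, computed on representative rows.
rule_scores <- function(model, features) {
  if (model$pipeline == "a1r") {
    f <- features
    f$valid_peak <- if ("NO_PEAK" %in% names(f)) f$NO_PEAK == 0 else TRUE
    as.numeric(a1_rule_pass(f, model$control))
  } else {
    f <- features
    f$valid_peak <- if ("NO_PEAK" %in% names(f)) f$NO_PEAK == 0 else TRUE
    as.numeric(classify_a2r(f, model$control) == "present")
  }
}

#' @export
print.tremor_model <- function(x, ...) {
  cat("<tremor_model> pipeline ", toupper(x$pipeline), " (", x$model_kind,
      ")\n", sep = "")
  cat("  features: ", length(x$feature_names), " [",
      paste(utils::head(x$feature_names, 4L), collapse = ", "),
      if (length(x$feature_names) > 4L) ", ...", "]\n", sep = "")
  cat("  threshold:", x$threshold, " seed:", x$seed, "\n")
  invisible(x)
}

#' @export
summary.tremor_model <- function(object, ...) {
  print(object)
  if (object$pipeline == "a1r") {
    ctl <- object$control
    cat(sprintf("  rules: BW <= %g Hz, |dP| <= %g dB, F_CENTER <= %g Hz, band %g-%g Hz\n",
                ctl$bw_max_hz, ctl$symmetry_tol_db, ctl$f_center_max_hz,
                ctl$band[1L], ctl$band[2L]))
  } else if (object$pipeline == "a2r") {
    ctl <- object$control
    cat(sprintf("  rules: %g <= F_CENTER <= %g Hz, AMPLITUDE >= %g mm\n",
                ctl$f_range[1L], ctl$f_range[2L], ctl$amp_min_mm))
  } else if (!is.null(object$fit) && inherits(object$fit, "svm")) {
    cat("  support vectors:", object$fit$tot.nSV, "\n")
  } else if (!is.null(object$fit)) {
    cat("  boosting rounds: 100\n")
  }
  invisible(object)
}

#' Save / load a fitted tremor model
#'
#' Serializes the model with a format-version stamp so saved models can be
#' rejected cleanly if the schema changes.
#'
#' @param model A `"tremor_model"`.
#' @param path File path (`.rds`).
#' @return `save_tremor_model()`: `path`, invisibly; `load_tremor_model()`:
#'   the model.
#' @export
save_tremor_model <- function(model, path) {
  stopifnot(inherits(model, "tremor_model"))
  saveRDS(list(format = "tremorkit-model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_tremor_model
#' @export
load_tremor_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "tremorkit-model") || obj$version != 1L) {
    stop("not a tremorkit model file: ", path)
  }
  obj$model
}
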