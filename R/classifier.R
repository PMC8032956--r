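#' Published operating characteristics of a rat-trained FIX classifier
#'
#' Per-threshold classification rates of a component classifier trained on
#' hand-labelled rat rs-fMRI ICA components: the percentage of components
#' called signal / artifact / unknown, and the artifact recall and
#' precision, at each classifier threshold. These reference rates drive
#' the dual-threshold review-fraction computation (the review share is the
#' difference of the artifact percentages at the aggressive and the
#' conservative threshold).
#'
#' @format `data.frame` with columns `threshold`, `signal_pct`,
#'   `artifact_pct`, `unknown_pct`, `recall_pct`, `precision_pct`.
#' @export
fix_reference_rates <- data.frame(
  threshold = c(20, 30, 40, 45, 50, 60, 70),
  signal_pct = c(44.9, 44.9, 44.9, 44.9, 44.9, 40.4, 36.2),
  artifact_pct = c(39.6, 43.9, 49.4, 52.7, 55.1, 59.6, 63.8),
  unknown_pct = c(15.5, 11.2, 5.7, 2.5, 0, 0, 0),
  recall_pct = c(69.8, 76.5, 83.3, 87.8, 89.7, 95.1, 98.5),
  precision_pct = c(100, 95.4, 91.6, 90.2, 86.5, 84.4, 82.2)
)

feature_columns <- c("n_clusters", "largest_cluster_frac", "supra_frac",
                     "rim_frac", "slice_conc", "low_band_frac", "peak_freq",
                     "kurtosis")

#' Train an artifact classifier on labeled component features
#'
#' A random-forest probability model over the [extract_features()] feature
#' set. The artifact score of a component is `100 * P(artifact)`.
#' Held-out performance (recall/precision of the artifact class at score
#' 50) is estimated by k-fold cross-validation before the final model is
#' fit on the full corpus.
#'
#' @param features `data.frame` of component features.
#' @param labels Factor with levels `signal` / `artifact` (both present,
#'   >= 10 exemplars each).
#' @param seed Integer seed (model fitting is deterministic given it).
#' @param n_folds Cross-validation folds (default 5).
#' @param ntree Trees in the forest.
#' @return An object of class `fix_classifier` with fields `model`,
#'   `cv_recall`, `cv_precision`, `n_train`, `seed`.
#' @export
train_classifier <- function(features, labels, seed, n_folds = 5,
                             ntree = 500) {
  if (missing(seed)) stop("train_classifier requires an explicit seed")
  labels <- factor(labels, levels = c("signal", "artifact"))
  if (nlevels(droplevels(labels)) < 2)
    stop("training corpus must contain both signal and artifact exemplars")
  if (any(table(labels) < 10))
    stop("need >= 10 exemplars per class")
  X <- features[, feature_columns, drop = FALSE]
  dup <- duplicated(X) | duplicated(X, fromLast = TRUE)
  if (any(dup)) {
    for (key in unique(apply(X[dup, , drop = FALSE], 1, paste, collapse = "|"))) {
      rows <- which(apply(X, 1, paste, collapse = "|") == key)
      if (length(unique(labels[rows])) > 1)
        warning("duplicated exemplars with conflicting labels; training proceeds")
    }
  }
  with_seed(seed, {
    fold <- sample(rep_len(seq_len(n_folds), nrow(X)))
    tp <- fp <- fn <- 0
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      if (nlevels(droplevels(labels[tr])) < 2) next
      m <- randomForest::randomForest(X[tr, , drop = FALSE], labels[tr],
                                      ntree = ntree)
      pr <- stats::predict(m, X[!tr, , drop = FALSE], type = "prob")[, "artifact"]
      pred_art <- pr >= 0.5
      true_art <- labels[!tr] == "artifact"
      tp <- tp + sum(pred_art & true_art)
      fp <- fp + sum(pred_art & !true_art)
      fn <- fn + sum(!pred_art & true_art)
    }
    model <- randomForest::randomForest(X, labels, ntree = ntree)
    structure(list(model = model,
                   cv_recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                   cv_precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                   n_train = nrow(X), seed = seed),
              class = "fix_classifier")
  })
}

#' Artifact scores for a set of components
#'
#' @param classifier A [train_classifier()] model.
#' @param features Feature `data.frame` from [extract_features()].
#' @return Numeric vector of artifact scores in `[0, 100]`.
#' @export
artifact_scores <- function(classifier, features) {
  stopifnot(inherits(classifier, "fix_classifier"))
  100 * stats::predict(classifier$model,
                       features[, feature_columns, drop = FALSE],
                       type = "prob")[, "artifact"]
}

#' Threshold-based component classification
#'
#' A component with score `s` is labelled `artifact` iff `s >= 100 -
#' threshold` (so raising the threshold can only grow the artifact set),
#' except that components within `unknown_band` of the decision boundary
#' are labelled `unknown`. Components with extreme scores (0 or 100) and
#' the boundary thresholds 0 / 100 are never `unknown`.
#'
#' @param classifier A [train_classifier()] model.
#' @param features Feature `data.frame`.
#' @param threshold Threshold in `[0, 100]`; larger = more aggressive.
#' @param unknown_band Half-width of the `unknown` score band (default 5).
#' @return An object of class `classification_result`: `scores`, `labels`
#'   (factor signal/unknown/artifact), `threshold`, `artifact_idx`.
#' @export
classify_components <- function(classifier, features, threshold,
                                unknown_band = 5) {
  if (threshold < 0 || threshold > 100) stop("threshold must lie in [0, 100]")
  s <- artifact_scores(classifier, features)
  cut <- 100 - threshold
  lab <- ifelse(s >= cut, "artifact", "signal")
  lab[abs(s - cut) < unknown_band & threshold > 0 & threshold < 100 &
        s > 0 & s < 100] <- "unknown"
  lab <- factor(lab, levels = c("signal", "unknown", "artifact"))
  structure(list(scores = s, labels = lab, threshold = threshold,
                 unknown_band = unknown_band,
                 artifact_idx = which(lab == "artifact")),
            class = "classification_result")
}

#' Dual-threshold review workflow
#'
#' The classifier is run at a conservative and an aggressive threshold;
#' components on which the two runs agree are auto-accepted, and only the
#' symmetric difference of the two artifact lists is queued for manual
#' review.
#'
#' @param classifier A [train_classifier()] model.
#' @param features Feature `data.frame`.
#' @param t_low,t_high The two thresholds, `t_low < t_high`.
#' @param unknown_band Passed to [classify_components()].
#' @return List with `auto_artifact` (flagged at both), `auto_signal`
#'   (flagged at neither), `review` (flagged at exactly one), and the two
#'   underlying [classify_components()] results.
#' @export
dual_threshold_review <- function(classifier, features, t_low = 20,
                                  t_high = 70, unknown_band = 5) {
  if (t_low >= t_high) stop("t_low must be below t_high")
  lo <- classify_components(classifier, features, t_low, unknown_band)
  hi <- classify_components(classifier, features, t_high, unknown_band)
  a_lo <- lo$artifact_idx
  a_hi <- hi$artifact_idx
  all_idx <- seq_len(nrow(features))
  list(auto_artifact = intersect(a_lo, a_hi),
       auto_signal = setdiff(all_idx, union(a_lo, a_hi)),
       review = sort(union(setdiff(a_lo, a_hi), setdiff(a_hi, a_lo))),
       low = lo, high = hi)
}

#' Recall and precision of an artifact classification
#'
#' Recall is the fraction of true artifact components detected; precision
#' the fraction of detections that are true artifacts. Empty truth or
#' prediction sets give an explicit `NA` with a flag rather than a silent
#' zero.
#'
#' @param predicted Integer indices predicted artifact.
#' @param truth Integer indices of true artifacts.
#' @param universe_size Number of components.
#' @return List with `recall`, `precision`, `recall_defined`,
#'   `precision_defined`, `tp`, `fp`, `fn`.
#' @export
evaluate_classification <- function(predicted, truth, universe_size) {
  predicted <- unique(as.integer(predicted))
  truth <- unique(as.integer(truth))
  if (any(c(predicted, truth) < 1) || any(c(predicted, truth) > universe_size))
    stop("indices must lie within 1..universe_size")
  tp <- length(intersect(predicted, truth))
  list(recall = if (length(truth)) tp / length(truth) else NA_real_,
       precision = if (length(predicted)) tp / length(predicted) else NA_real_,
       recall_defined = length(truth) > 0,
       precision_defined = length(predicted) > 0,
       tp = tp, fp = length(setdiff(predicted, truth)),
       fn = length(setdiff(truth, predicted)))
}

#' Manual-review percentage implied by per-threshold artifact rates
#'
#' In the dual-threshold workflow the review set is the difference of the
#' artifact lists at the aggressive and the conservative threshold, so its
#' expected share of components is the difference of the two artifact
#' fractions.
#'
#' @param artifact_pct_low,artifact_pct_high Percentage of components
#'   labelled artifact at the conservative / aggressive threshold.
#' @return Review percentage.
#' @export
review_fraction_pct <- function(artifact_pct_low, artifact_pct_high) {
  if (artifact_pct_high < artifact_pct_low)
    stop("artifact percentage must be non-decreasing in threshold")
  artifact_pct_high - artifact_pct_low
}
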