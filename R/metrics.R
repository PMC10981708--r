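#' 3-class murmur confusion matrix
#'
#' Counts matrix with rows = model prediction and columns = expert label in
#' the fixed class order Present, Unknown, Absent. `counts[i, j]` is the
#' number of patients predicted class `i` whose expert label is class `j`.
#'
#' @param y_true Expert labels (Present/Unknown/Absent).
#' @param y_pred Predicted labels, same length.
#' @return 3x3 integer matrix of class `pcg_murmur_confusion` with
#'   dimnames `predicted` x `expert`.
#' @export
confusion3 <- function(y_true, y_pred) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("'y_true' and 'y_pred' must have equal length")
  }
  bad <- setdiff(unique(c(y_true, y_pred)), MURMUR_CLASSES)
  if (length(bad) > 0) {
    stop(
      "invalid murmur label(s): ", paste(bad, collapse = ", "),
      " (expected ", paste(MURMUR_CLASSES, collapse = "/"), ")"
    )
  }
  cm <- table(
    predicted = factor(y_pred, levels = MURMUR_CLASSES),
    expert = factor(y_true, levels = MURMUR_CLASSES)
  )
  structure(unclass(cm), class = "pcg_murmur_confusion")
}

#' Weighted accuracy for 3-class murmur detection
#'
#' The murmur-screening score: correct detections are weighted 5
#' (murmur Present), 3 (Unknown) and 1 (Absent) by the patient's expert
#' label, so that missing a murmur costs far more than a false alarm:
#' \deqn{WAcc = \frac{5 N_{PP} + 3 N_{UU} + N_{AA}}
#'   {5\sum_i N_{iP} + 3\sum_i N_{iU} + \sum_i N_{iA}}}
#' where the first index is the prediction and the second the expert label.
#'
#' @param cm A [confusion3()] matrix (or any 3x3 matrix in
#'   Present/Unknown/Absent order, prediction rows).
#' @param weights Per-expert-class weights, default `c(5, 3, 1)`. With all
#'   weights 1 this reduces to plain accuracy.
#' @return Weighted accuracy in \[0, 1\].
#' @examples
#' cm <- confusion3(
#'   y_true = c("Present", "Present", "Absent"),
#'   y_pred = c("Present", "Absent", "Absent")
#' )
#' weighted_accuracy(cm)
#' @export
weighted_accuracy <- function(cm, weights = c(5, 3, 1)) {
  cm <- unclass(cm)
  if (!all(dim(cm) == c(3L, 3L))) stop("expected a 3x3 confusion matrix")
  if (any(cm < 0)) stop("confusion counts must be nonnegative")
  denom <- sum(weights * colSums(cm))
  if (denom == 0) stop("weighted accuracy undefined: no scored patients")
  sum(weights * diag(cm)) / denom
}

#' Binary weighted accuracy for outcome screening
#'
#' Two-class analogue used to score Abnormal/Normal outcome predictions on
#' the same weighted scale: correct Abnormal detections weigh 5, correct
#' Normal 1.
#'
#' @param y_true Expert outcome labels (Abnormal/Normal).
#' @param y_pred Predicted outcome labels.
#' @return Weighted accuracy in \[0, 1\].
#' @export
weighted_accuracy_binary <- function(y_true, y_pred) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  bad <- setdiff(unique(c(y_true, y_pred)), OUTCOME_CLASSES)
  if (length(bad) > 0) stop("invalid outcome label(s): ", paste(bad, collapse = ", "))
  n_aa <- sum(y_true == "Abnormal" & y_pred == "Abnormal")
  n_nn <- sum(y_true == "Normal" & y_pred == "Normal")
  denom <- 5 * sum(y_true == "Abnormal") + sum(y_true == "Normal")
  if (denom == 0) stop("weighted accuracy undefined: no scored patients")
  (5 * n_aa + n_nn) / denom
}

#' Outcome screening counts
#'
#' The quantities entering the clinical cost metric: `N` total patients,
#' `M` patients predicted Abnormal (correctly or not), `TP` patients
#' correctly predicted Abnormal, `FN` abnormal patients predicted Normal.
#'
#' @param y_true Expert outcome labels (Abnormal/Normal).
#' @param y_pred Predicted outcome labels.
#' @return A `pcg_outcome_counts` list with `N`, `M`, `TP`, `FN`.
#' @export
outcome_counts <- function(y_true, y_pred) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  bad <- setdiff(unique(c(y_true, y_pred)), OUTCOME_CLASSES)
  if (length(bad) > 0) stop("invalid outcome label(s): ", paste(bad, collapse = ", "))
  structure(
    list(
      N = length(y_true),
      M = sum(y_pred == "Abnormal"),
      TP = sum(y_pred == "Abnormal" & y_true == "Abnormal"),
      FN = sum(y_pred == "Normal" & y_true == "Abnormal")
    ),
    class = "pcg_outcome_counts"
  )
}

#' Clinical outcome cost
#'
#' The cost-based outcome score: per-patient expected cost of screening
#' (the polynomial in `M`, modelling expert-review capacity), treatment
#' (10000 per treated true positive) and missed diagnoses (50000 per false
#' negative). Lower is better; an all-Normal prediction on an all-Normal
#' cohort costs exactly 35 per patient (the screening baseline).
#' \deqn{c = \frac{1}{N}\left(35N + 397M - 1718\frac{M^2}{N}
#'   + 11296\frac{M^4}{N^3} + 10000\,TP + 50000\,FN\right)}
#'
#' @param counts A [outcome_counts()] object, or a list with `N`, `M`,
#'   `TP`, `FN`.
#' @return The mean per-patient cost (nonnegative float).
#' @examples
#' outcome_cost(list(N = 100, M = 10, TP = 5, FN = 5)) # 3058.6496
#' @export
outcome_cost <- function(counts) {
  N <- counts$N; M <- counts$M; TP <- counts$TP; FN <- counts$FN
  if (is.null(N) || N < 1) stop("outcome cost undefined for N < 1")
  if (M > N || TP > M || FN > N - M || any(c(M, TP, FN) < 0)) {
    stop("invalid outcome counts: need 0 <= TP <= M <= N and 0 <= FN <= N - M")
  }
  (35 * N + 397 * M - 1718 * M^2 / N + 11296 * M^4 / N^3 +
    10000 * TP + 50000 * FN) / N
}

# AUC by the rank method; ties between positive and negative scores count
# one half, matching brute-force pairwise comparison.
auc_rank <- function(labels, scores) {
  pos <- labels == 1L
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: both classes must be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary classification metrics
#'
#' Accuracy, sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, F-score
#' (harmonic mean of precision and recall) and AUC (rank method; ties count
#' half). Undefined components (e.g. no positive patients) are returned as
#' `NaN` with a warning.
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels.
#' @param scores Optional numeric scores, increasing with confidence in the
#'   positive class; required for AUC.
#' @param positive The label counted as positive.
#' @return Named list: `acc`, `se`, `sp`, `f_score`, and `auc` (NA when no
#'   scores are given).
#' @export
binary_metrics <- function(y_true, y_pred, scores = NULL, positive) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  tp <- sum(y_true == positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); returning NaN")
      return(NaN)
    }
    num / den
  }
  se <- div(tp, tp + fn, "sensitivity")
  sp <- div(tn, tn + fp, "specificity")
  prec <- div(tp, tp + fp, "precision")
  f <- if (is.nan(prec) || is.nan(se) || (prec + se) == 0) {
    NaN
  } else {
    2 * prec * se / (prec + se)
  }
  auc <- NA_real_
  if (!is.null(scores)) {
    auc <- auc_rank(as.integer(y_true == positive), scores)
  }
  list(acc = (tp + tn) / length(y_true), se = se, sp = sp, f_score = f,
       auc = auc)
}

#' Macro-average of per-class metric values
#'
#' Unweighted mean over classes of one-vs-rest metric values, the averaging
#' rule used for multi-class sensitivity/specificity/F summaries.
#'
#' @param values Numeric vector of per-class values.
#' @return Their unweighted mean (`NaN` components propagate).
#' @export
macro_average <- function(values) {
  if (length(values) < 1L) stop("need at least one class value")
  mean(as.numeric(values))
}

#' Per-class one-vs-rest metrics for a multi-class problem
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels.
#' @param score_matrix Optional matrix of class scores (columns named by
#'   class) for per-class AUC.
#' @param classes Class order (default: murmur classes).
#' @return Data.frame with one row per class: `se`, `sp`, `f_score`, `auc`.
#' @export
per_class_metrics <- function(y_true, y_pred, score_matrix = NULL,
                              classes = MURMUR_CLASSES) {
  rows <- lapply(classes, function(cl) {
    sc <- if (!is.null(score_matrix)) score_matrix[, cl] else NULL
    m <- binary_metrics(y_true, y_pred, scores = sc, positive = cl)
    data.frame(class = cl, se = m$se, sp = m$sp, f_score = m$f_score,
               auc = m$auc)
  })
  do.call(rbind, rows)
}
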