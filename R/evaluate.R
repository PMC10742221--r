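# Confusion-matrix metrics and split bookkeeping shared by the CSP and CNN
# branches. The positive class is "expert" throughout.

#' Confusion matrix for binary expert/novice classification
#'
#' Layout `C = [TP, FP; FN, TN]` with "expert" as the positive class.
#'
#' @param y_true,y_pred label vectors (values from the same two-class set).
#' @param positive label counted as positive (default "expert").
#' @return a 2x2 integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(y_true, y_pred, positive = "expert") {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (!length(y_true) || length(y_true) != length(y_pred)) {
    stop("need equal-length, non-empty label vectors", call. = FALSE)
  }
  lv <- unique(c(y_true, y_pred))
  if (length(lv) > 2 || !(positive %in% c(lv, positive))) {
    stop("labels must come from a two-class set", call. = FALSE)
  }
  tp <- sum(y_true == positive & y_pred == positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  tn <- sum(y_true != positive & y_pred != positive)
  structure(matrix(as.integer(c(tp, fn, fp, tn)), 2, 2,
                   dimnames = list(pred = c("positive", "negative"),
                                   true = c("positive", "negative"))),
            class = c("confusion_matrix", "matrix"))
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Classification metrics from a confusion matrix
#'
#' Accuracy, precision `TP/(TP+FP)`, sensitivity/recall `TP/(TP+FN)`,
#' specificity `TN/(FP+TN)`, `F1 = 2 pr / (p + r)`, Matthews correlation
#' coefficient, and Cohen's kappa. Metrics with a zero denominator are
#' reported as 0 and the report's `degenerate` flag is set.
#'
#' @param conf a [confusion()] matrix, or a length-4 vector `(TP, FP, FN, TN)`.
#' @return a `classifier_report`: list with the confusion matrix, each metric,
#'   `n_samples`, and `degenerate`.
#' @export
classification_metrics <- function(conf) {
  if (is.matrix(conf)) {
    tp <- conf[1, 1]; fp <- conf[1, 2]; fn <- conf[2, 1]; tn <- conf[2, 2]
  } else {
    stopifnot(length(conf) == 4)
    tp <- conf[1]; fp <- conf[2]; fn <- conf[3]; tn <- conf[4]
  }
  n <- tp + fp + fn + tn
  acc <- safe_div(tp + tn, n)
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, fp + tn)
  f1 <- if (is.na(prec) || is.na(rec) || (prec + rec) == 0) NA_real_ else
    2 * prec * rec / (prec + rec)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  kap <- cohen_kappa(matrix(c(tp, fn, fp, tn), 2, 2))
  vals <- c(accuracy = acc, precision = prec, sensitivity = rec,
            specificity = spec, f1 = f1, mcc = mcc, kappa = kap)
  degenerate <- anyNA(vals)
  if (degenerate) {
    warning("zero-denominator metric(s) reported as 0", call. = FALSE)
    vals[is.na(vals)] <- 0
  }
  structure(c(list(confusion = matrix(as.numeric(c(tp, fn, fp, tn)), 2, 2,
                                      dimnames = list(pred = c("positive", "negative"),
                                                      true = c("positive", "negative"))),
                   n_samples = n, degenerate = degenerate),
              as.list(vals)),
            class = "classifier_report")
}

#' Cohen's kappa from a 2x2 confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`: 0 for random
#' classification, 1 for perfect agreement.
#'
#' @param conf 2x2 matrix `[TP, FP; FN, TN]` (rows = predicted).
#' @return kappa in `[-1, 1]` (0 when `p_e = 1`).
#' @export
cohen_kappa <- function(conf) {
  conf <- matrix(as.numeric(conf), 2, 2)
  n <- sum(conf)
  if (n == 0) return(NA_real_)
  po <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  if (abs(1 - pe) < .Machine$double.eps) return(0)
  (po - pe) / (1 - pe)
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(paste0("<classifier_report> n = %d%s\n",
                     "  accuracy %.4f | F1 %.4f | MCC %.4f | kappa %.4f\n",
                     "  sensitivity %.4f | specificity %.4f | precision %.4f\n"),
              x$n_samples, if (x$degenerate) " (degenerate)" else "",
              x$accuracy, x$f1, x$mcc, x$kappa,
              x$sensitivity, x$specificity, x$precision))
  invisible(x)
}

#' Summarize repeated classifier reports
#'
#' Mean, standard deviation, and maximum per metric over a list of reports —
#' the layout used to report repeated cross-validation.
#'
#' @param reports list of `classifier_report` objects.
#' @return a tibble with columns `metric`, `mean`, `sd`, `max`.
#' @export
summarize_repeats <- function(reports) {
  stopifnot(length(reports) >= 1)
  metrics <- c("accuracy", "precision", "sensitivity", "specificity",
               "f1", "mcc", "kappa")
  vals <- vapply(reports, function(r) unlist(r[metrics]), numeric(length(metrics)))
  vals <- matrix(vals, nrow = length(metrics))
  tibble::tibble(
    metric = metrics,
    mean = rowMeans(vals),
    sd = apply(vals, 1, function(v) if (length(v) > 1) stats::sd(v) else 0),
    max = apply(vals, 1, max))
}

# stratified fold assignment: returns a fold id per sample
stratified_folds <- function(labels, folds, seed = 1) {
  fold_id <- integer(length(labels))
  with_seed(seed, {
    for (s in unique(labels)) {
      idx <- which(labels == s)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold_id
}

#' Deterministic holdout + k-fold split plan
#'
#' Draws a disjoint holdout set of `round(holdout * n)` indices, then
#' partitions the remainder into `folds` folds whose sizes differ by at most
#' one. Deterministic under `seed`.
#'
#' @param n number of samples.
#' @param holdout holdout fraction in `(0, 1)`.
#' @param folds number of folds for the remainder.
#' @param seed integer seed.
#' @param labels optional label vector of length `n`; when given, both the
#'   holdout draw and the folds are stratified by label.
#' @return list with `holdout` (indices) and `folds` (list of index vectors);
#'   the union of folds is exactly the non-holdout set.
#' @export
make_splits <- function(n, holdout = 0.1, folds = 5, seed = 1, labels = NULL) {
  if (holdout <= 0 || holdout >= 1) stop("holdout must be in (0, 1)", call. = FALSE)
  if (folds < 2) stop("need at least 2 folds", call. = FALSE)
  with_seed(seed, {
    strata <- if (is.null(labels)) rep(1L, n) else as.integer(factor(labels))
    hold <- integer()
    for (s in unique(strata)) {
      idx <- which(strata == s)
      hold <- c(hold, sample(idx, round(holdout * length(idx))))
    }
    hold <- sort(hold)
    rest <- setdiff(seq_len(n), hold)
    fold_of <- integer(length(rest))
    for (s in unique(strata)) {
      j <- which(strata[rest] == s)
      fold_of[j] <- sample(rep_len(seq_len(folds), length(j)))
    }
    list(holdout = hold,
         folds = lapply(seq_len(folds), function(f) rest[fold_of == f]))
  })
}
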