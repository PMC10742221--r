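# Regularized common spatial patterns conditioned on microstate labels, with
# a Fisher linear discriminant classifier and fold-honest cross-validation.

#' Class scatter matrix of an epoch set
#'
#' Sum over epochs of `X' X` (optionally trace-normalizing each epoch's
#' contribution), the scatter that enters the CSP variance-ratio objective.
#'
#' @param epochs an [eeg_epochs()] object or list of `n x C` matrices.
#' @param trace_norm divide each epoch's scatter by its trace (default FALSE,
#'   matching the raw `X' X` form of the objective).
#' @return a symmetric positive semi-definite `C x C` matrix.
#' @export
class_scatter <- function(epochs, trace_norm = FALSE) {
  eps <- if (inherits(epochs, "eeg_epochs")) epochs$epochs else epochs
  mats <- lapply(eps, function(e) {
    S <- crossprod(as.matrix(e))
    if (trace_norm) S / sum(diag(S)) else S
  })
  Reduce(`+`, mats)
}

#' Restrict epochs to samples of one microstate
#'
#' Keeps only the samples whose backfitted label equals `state`, preserving
#' the channel dimension. This is the microstate conditioning step that feeds
#' state-specific scatter matrices into CSP. With `state = "auto"`, each
#' epoch keeps the samples of its own dominant task-onset state (the modal
#' backfitted label of the epoch, robust to single-sample jitter at the
#' epoch edge).
#'
#' @param epochs an [eeg_epochs()] or list of matrices.
#' @param segmentations list of [backfit()] results (or integer label
#'   vectors), one per epoch.
#' @param state integer state index, or `"auto"`.
#' @return list of matrices (one per epoch, possibly with differing row
#'   counts).
#' @export
microstate_condition <- function(epochs, segmentations, state) {
  eps <- if (inherits(epochs, "eeg_epochs")) epochs$epochs else epochs
  stopifnot(length(eps) == length(segmentations))
  out <- vector("list", length(eps))
  for (i in seq_along(eps)) {
    lab <- if (inherits(segmentations[[i]], "microstate_segmentation"))
      segmentations[[i]]$labels else as.integer(segmentations[[i]])
    if (length(lab) != nrow(eps[[i]])) {
      stop("segmentation does not cover epoch ", i, call. = FALSE)
    }
    st <- if (identical(state, "auto")) {
      tab <- tabulate(lab)
      which.max(tab)
    } else state
    keep <- which(lab == st)
    if (!length(keep)) {
      stop("state ", st, " never occurs in epoch ", i, call. = FALSE)
    }
    out[[i]] <- eps[[i]][keep, , drop = FALSE]
  }
  out
}

#' Run the full microstate-CSP-LDA branch on preprocessed epochs
#'
#' Aggregates GFP-peak maps across all subjects, fits (or selects) a
#' microstate model, backfits every epoch with temporal smoothing, and
#' cross-validates CSP + LDA — optionally conditioning the CSP scatter on
#' one microstate, which is the configuration that exploits state-specific
#' group differences.
#'
#' @param epoch_sets list of [eeg_epochs()] (one per subject-trial, with
#'   `group` annotations; `NULL` entries from excluded subjects are skipped).
#' @param K fixed number of microstates, or `NULL` to select over `K_range`
#'   by the CV criterion.
#' @param K_range candidate K when selecting (default 2:8).
#' @param n_init K-means restarts.
#' @param n_peaks GFP peaks retained per epoch.
#' @param smooth_window_ms backfitting smoothing window.
#' @param condition condition CSP on a microstate (`TRUE` uses each epoch's
#'   first active state; an integer picks a global state; `FALSE` disables).
#' @param folds,seed,alpha,n_pairs passed to [crossvalidate_csp_lda()].
#' @return list with `model` (the microstate model), `report` (the
#'   cross-validated `classifier_report`), `segmentations`, `labels`.
#' @export
csp_branch_pipeline <- function(epoch_sets, K = NULL, K_range = 2:8,
                                n_init = 10, n_peaks = 1000,
                                smooth_window_ms = 30, condition = TRUE,
                                folds = 10, seed = 1, alpha = NULL, n_pairs = 1) {
  epoch_sets <- Filter(Negate(is.null), epoch_sets)
  eps <- list(); labels <- character(); fs <- NULL
  for (es in epoch_sets) {
    for (i in seq_along(es$epochs)) {
      eps[[length(eps) + 1L]] <- es$epochs[[i]]
      labels <- c(labels, es$info$group[i])
    }
    fs <- es$fs
  }
  peak_maps <- do.call(rbind, lapply(seq_along(eps), function(i) {
    g <- gfp(eps[[i]])
    pk <- pick_gfp_peaks(g, fs, n_peaks = n_peaks, seed = seed + i)
    eps[[i]][pk, , drop = FALSE]
  }))
  model <- if (is.null(K)) {
    select_microstate_model(peak_maps, K_range, n_init = n_init, seed = seed)
  } else {
    microstate_kmeans(peak_maps, K, n_init = n_init, seed = seed)
  }
  segs <- lapply(eps, backfit, model = model,
                 smooth_window_ms = smooth_window_ms, fs = fs)
  state <- if (isTRUE(condition)) "auto" else condition
  report <- if (isFALSE(condition)) {
    crossvalidate_csp_lda(eps, labels, folds = folds, seed = seed,
                          alpha = alpha, n_pairs = n_pairs)
  } else {
    crossvalidate_csp_lda(eps, labels, folds = folds, seed = seed,
                          alpha = alpha, n_pairs = n_pairs,
                          segmentations = segs, state = state)
  }
  list(model = model, report = report, segmentations = segs, labels = labels)
}

fix_sign <- function(W) {
  # sign convention: largest-magnitude entry of each column positive
  s <- apply(W, 2, function(w) sign(w[which.max(abs(w))]))
  s[s == 0] <- 1
  W %*% diag(s, ncol(W))
}

#' Fit regularized common spatial patterns
#'
#' Solves the two Tikhonov-regularized eigenproblems
#' `M1 = (C2 + alpha K)^-1 C1` and `M2 = (C1 + alpha K)^-1 C2` with `K = I`.
#' Eigenvectors of `M1` maximize the class-1 to regularized-class-2 variance
#' ratio (and vice versa); the leading eigenvector of each is the
#' discriminative spatial filter for its class. Filters are unit-norm with
#' the largest-magnitude coefficient positive; spatial patterns are the
#' columns of the inverse transpose of the filter matrix.
#'
#' @param C1,C2 symmetric PSD scatter/covariance matrices (class 1 = expert,
#'   class 2 = novice).
#' @param alpha Tikhonov regularization weight; `NULL` uses
#'   `0.1 * tr(C2) / n_channels`.
#' @return an object of class `csp_model` with `W1`, `W2` (filters, columns
#'   sorted by decreasing eigenvalue), `patterns1`, `patterns2`, `eigvals1`,
#'   `eigvals2`, `alpha`.
#' @export
fit_regularized_csp <- function(C1, C2, alpha = NULL) {
  C1 <- as.matrix(C1); C2 <- as.matrix(C2)
  stopifnot(nrow(C1) == ncol(C1), identical(dim(C1), dim(C2)))
  if (max(abs(C1 - t(C1))) > 1e-9 * max(1, max(abs(C1))) ||
      max(abs(C2 - t(C2))) > 1e-9 * max(1, max(abs(C2)))) {
    stop("scatter matrices must be symmetric", call. = FALSE)
  }
  nch <- nrow(C1)
  if (is.null(alpha)) alpha <- 0.1 * sum(diag(C2)) / nch
  solve_branch <- function(Cnum, Cden) {
    Creg <- Cden + diag(alpha, nch)
    M <- tryCatch(solve(Creg, Cnum), error = function(e)
      stop("regularized denominator is singular; increase alpha", call. = FALSE))
    e <- eigen(M)
    if (max(abs(Im(e$values))) > 1e-8 * max(1, max(abs(Re(e$values)))) ||
        max(abs(Im(e$vectors))) > 1e-8) {
      stop("complex spatial filters: eigendecomposition is not real", call. = FALSE)
    }
    vals <- Re(e$values); vecs <- Re(e$vectors)
    ord <- order(vals, decreasing = TRUE)
    vals <- vals[ord]
    W <- vecs[, ord, drop = FALSE]
    W <- W %*% diag(1 / sqrt(colSums(W^2)), ncol(W))
    W <- fix_sign(W)
    list(W = W, vals = vals)
  }
  b1 <- solve_branch(C1, C2)
  b2 <- solve_branch(C2, C1)
  structure(list(C1 = C1, C2 = C2, alpha = alpha,
                 W1 = b1$W, W2 = b2$W,
                 eigvals1 = b1$vals, eigvals2 = b2$vals,
                 patterns1 = t(solve(b1$W)), patterns2 = t(solve(b2$W))),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d channels, alpha = %.4g, top eigenvalues %.3g / %.3g\n",
              nrow(x$C1), x$alpha, x$eigvals1[1], x$eigvals2[1]))
  invisible(x)
}

#' Log-variance CSP features of an epoch
#'
#' Projects the epoch on the top `n_pairs` filters from each branch and
#' returns the log mean-square amplitude of each projection
#' (`2 * n_pairs` features). Scaling the epoch by `c` adds `2 log|c|` to
#' every feature.
#'
#' @param epoch `n x C` matrix.
#' @param model a [fit_regularized_csp()] model.
#' @param n_pairs filters per branch (default 1: the leading eigenvector of
#'   each M).
#' @return numeric feature vector of length `2 * n_pairs`.
#' @export
csp_features <- function(epoch, model, n_pairs = 1) {
  W <- cbind(model$W1[, seq_len(n_pairs), drop = FALSE],
             model$W2[, seq_len(n_pairs), drop = FALSE])
  proj <- as.matrix(epoch) %*% W
  log(colMeans(proj^2))
}

#' Fisher linear discriminant with shrinkage
#'
#' Two-class LDA on feature vectors: `w = Sw^-1 (m1 - m0)` with the pooled
#' within-class covariance shrunk toward its average diagonal,
#' `Sw(lambda) = (1 - lambda) Sw + lambda mean(diag(Sw)) I`, which keeps the
#' fit defined for zero-variance features. The decision is affine:
#' `sign(w'x + b)`.
#'
#' @param X `n x p` feature matrix.
#' @param y labels (two classes; the first level alphabetically is coded 0).
#' @param shrinkage lambda in `[0, 1]` (default 1e-3).
#' @return an object of class `lda_model` (`w`, `b`, `classes`, `shrinkage`).
#' @export
lda_fit <- function(X, y, shrinkage = 1e-3) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("LDA needs exactly two classes", call. = FALSE)
  i0 <- y == classes[1]; i1 <- y == classes[2]
  if (sum(i0) < 2 || sum(i1) < 2) stop("need >= 2 samples per class", call. = FALSE)
  m0 <- colMeans(X[i0, , drop = FALSE]); m1 <- colMeans(X[i1, , drop = FALSE])
  S0 <- crossprod(sweep(X[i0, , drop = FALSE], 2, m0))
  S1 <- crossprod(sweep(X[i1, , drop = FALSE], 2, m1))
  Sw <- (S0 + S1) / (nrow(X) - 2)
  avg <- mean(diag(Sw))
  if (avg == 0) avg <- 1
  Sw <- (1 - shrinkage) * Sw + shrinkage * avg * diag(ncol(X))
  w <- solve(Sw, m1 - m0)
  b <- -sum(w * (m0 + m1)) / 2 + log(sum(i1) / sum(i0))
  structure(list(w = w, b = b, classes = classes, shrinkage = shrinkage),
            class = "lda_model")
}

#' Predict class labels from an LDA model
#' @param object an [lda_fit()] model.
#' @param newdata `n x p` feature matrix.
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  score <- as.matrix(newdata) %*% object$w + object$b
  object$classes[(score > 0) + 1L]
}

#' Cross-validated CSP + LDA classification of epochs
#'
#' Stratified k-fold cross-validation with CSP and LDA re-fit inside every
#' training fold (no leakage): per fold, class scatters are built from the
#' training epochs only (optionally conditioned on a microstate state),
#' filters and the discriminant are fitted, and the held-out epochs are
#' predicted. Fold predictions are pooled into one confusion matrix.
#'
#' @param epochs an [eeg_epochs()] or list of `n x C` matrices.
#' @param labels class label per epoch (`"expert"` / `"novice"`).
#' @param folds number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param alpha CSP regularization (NULL = default heuristic).
#' @param n_pairs filters per branch.
#' @param segmentations optional list of [backfit()] results for microstate
#'   conditioning.
#' @param state microstate to condition on (integer or "auto"); ignored when
#'   `segmentations` is NULL.
#' @param shrinkage LDA shrinkage.
#' @return a `classifier_report` (see [classification_metrics()]).
#' @export
crossvalidate_csp_lda <- function(epochs, labels, folds = 10, seed = 1,
                                  alpha = NULL, n_pairs = 1,
                                  segmentations = NULL, state = "auto",
                                  shrinkage = 1e-3) {
  eps <- if (inherits(epochs, "eeg_epochs")) epochs$epochs else epochs
  labels <- as.character(labels)
  stopifnot(length(eps) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("need exactly two classes", call. = FALSE)
  if (min(table(labels)) < folds) {
    stop("need at least `folds` epochs per class", call. = FALSE)
  }
  fold_id <- integer(length(labels))
  with_seed(seed, {
    for (cl in classes) {
      idx <- which(labels == cl)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  cond <- function(idx) {
    if (is.null(segmentations)) return(eps[idx])
    microstate_condition(eps[idx], segmentations[idx], state)
  }
  pred <- character(length(labels))
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f); te <- which(fold_id == f)
    # class 1 = expert when present, else first class alphabetically
    pos <- if ("expert" %in% classes) "expert" else classes[1]
    C1 <- class_scatter(cond(tr[labels[tr] == pos]))
    C2 <- class_scatter(cond(tr[labels[tr] != pos]))
    model <- fit_regularized_csp(C1, C2, alpha = alpha)
    feat <- function(idx) t(vapply(cond(idx), csp_features, numeric(2 * n_pairs),
                                   model = model, n_pairs = n_pairs))
    lda <- lda_fit(feat(tr), labels[tr], shrinkage = shrinkage)
    pred[te] <- predict(lda, feat(te))
  }
  conf <- confusion(labels, pred, positive = if ("expert" %in% classes) "expert" else classes[1])
  classification_metrics(conf)
}
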