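# Polarity-invariant microstate analysis: prototype fitting by modified
# K-means on GFP-peak maps, model selection by the predictive cross-validation
# criterion, and backfitting with small-segment temporal smoothing.

#' Global field power
#'
#' Per-sample population standard deviation of the scalp potential across
#' channels. Maps are centred across channels first, so the result is the
#' same for as-recorded and average-referenced input.
#'
#' @param X numeric matrix `n_samples x n_channels`.
#' @return numeric vector of length `n_samples`.
#' @export
gfp <- function(X) {
  X <- as.matrix(X)
  xc <- X - rowMeans(X)
  sqrt(rowMeans(xc^2))
}

#' Pick GFP peaks for prototype fitting
#'
#' Local maxima of the GFP series at least `min_distance_ms` apart (the
#' larger peak wins within the exclusion distance). Peaks whose GFP exceeds
#' `mean + reject_sd * SD` of all peak GFPs (population SD) are rejected as
#' likely artifacts, and at most `n_peaks` of the survivors are retained by
#' seeded uniform subsampling.
#'
#' @param g GFP series (vector).
#' @param fs sampling rate in Hz.
#' @param min_distance_ms minimum peak separation in milliseconds.
#' @param n_peaks maximum number of peaks to keep.
#' @param reject_sd rejection threshold in peak-GFP standard deviations.
#' @param seed integer seed for the subsampling step.
#' @return integer vector of (1-based) sample indices into `g`.
#' @export
pick_gfp_peaks <- function(g, fs, min_distance_ms = 10, n_peaks = 1000,
                           reject_sd = 1, seed = 1) {
  n <- length(g)
  if (n < 3) stop("GFP series too short", call. = FALSE)
  is_peak <- which(g[2:(n - 1)] > g[1:(n - 2)] & g[2:(n - 1)] >= g[3:n]) + 1L
  if (!length(is_peak)) stop("no GFP peaks found", call. = FALSE)
  min_dist <- max(1L, round(min_distance_ms / 1000 * fs))
  # greedy by descending height with exclusion radius
  ord <- is_peak[order(g[is_peak], decreasing = TRUE)]
  taken <- logical(n)
  keep <- integer()
  for (p in ord) {
    lo <- max(1L, p - min_dist + 1L); hi <- min(n, p + min_dist - 1L)
    if (!any(taken[lo:hi])) {
      keep <- c(keep, p)
      taken[p] <- TRUE
    }
  }
  keep <- sort(keep)
  gp <- g[keep]
  mu <- mean(gp)
  sdev <- sqrt(mean((gp - mu)^2)) # population SD
  keep <- keep[gp <= mu + reject_sd * sdev]
  if (!length(keep)) stop("all GFP peaks rejected", call. = FALSE)
  if (length(keep) > n_peaks) {
    keep <- sort(with_seed(seed, sample(keep, n_peaks)))
  }
  keep
}

# squared spatial Pearson correlation between rows of X and prototype rows of A
sq_spatial_cor <- function(X, A) {
  xc <- X - rowMeans(X)
  ac <- A - rowMeans(A)
  num <- tcrossprod(xc, ac) # n x K
  den <- outer(sqrt(rowSums(xc^2)), sqrt(rowSums(ac^2)))
  r <- num / den
  r[!is.finite(r)] <- 0
  r^2
}

#' Modified K-means microstate clustering
#'
#' Polarity-invariant clustering of topographic maps: samples are assigned to
#' the prototype with the highest squared spatial correlation (sign ignored),
#' and each prototype is updated as the dominant eigenvector of the outer-
#' product sum of its assigned maps. Initialization is k-means++-style on the
#' polarity-folded squared Euclidean distance; the best of `n_init` restarts
#' by global explained variance is returned, with prototypes sorted by
#' decreasing per-state GEV.
#'
#' @param maps `n_maps x n_channels` matrix of (average-referenced) maps,
#'   e.g. GFP-peak maps.
#' @param K number of microstate classes.
#' @param n_init random restarts (default 100).
#' @param max_iter iteration cap per restart (default 1000).
#' @param tol relative convergence threshold on residual variance
#'   (default 1e-6).
#' @param seed integer seed; fixed seed gives bit-identical results.
#' @return an object of class `microstate_model`: fields `prototypes`
#'   (`K x n_channels`, unit-norm zero-mean rows), `K`, `gev_total`,
#'   `gev_per_state`, `cv`, `sorted`.
#' @export
microstate_kmeans <- function(maps, K, n_init = 100, max_iter = 1000,
                              tol = 1e-6, seed = 1) {
  maps <- as.matrix(maps)
  K <- as.integer(K)
  n <- nrow(maps); nch <- ncol(maps)
  if (K > n) stop("K exceeds the number of maps", call. = FALSE)
  Xc <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(Xc^2))
  nrm[nrm == 0] <- 1
  U <- Xc / nrm # unit-norm maps for seeding/assignment geometry

  run_once <- function() {
    # k-means++ seeding, polarity-folded squared Euclidean distance
    centers <- matrix(0, K, nch)
    centers[1, ] <- U[sample.int(n, 1), ]
    if (K > 1) {
      for (k in 2:K) {
        sim2 <- tcrossprod(U, centers[seq_len(k - 1L), , drop = FALSE])^2
        d2 <- 2 - 2 * sqrt(apply(sim2, 1, max)) # min over +/- sign
        d2 <- pmax(d2, 0)
        if (sum(d2) == 0) d2 <- rep(1, n)
        centers[k, ] <- U[sample.int(n, 1, prob = d2), ]
      }
    }
    A <- centers
    prev_sigma <- Inf
    lab <- integer(n)
    for (it in seq_len(max_iter)) {
      sim <- tcrossprod(U, A)^2
      lab <- max.col(sim, ties.method = "first")
      for (k in seq_len(K)) {
        idx <- which(lab == k)
        if (!length(idx)) {
          # re-seed an empty class at the worst-fitted map
          worst <- which.min(apply(sim, 1, max))
          A[k, ] <- U[worst, ]
          next
        }
        S <- crossprod(Xc[idx, , drop = FALSE])
        ev <- eigen(S, symmetric = TRUE)
        a <- ev$vectors[, 1]
        a <- a - mean(a)
        A[k, ] <- a / sqrt(sum(a^2))
      }
      proj <- tcrossprod(Xc, A)
      sigma <- (sum(Xc^2) - sum(proj[cbind(seq_len(n), lab)]^2)) / (n * (nch - 1))
      if (is.finite(prev_sigma) && abs(prev_sigma - sigma) <= tol * prev_sigma) break
      prev_sigma <- sigma
    }
    list(A = A, lab = lab)
  }

  with_seed(seed, {
    best <- NULL; best_gev <- -Inf
    for (i in seq_len(n_init)) {
      fit <- run_once()
      g <- gev_from_fit(maps, fit$A, fit$lab)
      if (g$total > best_gev) { best_gev <- g$total; best <- c(fit, g) }
    }
    # sort prototypes by decreasing per-state GEV
    ord <- order(best$per_state, decreasing = TRUE)
    A <- best$A[ord, , drop = FALSE]
    model <- structure(list(prototypes = A, K = K,
                            gev_total = best$total,
                            gev_per_state = best$per_state[ord],
                            cv = NA_real_, sorted = TRUE),
                       class = "microstate_model")
    model$cv <- cv_criterion(maps, model)
    model
  })
}

gev_from_fit <- function(X, A, lab) {
  X <- as.matrix(X)
  g <- gfp(X)
  r <- sq_spatial_cor(X, A)
  r_assigned <- r[cbind(seq_len(nrow(X)), lab)]
  denom <- sum(g^2)
  contrib <- g^2 * r_assigned
  per_state <- vapply(seq_len(nrow(A)), function(k)
    sum(contrib[lab == k]) / denom, 0)
  list(total = sum(contrib) / denom, per_state = per_state)
}

#' Global explained variance of a labelled segmentation
#'
#' `GEV = sum_t (GFP_t * corr(x_t, a_{L_t}))^2 / sum_t GFP_t^2`, with the
#' squared spatial correlation making the measure polarity-invariant.
#' Unassigned samples (label `NA` or 0) contribute zero to the numerator.
#'
#' @param X `n_samples x n_channels` data matrix.
#' @param model a [microstate_kmeans()] model (or any list with a
#'   `prototypes` matrix).
#' @param labels per-sample state indices in `1..K` (NA/0 = unassigned).
#' @return GEV in `[0, 1]`.
#' @export
gev <- function(X, model, labels) {
  X <- as.matrix(X)
  g <- gfp(X)
  r <- sq_spatial_cor(X, model$prototypes)
  ok <- !is.na(labels) & labels > 0
  contrib <- numeric(nrow(X))
  contrib[ok] <- g[ok]^2 * r[cbind(which(ok), labels[ok])]
  sum(contrib) / sum(g^2)
}

#' Predictive cross-validation criterion for choosing K
#'
#' Residual noise variance of the polarity-invariant segmentation with the
#' small-sample correction `((C - 1) / (C - 1 - K))^2` (C = channels), i.e.
#' `CV = sigma^2 * ((C-1)/(C-1-K))^2` with
#' `sigma^2 = sum_t (x_t' x_t - (a_{L_t}' x_t)^2) / (T (C - 1))`.
#' Smaller is better; on data generated from K well-separated prototypes the
#' criterion is minimized at the generating K.
#'
#' @param X `n_samples x n_channels` data matrix.
#' @param model a [microstate_kmeans()] model.
#' @return the CV criterion value (microvolts squared).
#' @export
cv_criterion <- function(X, model) {
  X <- as.matrix(X)
  nch <- ncol(X)
  K <- nrow(model$prototypes)
  if (K >= nch - 1) {
    warning("K >= n_channels - 1: correction factor diverges", call. = FALSE)
    return(Inf)
  }
  Xc <- X - rowMeans(X)
  proj <- tcrossprod(Xc, model$prototypes) # a_k' x_t (prototypes unit-norm)
  lab <- max.col(proj^2, ties.method = "first")
  assigned <- proj[cbind(seq_len(nrow(Xc)), lab)]
  sigma2 <- (sum(Xc^2) - sum(assigned^2)) / (nrow(Xc) * (nch - 1))
  sigma2 * ((nch - 1) / (nch - 1 - K))^2
}

#' Fit microstate models over a range of K and select by the CV criterion
#'
#' @param maps `n_maps x n_channels` matrix of GFP-peak maps.
#' @param K_range candidate numbers of microstates (default 2:8).
#' @param ... passed to [microstate_kmeans()] (`n_init`, `seed`, ...).
#' @return the CV-minimizing `microstate_model`; the full scan is attached as
#'   attribute `scan` (tibble with K, gev_total, cv).
#' @export
select_microstate_model <- function(maps, K_range = 2:8, ...) {
  if (!length(K_range)) stop("empty K range", call. = FALSE)
  fits <- lapply(K_range, function(k) microstate_kmeans(maps, k, ...))
  cvs <- vapply(fits, function(f) f$cv, 0)
  best <- fits[[which.min(cvs)]]
  attr(best, "scan") <- tibble::tibble(
    K = as.integer(K_range),
    gev_total = vapply(fits, function(f) f$gev_total, 0),
    cv = cvs)
  best
}

#' Backfit microstate labels to continuous data
#'
#' Each sample is labelled with the prototype of the highest squared spatial
#' correlation (polarity ignored; the per-sample polarity sign is returned
#' separately). With smoothing, segments shorter than `smooth_window_ms` are
#' dissolved: their samples are reassigned to whichever flanking state
#' correlates better, repeated until no short segment remains.
#'
#' @param X `n_samples x n_channels` data matrix (one epoch).
#' @param model a [microstate_kmeans()] model.
#' @param smooth_window_ms minimum segment duration in ms, or `NULL` for raw
#'   argmax labels.
#' @param fs sampling rate in Hz (required when smoothing).
#' @return an object of class `microstate_segmentation`: `labels`, `polarity`,
#'   `smooth_window_ms`, `gev`.
#' @export
backfit <- function(X, model, smooth_window_ms = NULL, fs = NULL) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$prototypes)) {
    stop("channel count mismatch between data and model", call. = FALSE)
  }
  r2 <- sq_spatial_cor(X, model$prototypes)
  lab <- max.col(r2, ties.method = "first")
  Xc <- X - rowMeans(X)
  pol <- sign(tcrossprod(Xc, model$prototypes)[cbind(seq_along(lab), lab)])

  if (!is.null(smooth_window_ms)) {
    if (is.null(fs)) stop("`fs` is required for smoothing", call. = FALSE)
    min_len <- max(1L, round(smooth_window_ms / 1000 * fs))
    for (pass in seq_len(20L)) {
      r <- rle(lab)
      short <- which(r$lengths < min_len)
      short <- short[!(short %in% c(1L, length(r$lengths)))] # keep edges
      if (!length(short)) break
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (s in short) {
        left <- r$values[s - 1L]; right <- r$values[s + 1L]
        idx <- starts[s]:ends[s]
        pick <- ifelse(r2[idx, left] >= r2[idx, right], left, right)
        lab[idx] <- pick
      }
    }
    pol <- sign(tcrossprod(Xc, model$prototypes)[cbind(seq_along(lab), lab)])
  }
  structure(list(labels = lab, polarity = pol,
                 smooth_window_ms = smooth_window_ms,
                 gev = gev(X, model, lab)),
            class = "microstate_segmentation")
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> K = %d, GEV = %.3f, CV = %.4g\n",
              x$K, x$gev_total, x$cv))
  invisible(x)
}

#' @export
print.microstate_segmentation <- function(x, ...) {
  cat(sprintf("<microstate_segmentation> %d samples, %d states, GEV = %.3f%s\n",
              length(x$labels), length(unique(x$labels)), x$gev,
              if (is.null(x$smooth_window_ms)) "" else
                sprintf(", smoothed at %g ms", x$smooth_window_ms)))
  invisible(x)
}
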