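# Spherical-spline scalp interpolation and surface Laplacian (Perrin-style,
# spline order m = 4, series truncated at 50 Legendre terms, ridge 1e-5).

legendre_terms <- function(x, n_terms) {
  # P_1..P_n at x (vector); three-term recurrence
  out <- matrix(0, length(x), n_terms)
  pm1 <- rep(1, length(x)) # P_0
  p <- x # P_1
  out[, 1] <- p
  if (n_terms > 1) {
    for (n in 2:n_terms) {
      pn <- ((2 * n - 1) * x * p - (n - 1) * pm1) / n
      pm1 <- p; p <- pn
      out[, n] <- pn
    }
  }
  out
}

# g(cosang) for potentials; h(cosang) for the Laplacian kernel
spline_g <- function(cosang, m = 4, n_terms = 50) {
  n <- seq_len(n_terms)
  coef <- (2 * n + 1) / (n^m * (n + 1)^m)
  drop(legendre_terms(pmin(pmax(cosang, -1), 1), n_terms) %*% coef) / (4 * pi)
}

spline_h <- function(cosang, m = 4, n_terms = 50) {
  n <- seq_len(n_terms)
  coef <- (2 * n + 1) * (n * (n + 1)) / (n^m * (n + 1)^m)
  drop(legendre_terms(pmin(pmax(cosang, -1), 1), n_terms) %*% coef) / (4 * pi)
}

# Solve the constrained spline system for source electrodes `pos` (k x 3):
# [G + lambda I, 1; 1^T, 0] [c; c0] = [v; 0].  Returns a function of target
# positions giving the interpolation operator (n_targets x k), linear in v.
spline_operator <- function(pos, target, lambda = 1e-5, m = 4, n_terms = 50) {
  k <- nrow(pos)
  G <- matrix(spline_g(tcrossprod(pos), m, n_terms), k, k)
  A <- rbind(cbind(G + diag(lambda, k), 1), c(rep(1, k), 0))
  Gt <- matrix(spline_g(tcrossprod(target, pos), m, n_terms), nrow(target), k)
  B <- cbind(Gt, 1) # [Gt, 1] %*% [c; c0]
  op <- B %*% solve(A)[, seq_len(k), drop = FALSE]
  op
}

#' Interpolate flagged channels by spherical splines
#'
#' Replaces each flagged channel with the Perrin spherical-spline estimate
#' (order m = 4, ridge regularization 1e-5) computed from the remaining good
#' channels.
#'
#' @param rec an [eeg_recording()].
#' @param montage an [eeg_montage()] covering `rec$channel_names`.
#' @param flagged character vector (labels) or integer vector (column indices)
#'   of channels to rebuild. Must leave at least 3 good channels.
#' @return the recording with flagged channels replaced.
#' @export
interpolate_channels <- function(rec, montage, flagged) {
  idx <- if (is.character(flagged)) match(flagged, rec$channel_names) else as.integer(flagged)
  if (anyNA(idx)) stop("flagged channel(s) not present in recording", call. = FALSE)
  if (length(idx) == 0) return(rec)
  good <- setdiff(seq_len(n_channels(rec)), idx)
  if (length(good) < 3) stop("cannot interpolate: fewer than 3 good channels remain", call. = FALSE)
  mon <- montage_subset(montage, rec$channel_names)
  op <- spline_operator(mon$positions[good, , drop = FALSE],
                        mon$positions[idx, , drop = FALSE])
  rec$data[, idx] <- rec$data[, good, drop = FALSE] %*% t(op)
  rec
}

#' Spherical-spline surface Laplacian (current source density)
#'
#' Second spatial derivative of the scalp potential on the sphere, computed
#' through the spherical-spline expansion: the per-sample map is fitted with
#' the order-4 spline and the Laplacian kernel is applied to the fitted
#' coefficients. Attenuates spatially broad (deep or volume-conducted)
#' activity; a spatially constant map is sent to (numerically) zero. Output is
#' scaled by `1 / head_radius^2`, i.e. microvolts per square metre for the
#' default 0.09 m head radius.
#'
#' @param rec an [eeg_recording()].
#' @param montage an [eeg_montage()].
#' @param lambda ridge regularization of the spline fit.
#' @param head_radius assumed scalp sphere radius in metres.
#' @return an `eeg_recording` of CSD values.
#' @export
surface_laplacian <- function(rec, montage, lambda = 1e-5, head_radius = 0.09) {
  mon <- montage_subset(montage, rec$channel_names)
  pos <- mon$positions
  k <- nrow(pos)
  G <- matrix(spline_g(tcrossprod(pos)), k, k)
  A <- rbind(cbind(G + diag(lambda, k), 1), c(rep(1, k), 0))
  Ainv <- solve(A)[seq_len(k), seq_len(k), drop = FALSE] # v -> c (drops c0 row)
  H <- matrix(spline_h(tcrossprod(pos)), k, k)
  L <- (H %*% Ainv) / head_radius^2
  rec$data <- rec$data %*% t(L)
  rec
}

#' Detect bad channels
#'
#' Two criteria, mirroring common automated-cleaning defaults: a channel is
#' flagged if (a) it is flat (near-zero sample-to-sample variation) for at
#' least `flatline_s` seconds, or (b) its correlation with the
#' spherical-spline estimate from all other channels falls below
#' `corr_threshold` in more than half of 1-second windows.
#'
#' @param rec an [eeg_recording()] of at least 10 s.
#' @param montage an [eeg_montage()].
#' @param corr_threshold neighbour-correlation threshold (default 0.8).
#' @param flatline_s flatline duration threshold in seconds (default 5).
#' @return character vector of flagged channel labels (possibly empty).
#' @export
detect_bad_channels <- function(rec, montage, corr_threshold = 0.8, flatline_s = 5) {
  if (rec_duration(rec) < 10) stop("need at least 10 s of data", call. = FALSE)
  X <- rec$data
  nch <- ncol(X)
  flagged <- logical(nch)

  # flatline: longest run of |diff| below an absolute floor
  dx <- abs(diff(X))
  thr_flat <- 1e-8
  for (ch in seq_len(nch)) {
    r <- rle(dx[, ch] < thr_flat)
    mx <- suppressWarnings(max(r$lengths[r$values], 0L))
    if (mx >= flatline_s * rec$fs) flagged[ch] <- TRUE
  }

  # best correlation with spherical-spline estimates from random neighbour
  # subsets (RANSAC-style): a channel is kept if at least one subset predicts
  # it well, so a few bad channels cannot drag their neighbours down
  mon <- montage_subset(montage, rec$channel_names)
  win <- max(1L, floor(rec$fs))
  n_win <- floor(nrow(X) / win)
  n_subsets <- 12L
  wi <- lapply(seq_len(n_win), function(w) ((w - 1L) * win + 1L):(w * win))
  with_seed(20221L, {
    for (ch in which(!flagged)) {
      others <- setdiff(seq_len(nch), ch)
      k <- max(4L, round(0.5 * length(others)))
      preds <- vapply(seq_len(n_subsets), function(s) {
        sub <- sample(others, k)
        op <- spline_operator(mon$positions[sub, , drop = FALSE],
                              mon$positions[ch, , drop = FALSE])
        drop(X[, sub, drop = FALSE] %*% t(op))
      }, numeric(nrow(X)))
      best_cors <- vapply(wi, function(i) {
        cc <- suppressWarnings(stats::cor(X[i, ch], preds[i, , drop = FALSE]))
        cc[is.na(cc)] <- 0
        max(cc)
      }, 0)
      if (stats::median(best_cors) < corr_threshold) flagged[ch] <- TRUE
    }
  })
  rec$channel_names[flagged]
}

#' Is a subject admissible given its flagged channels?
#'
#' Subjects with `max_bad` or more bad channels are excluded from microstate
#' analysis (the admissibility bound is exclusive: 4 flags pass, 5 fail at the
#' default).
#'
#' @param flagged vector of flagged channels (labels or indices).
#' @param max_bad exclusive upper bound on the number of bad channels
#'   (default 5).
#' @return `TRUE` if the subject is admissible.
#' @export
subject_admissible <- function(flagged, max_bad = 5) {
  length(flagged) < max_bad
}
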