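# Artifact subspace reconstruction, offline calibrate-then-clean form with
# Euclidean statistics. Calibration learns the clean-data mixing matrix and
# per-direction rejection thresholds; cleaning eigendecomposes each sliding
# window and reconstructs components whose variance exceeds the calibration
# threshold from the retained subspace.

mat_sqrt <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Calibrate ASR on low-artifact data
#'
#' Learns the statistics used by [asr_process()]: the mixing matrix (square
#' root of the calibration covariance) and, for each calibration principal
#' direction, a robust amplitude threshold `median + cutoff * 1.4826 * MAD`
#' of windowed component RMS.
#'
#' @param calibration an [eeg_recording()] (or matrix + `fs` attribute) of at
#'   least 30 s of relatively clean data, e.g. rest periods.
#' @param cutoff rejection threshold k in robust standard deviations
#'   (default 20; `Inf` disables rejection entirely).
#' @param window_s sliding-window length in seconds (default 0.5).
#' @return an object of class `asr_model`.
#' @export
asr_calibrate <- function(calibration, cutoff = 20, window_s = 0.5) {
  X <- if (inherits(calibration, "eeg_recording")) calibration$data else as.matrix(calibration)
  fs <- if (inherits(calibration, "eeg_recording")) calibration$fs else attr(calibration, "fs")
  if (is.null(fs)) stop("calibration needs a sampling rate", call. = FALSE)
  win <- round(window_s * fs)
  if (nrow(X) < max(30 * fs, 2 * win)) {
    stop("calibration data must cover at least 30 s", call. = FALSE)
  }
  C0 <- crossprod(X) / nrow(X)
  e <- eigen(C0, symmetric = TRUE)
  V <- e$vectors
  M <- mat_sqrt(C0)
  Y <- X %*% V
  starts <- seq(1L, nrow(X) - win + 1L, by = max(1L, win %/% 2L))
  rms <- t(vapply(starts, function(s) {
    sqrt(colMeans(Y[s:(s + win - 1L), , drop = FALSE]^2))
  }, numeric(ncol(X))))
  mu <- apply(rms, 2, stats::median)
  sig <- apply(rms, 2, stats::mad) # mad() already scales by 1.4826
  thresh <- mu + cutoff * sig
  structure(list(M = M, V = V, T = if (all(is.finite(thresh)))
    diag(thresh) %*% t(V) else NULL,
    cutoff = cutoff, window_s = window_s),
    class = "asr_model")
}

#' Clean data with a calibrated ASR model
#'
#' Sliding-window PCA in the signal space: per window, components whose
#' variance exceeds the calibration threshold along their direction are
#' dropped and reconstructed from the retained subspace via the calibration
#' mixing matrix; windows are blended by raised-cosine overlap-add. Data
#' statistically consistent with the calibration pass through (almost)
#' unchanged; `cutoff = Inf` is the identity.
#'
#' @param X numeric matrix `n_samples x n_channels`.
#' @param model an [asr_calibrate()] result.
#' @param fs sampling rate of `X` in Hz.
#' @return the cleaned matrix.
#' @export
asr_process <- function(X, model, fs) {
  if (is.infinite(model$cutoff) || is.null(model$T)) return(X)
  n <- nrow(X)
  win <- round(model$window_s * fs)
  if (n < win) return(X)
  hop <- max(1L, win %/% 2L)
  starts <- unique(c(seq(1L, n - win + 1L, by = hop), n - win + 1L))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(win) / (win + 1))
  out <- matrix(0, n, ncol(X))
  wsum <- numeric(n)
  Tm <- model$T
  for (s in starts) {
    i <- s:(s + win - 1L)
    Xw <- X[i, , drop = FALSE]
    Cw <- crossprod(Xw) / nrow(Xw)
    ew <- eigen(Cw, symmetric = TRUE)
    keep <- ew$values < colSums((Tm %*% ew$vectors)^2)
    if (all(keep)) {
      Yw <- Xw
    } else {
      VtM <- t(ew$vectors) %*% model$M
      VtM[!keep, ] <- 0
      R <- model$M %*% pracma::pinv(VtM) %*% t(ew$vectors)
      Yw <- Xw %*% t(R)
    }
    out[i, ] <- out[i, ] + w * Yw
    wsum[i] <- wsum[i] + w
  }
  out / wsum
}
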