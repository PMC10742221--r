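#' Preprocessing configuration
#'
#' Bundles the tunable parameters of the cleaning chain. Defaults follow
#' common automated-pipeline settings: downsample to 250 Hz, 1 Hz zero-phase
#' FIR high-pass, ASR cutoff 20, bad-channel exclusion at 5 or more flags,
#' and a 10 s task-onset analysis window.
#'
#' @param target_fs resampling target in Hz.
#' @param hp_cutoff high-pass cutoff in Hz.
#' @param line_freq mains frequency in Hz (60 for US recordings).
#' @param asr_cutoff ASR rejection threshold k (robust SDs).
#' @param bad_channel_corr_threshold neighbour-correlation threshold.
#' @param flatline_s flatline duration threshold in seconds.
#' @param max_bad_channels exclusive bound on bad channels per subject.
#' @param epoch_onset_s epoch start relative to the task trigger in seconds.
#' @param epoch_duration_s epoch length in seconds.
#' @param trigger_label marker label that starts a task epoch.
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_fs = 250, hp_cutoff = 1, line_freq = 60,
                              asr_cutoff = 20, bad_channel_corr_threshold = 0.8,
                              flatline_s = 5, max_bad_channels = 5,
                              epoch_onset_s = 0, epoch_duration_s = 10,
                              trigger_label = "start") {
  structure(as.list(environment()), class = "preprocess_config")
}

# reduced integer ratio p/q = target_fs/fs (rates taken to 1 mHz precision)
rate_ratio <- function(target_fs, fs) {
  p <- round(target_fs * 1000); q <- round(fs * 1000)
  g <- pracma::gcd(p, q)
  c(p, q) / g
}

# rational polyphase resampling by p/q: zero-stuff by p, zero-phase FIR
# anti-alias/anti-image lowpass at pi/max(p, q), pick every q-th sample.
# The symmetric FIR is applied with exact group-delay compensation, so the
# output has no residual lag.
resample_poly <- function(x, p, q) {
  n <- length(x)
  up <- numeric(n * p)
  up[seq(1, by = p, length.out = n)] <- x
  ord <- 20 * max(p, q)
  if (ord %% 2 == 1) ord <- ord + 1
  h <- signal::fir1(ord, 1 / max(p, q)) * p
  filt <- fir_zerophase(matrix(up, ncol = 1), h)[, 1]
  filt[seq(1, length(filt), by = q)]
}

#' Resample a recording (anti-aliased polyphase)
#'
#' Downsamples with `signal::resample` (polyphase FIR with anti-aliasing).
#' Event sample indices are rescaled by the rate ratio with round-half-even.
#'
#' @param rec an [eeg_recording()].
#' @param target_fs target rate in Hz; must not exceed `rec$fs`.
#' @return the resampled recording.
#' @export
resample_recording <- function(rec, target_fs) {
  if (target_fs > rec$fs) stop("upsampling is not supported", call. = FALSE)
  if (target_fs == rec$fs) return(rec)
  pq <- rate_ratio(target_fs, rec$fs)
  new_data <- apply(rec$data, 2, resample_poly, p = pq[1], q = pq[2])
  ev <- rec$events
  ev$sample <- as.integer(round(ev$sample * target_fs / rec$fs)) # round-half-even
  ev <- ev[ev$sample < nrow(new_data), , drop = FALSE]
  eeg_recording(new_data, target_fs, rec$channel_names, ev, rec$reference)
}

# zero-phase linear-phase FIR: reflect-pad, filter, compensate group delay
fir_zerophase <- function(X, h) {
  L <- length(h)
  d <- (L - 1) / 2
  n <- nrow(X)
  if (d >= n) stop("signal shorter than filter", call. = FALSE)
  pad_top <- X[(d + 1):2, , drop = FALSE]
  pad_bot <- X[(n - 1):(n - d), , drop = FALSE]
  Xp <- rbind(pad_top, X, pad_bot)
  out <- apply(Xp, 2, function(x) signal::fftfilt(h, x))
  out[(2 * d + 1):(2 * d + n), , drop = FALSE]
}

#' Zero-phase FIR high-pass filter
#'
#' Hamming-window FIR design (`signal::fir1`) with ~1 Hz transition width,
#' applied forward with exact group-delay compensation (linear phase, so the
#' net response has zero phase). Channel means are removed first, so constant
#' offsets map exactly to zero.
#'
#' @param rec an [eeg_recording()].
#' @param cutoff cutoff frequency in Hz, below Nyquist.
#' @param transition transition-band width in Hz used to size the filter.
#' @return the filtered recording.
#' @export
highpass_recording <- function(rec, cutoff, transition = 1) {
  if (cutoff >= rec$fs / 2) stop("cutoff must be below Nyquist", call. = FALSE)
  ord <- ceiling(3.3 * rec$fs / transition)
  if (ord %% 2 == 1) ord <- ord + 1 # even order -> odd length, integer delay
  h <- signal::fir1(ord, cutoff / (rec$fs / 2), type = "high")
  X <- sweep(rec$data, 2, colMeans(rec$data))
  rec$data <- fir_zerophase(X, h)
  rec
}

#' Remove mains line noise by sliding-window sinusoid regression
#'
#' Within overlapping windows, each channel is regressed on sine/cosine pairs
#' at the line frequency and its first harmonic, and the fit is subtracted.
#' Windows are combined by Hann-weighted overlap-add, so slowly varying line
#' amplitude/phase is tracked while broadband content is left intact (only a
#' rank-4 subspace per window is touched).
#'
#' @param rec an [eeg_recording()].
#' @param line_freq line frequency in Hz, below Nyquist.
#' @param window_s regression window length in seconds.
#' @return the cleaned recording.
#' @export
remove_line_noise <- function(rec, line_freq, window_s = 4) {
  if (line_freq >= rec$fs / 2) stop("line frequency must be below Nyquist", call. = FALSE)
  n <- n_samples(rec)
  win <- min(n, round(window_s * rec$fs))
  hop <- max(1L, win %/% 2L)
  freqs <- line_freq
  if (2 * line_freq < rec$fs / 2) freqs <- c(freqs, 2 * line_freq)
  starts <- unique(c(seq(1L, max(1L, n - win + 1L), by = hop), n - win + 1L))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(win) / (win + 1)) # Hann, nonzero ends
  fitted <- matrix(0, n, n_channels(rec))
  wsum <- numeric(n)
  for (s in starts) {
    i <- s:(s + win - 1L)
    tt <- (i - 1) / rec$fs
    B <- do.call(cbind, lapply(freqs, function(f)
      cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt))))
    fit <- B %*% qr.solve(B, rec$data[i, , drop = FALSE])
    fitted[i, ] <- fitted[i, ] + w * fit
    wsum[i] <- wsum[i] + w
  }
  rec$data <- rec$data - fitted / wsum
  rec
}

#' Re-reference to the common average
#'
#' Subtracts the per-sample mean across channels; idempotent, and sends a
#' single-channel recording to all zeros.
#'
#' @param rec an [eeg_recording()].
#' @return the re-referenced recording (reference set to "common-average").
#' @export
average_reference <- function(rec) {
  rec$data <- rec$data - rowMeans(rec$data)
  rec$reference <- "common-average"
  rec
}

#' Extract task epochs around trigger events
#'
#' One epoch per matching trigger, starting `onset_s` seconds after the
#' trigger (negative = before) and lasting `duration_s` seconds.
#'
#' @param rec an [eeg_recording()].
#' @param trigger_label marker label to epoch on (default "start").
#' @param onset_s epoch start relative to the trigger, seconds.
#' @param duration_s epoch length, seconds.
#' @param subject,trial,group optional annotations stored with the epochs.
#' @return an [eeg_epochs()] object.
#' @export
extract_task_epochs <- function(rec, trigger_label = "start", onset_s = 0,
                                duration_s = 10, subject = NA, trial = NA, group = NA) {
  trig <- rec$events$sample[rec$events$label == trigger_label]
  if (!length(trig)) stop("no '", trigger_label, "' trigger in recording", call. = FALSE)
  len <- round(duration_s * rec$fs)
  eps <- lapply(trig, function(s0) {
    a <- s0 + round(onset_s * rec$fs) # 0-based start
    if (a < 0) stop("epoch starts before the recording", call. = FALSE)
    if (a + len > n_samples(rec)) {
      stop("epoch extends past the end of the recording", call. = FALSE)
    }
    rec$data[(a + 1):(a + len), , drop = FALSE]
  })
  eeg_epochs(eps, rec$fs, subject = subject, trial = trial, group = group)
}

#' Run the full preprocessing chain on one recording
#'
#' Stage order: resample, high-pass, line-noise removal, bad-channel
#' detection and spherical-spline interpolation, common-average reference,
#' task epoching, ASR (calibrated on the pre-trigger rest), common-average
#' reference again, surface Laplacian. The executed stage order and
#' quality-control facts (flagged channels, admissibility) are attached as
#' the `manifest` attribute.
#'
#' @param rec an [eeg_recording()].
#' @param montage an [eeg_montage()].
#' @param config a [preprocess_config()].
#' @param subject,trial,group annotations carried into the epochs.
#' @param laplacian apply the final surface Laplacian (default TRUE).
#' @param asr apply ASR (default TRUE; needs >= 30 s of pre-trigger rest).
#' @return an [eeg_epochs()] with a `manifest` attribute (list with `stages`,
#'   `flagged_channels`, `admissible`), or `NULL` when the subject is
#'   excluded for too many bad channels.
#' @export
preprocess_recording <- function(rec, montage, config = preprocess_config(),
                                 subject = NA, trial = NA, group = NA,
                                 laplacian = TRUE, asr = TRUE) {
  stages <- character()
  push <- function(s) stages <<- c(stages, s)

  rec <- resample_recording(rec, config$target_fs); push("resample")
  rec <- highpass_recording(rec, config$hp_cutoff); push("highpass")
  rec <- remove_line_noise(rec, config$line_freq); push("line_noise")
  flagged <- detect_bad_channels(rec, montage,
                                 corr_threshold = config$bad_channel_corr_threshold,
                                 flatline_s = config$flatline_s)
  push("bad_channels")
  if (!subject_admissible(flagged, config$max_bad_channels)) {
    warning(sprintf("subject excluded: %d bad channels (>= %d)",
                    length(flagged), config$max_bad_channels), call. = FALSE)
    return(NULL)
  }
  if (length(flagged)) {
    rec <- interpolate_channels(rec, montage, flagged)
  }
  push("interpolate")
  rec <- average_reference(rec); push("average_reference")

  trig <- rec$events$sample[rec$events$label == config$trigger_label]
  asr_model <- NULL
  if (asr && length(trig) && trig[1] >= 30 * rec$fs) {
    calib <- rec
    calib$data <- rec$data[seq_len(trig[1]), , drop = FALSE]
    asr_model <- asr_calibrate(calib, cutoff = config$asr_cutoff)
  }
  ep <- extract_task_epochs(rec, config$trigger_label, config$epoch_onset_s,
                            config$epoch_duration_s,
                            subject = subject, trial = trial, group = group)
  push("epoch")
  if (!is.null(asr_model)) {
    ep$epochs <- lapply(ep$epochs, function(e) asr_process(e, asr_model, ep$fs))
    push("asr")
  }
  ep$epochs <- lapply(ep$epochs, function(e) e - rowMeans(e))
  push("average_reference")
  if (laplacian) {
    mon <- montage_subset(montage, rec$channel_names)
    ep$epochs <- lapply(ep$epochs, function(e) {
      r <- eeg_recording(e, ep$fs, rec$channel_names)
      surface_laplacian(r, mon)$data
    })
    push("laplacian")
  }
  attr(ep, "manifest") <- list(stages = stages, flagged_channels = flagged,
                               admissible = TRUE, config = unclass(config))
  ep
}
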