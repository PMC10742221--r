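# Synthetic two-group EEG with planted topographic structure. The generator
# emulates the study protocol this package targets: 32-channel 500 Hz
# recordings, repeated 3-min task epochs with rest periods and a 'start'
# trigger, and two groups whose task-onset EEG is dominated by different
# scalp prototypes over 1/f background, line noise, and optional bad channels.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Idealized 32-channel scalp montage
#'
#' A 10-10-style layout (Fp, F, FC, C, CP, P, PO, O rows) on the unit sphere,
#' head-centred: x toward the right ear, y toward the nasion, z toward the
#' vertex. Inclination/azimuth angles follow the usual proportional placement
#' of the extended 10-20 system.
#'
#' @return an [eeg_montage()] with 32 electrodes.
#' @export
standard_montage_32 <- function() {
  tab <- rbind(
    c("Cz", 0, 0), c("Fz", 36.8, 90), c("C3", 36.8, 180), c("C4", 36.8, 0),
    c("Pz", 36.8, -90),
    c("FC1", 33, 135), c("FC2", 33, 45), c("CP1", 33, -135), c("CP2", 33, -45),
    c("F3", 62, 129), c("F4", 62, 51), c("P3", 62, -129), c("P4", 62, -51),
    c("FC5", 66, 157), c("FC6", 66, 23), c("CP5", 66, -157), c("CP6", 66, -23),
    c("Fp1", 92, 108), c("Fp2", 92, 72), c("F7", 92, 147), c("F8", 92, 33),
    c("T7", 92, 180), c("T8", 92, 0), c("P7", 92, -147), c("P8", 92, -33),
    c("O1", 92, -108), c("O2", 92, -72), c("Oz", 92, -90),
    c("PO3", 78, -115), c("PO4", 78, -65), c("PO7", 92, -126), c("PO8", 92, -54)
  )
  th <- as.numeric(tab[, 2]) * pi / 180
  ph <- as.numeric(tab[, 3]) * pi / 180
  eeg_montage(tab[, 1], cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th)))
}

# smooth unit-norm zero-mean topography: Gaussian bump(s) on the sphere
bump_map <- function(positions, centers, signs, width = 0.9) {
  v <- numeric(nrow(positions))
  for (j in seq_len(nrow(centers))) {
    ang <- acos(pmin(pmax(positions %*% centers[j, ], -1), 1))
    v <- v + signs[j] * exp(-(ang / width)^2)
  }
  v <- v - mean(v)
  v / sqrt(sum(v^2))
}

sph_dir <- function(theta_deg, phi_deg) {
  th <- theta_deg * pi / 180; ph <- phi_deg * pi / 180
  c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

#' Build a bank of prototype scalp topographies
#'
#' Returns `K` unit-norm, zero-mean (i.e. average-referenced) topographies
#' with pairwise absolute spatial correlation below 0.7. The first prototype
#' is left-posterior-weighted and the second is a right-frontal/left-posterior
#' dipole, mimicking the two microstate classes that differ between skill
#' groups; further prototypes are randomly placed smooth maps.
#'
#' @param montage an [eeg_montage()].
#' @param K number of prototypes (2 <= K <= n_channels; K = 1 returns the
#'   left-posterior map alone).
#' @param seed integer seed (the bank is deterministic given the seed).
#' @param max_abs_cor pairwise absolute-correlation bound (default 0.7).
#' @return a `K x n_channels` matrix of prototypes, rows unit-norm.
#' @export
make_prototype_bank <- function(montage, K, seed = 1, max_abs_cor = 0.7) {
  P <- montage$positions
  nch <- nrow(P)
  if (K > nch) stop("K must not exceed the number of channels", call. = FALSE)
  if (K < 1) stop("K must be at least 1", call. = FALSE)
  bank <- matrix(0, K, nch, dimnames = list(NULL, montage$labels))
  # left lateral-posterior hotspot (inferior parietal / parieto-occipital)
  bank[1, ] <- bump_map(P, rbind(sph_dir(80, -150)), 1, width = 0.7)
  if (K >= 2) {
    # right-frontal positive / occipital negative dipole
    bank[2, ] <- bump_map(P, rbind(sph_dir(60, 50), sph_dir(85, -85)),
                          c(1, -1), width = 1.0)
  }
  if (K >= 3) {
    with_seed(seed, {
      k <- 3L
      tries <- 0L
      while (k <= K && tries < 500L) {
        tries <- tries + 1L
        nb <- sample(1:2, 1)
        ctr <- t(vapply(seq_len(nb), function(i)
          sph_dir(stats::runif(1, 0, 95), stats::runif(1, -180, 180)), numeric(3)))
        cand <- bump_map(P, ctr, sample(c(-1, 1), nb, replace = TRUE),
                         width = stats::runif(1, 0.6, 1.1))
        cors <- abs(stats::cor(cand, t(bank[seq_len(k - 1L), , drop = FALSE])))
        if (all(cors < max_abs_cor)) {
          bank[k, ] <- cand
          k <- k + 1L
        }
      }
      if (k <= K) stop("could not draw a prototype bank with the requested decorrelation",
                       call. = FALSE)
    })
  }
  bank
}

#' Specify a synthetic cohort simulation
#'
#' Defaults reproduce the emulated study conditions: 8 experts and 13 novices,
#' three trials each, 32 channels at 500 Hz, 180 s task and 120 s rest per
#' trial with a 'start' trigger, group-specific prototype weighting (experts
#' dominated by the left-posterior prototype 1, novices by the dipolar
#' prototype 2), 0 dB signal-to-noise over 1/f background, and 60 Hz line
#' noise.
#'
#' @param n_experts,n_novices,trials_per_subject cohort layout.
#' @param fs sampling rate in Hz.
#' @param task_s,rest_s,pre_trigger_s segment durations in seconds; the
#'   'start' trigger sits at `pre_trigger_s`.
#' @param montage an [eeg_montage()]; default [standard_montage_32()].
#' @param prototype_bank `K x n_channels` matrix; default
#'   `make_prototype_bank(montage, 6, seed)`.
#' @param expert_weights,novice_weights probability vectors over prototypes
#'   used during the task segment (rest uses uniform weights).
#' @param snr_db broadband signal-to-noise ratio on average-referenced power;
#'   `Inf` disables noise and line noise.
#' @param line_freq mains frequency in Hz.
#' @param bad_channel_prob per-channel probability of being replaced by
#'   uncorrelated noise.
#' @param signal_rms_uv target task-signal RMS in microvolts.
#' @param seed master integer seed; subject/trial streams are derived from it.
#' @return a list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_experts = 8, n_novices = 13, trials_per_subject = 3,
                            fs = 500, task_s = 180, rest_s = 120, pre_trigger_s = 30,
                            montage = standard_montage_32(),
                            prototype_bank = NULL,
                            expert_weights = NULL, novice_weights = NULL,
                            snr_db = 0, line_freq = 60, bad_channel_prob = 0,
                            signal_rms_uv = 10, seed = 1) {
  if (is.null(prototype_bank)) {
    prototype_bank <- make_prototype_bank(montage, 6, seed = seed)
  }
  K <- nrow(prototype_bank)
  default_w <- function(own) {
    w <- rep(if (K > 2) 0.55 / (K - 2) else 0, K)
    w[own] <- 0.40; w[c(1, 2)[c(1, 2) != own]] <- 0.05
    if (K == 1) w <- 1
    if (K == 2) w <- replace(rep(0.1, 2), own, 0.9)
    w / sum(w)
  }
  if (is.null(expert_weights)) expert_weights <- default_w(1L)
  if (is.null(novice_weights)) novice_weights <- default_w(min(2L, K))
  stopifnot(length(expert_weights) == K, length(novice_weights) == K,
            abs(sum(expert_weights) - 1) < 1e-8, abs(sum(novice_weights) - 1) < 1e-8,
            task_s > 0, rest_s > 0)
  structure(list(
    n_experts = n_experts, n_novices = n_novices,
    trials_per_subject = trials_per_subject, fs = fs,
    task_s = task_s, rest_s = rest_s, pre_trigger_s = pre_trigger_s,
    montage = montage, prototype_bank = prototype_bank,
    expert_weights = expert_weights, novice_weights = novice_weights,
    snr_db = snr_db, line_freq = line_freq, bad_channel_prob = bad_channel_prob,
    signal_rms_uv = signal_rms_uv, seed = seed
  ), class = "simulation_spec")
}

one_over_f_noise <- function(n, nch) {
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f) # two-sided frequency index
  shape <- ifelse(f == 0, 0, 1 / sqrt(f))
  vapply(seq_len(nch), function(i) {
    w <- stats::rnorm(n)
    Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
  }, numeric(n))
}

#' Simulate one subject-trial recording
#'
#' The signal is a piecewise-constant microstate sequence: dwell times are
#' uniform on 50-150 ms, each segment draws a prototype (group weights during
#' the task, uniform during pre-trigger and rest), and the active prototype is
#' scaled by a band-limited oscillation under a slow positive envelope. 1/f
#' background noise at the requested SNR, sinusoidal line noise, and optional
#' bad channels are added on top. A 'start' event marks the task onset.
#'
#' @param spec a [simulation_spec()].
#' @param group `"expert"` or `"novice"`.
#' @param subject_id,trial_id integers; together with `spec$seed` they fix the
#'   random stream, so repeated calls are bit-identical.
#' @return an [eeg_recording()].
#' @export
simulate_subject <- function(spec, group = c("expert", "novice"),
                             subject_id = 1, trial_id = 1) {
  group <- match.arg(group)
  seed <- (spec$seed * 1009L + subject_id * 131L + trial_id * 17L +
             (group == "expert") * 7L) %% .Machine$integer.max
  with_seed(seed, {
    fs <- spec$fs
    n_pre <- round(spec$pre_trigger_s * fs)
    n_task <- round(spec$task_s * fs)
    n <- n_pre + n_task + round(spec$rest_s * fs)
    P <- spec$prototype_bank
    K <- nrow(P)
    nch <- ncol(P)
    w_task <- if (group == "expert") spec$expert_weights else spec$novice_weights
    w_rest <- rep(1 / K, K)

    # piecewise-constant prototype index, dwell ~ U(50, 150) ms
    state <- integer(n)
    pos <- 1L
    while (pos <= n) {
      dwell <- max(1L, round(stats::runif(1, 0.05, 0.15) * fs))
      in_task <- pos > n_pre && pos <= n_pre + n_task
      w <- if (in_task) w_task else w_rest
      state[pos:min(n, pos + dwell - 1L)] <- sample.int(K, 1, prob = w)
      pos <- pos + dwell
    }

    # band-limited oscillation under a slow positive envelope
    bp <- signal::butter(4, c(4, 20) / (fs / 2), type = "pass")
    osc <- signal::filtfilt(bp, stats::rnorm(n))
    lp <- signal::butter(2, 0.5 / (fs / 2), type = "low")
    env <- 1 + 0.5 * tanh(signal::filtfilt(lp, stats::rnorm(n)) * 3)
    a <- osc * env
    S <- a * P[state, , drop = FALSE]

    ref <- S - rowMeans(S)
    sig_rms <- sqrt(mean(ref^2))
    S <- S * spec$signal_rms_uv / sig_rms

    if (is.finite(spec$snr_db)) {
      # spatially structured 1/f background: smooth random source maps mixed
      # onto the scalp (volume conduction) plus a small independent sensor
      # noise floor
      n_src <- 10L
      mix <- t(vapply(seq_len(n_src), function(j)
        bump_map(spec$montage$positions,
                 rbind(sph_dir(stats::runif(1, 0, 95),
                               stats::runif(1, -180, 180))), 1,
                 width = stats::runif(1, 0.8, 1.4)),
        numeric(nch)))
      src <- one_over_f_noise(n, n_src) %*% mix
      noise <- src + 0.08 * sqrt(mean(src^2)) * matrix(stats::rnorm(n * nch), n)
      noise_ref <- noise - rowMeans(noise)
      noise <- noise * (spec$signal_rms_uv / sqrt(mean(noise_ref^2))) /
        10^(spec$snr_db / 20)
      amp <- stats::runif(nch, 0.1, 0.3) * spec$signal_rms_uv
      phase <- stats::runif(1, 0, 2 * pi) + stats::runif(nch, -0.3, 0.3)
      tt <- (seq_len(n) - 1) / fs
      line <- outer(2 * pi * spec$line_freq * tt, rep(1, nch)) +
        matrix(phase, n, nch, byrow = TRUE)
      S <- S + noise + sin(line) * matrix(amp, n, nch, byrow = TRUE)
    }

    bad <- which(stats::runif(nch) < spec$bad_channel_prob)
    if (length(bad)) {
      S[, bad] <- matrix(stats::rnorm(n * length(bad)), n) *
        3 * spec$signal_rms_uv
    }

    rec <- eeg_recording(S, fs, colnames(P),
                         events = data.frame(sample = n_pre, label = "start"))
    attr(rec, "bad_channels") <- colnames(P)[bad]
    attr(rec, "state_sequence") <- state
    rec
  })
}

#' Simulate and write a full cohort
#'
#' One BrainVision triplet per subject-trial, plus a tab-separated cohort
#' manifest (`manifest.tsv`: subject, group, trial, path) and the scalar
#' simulation parameters as YAML (`simulation.yaml`).
#'
#' @param spec a [simulation_spec()].
#' @param out_dir output directory (created if missing).
#' @return the manifest as a tibble, invisibly also written to disk.
#' @export
simulate_cohort <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  subjects <- c(sprintf("E%02d", seq_len(spec$n_experts)),
                sprintf("N%02d", seq_len(spec$n_novices)))
  groups <- rep(c("expert", "novice"), c(spec$n_experts, spec$n_novices))
  sid <- 0L
  for (i in seq_along(subjects)) {
    sid <- sid + 1L
    for (tr in seq_len(spec$trials_per_subject)) {
      rec <- simulate_subject(spec, groups[i], subject_id = sid, trial_id = tr)
      base <- file.path(out_dir, sprintf("sub-%s_trial-%d", subjects[i], tr))
      write_recording(rec, base, format = "brainvision")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = subjects[i], group = groups[i], trial = tr,
        path = paste0(base, ".vhdr"))
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  scalars <- spec[!(names(spec) %in% c("montage", "prototype_bank"))]
  scalars$expert_weights <- as.numeric(scalars$expert_weights)
  scalars$novice_weights <- as.numeric(scalars$novice_weights)
  yaml::write_yaml(scalars, file.path(out_dir, "simulation.yaml"))
  write_montage(spec$montage, file.path(out_dir, "montage.tsv"))
  manifest
}

#' Simulate a labelled tensor dataset with a planted spatial signature
#'
#' Generates topographic `grid x grid x 360` tensors directly (bypassing the
#' raw-EEG path) for exercising the CNN branch: both classes share smooth
#' spatiotemporal background activity, and the expert class carries an extra
#' oscillatory component confined to one spatial quadrant of the grid
#' (default lower-left, i.e. the left parieto-occipital corner of the
#' projected scalp). With `transient = FALSE` only the expert class carries
#' the component, sustained over the whole window. With `transient = TRUE`
#' both classes carry it at equal whole-window energy, but for experts it is
#' concentrated in a 20% time sub-window (a burst) while for novices it is
#' sustained — whole-window variance is then identical between classes, so
#' only temporally resolved features can separate them.
#'
#' @param n_per_class tensors per class.
#' @param effect amplitude of the planted component relative to background.
#' @param quadrant one of "lower-left", "lower-right", "upper-left",
#'   "upper-right".
#' @param transient confine the signature to a 20% time sub-window.
#' @param grid spatial grid size (default 16).
#' @param t_len temporal depth in samples at 120 Hz (default 360).
#' @param seed integer seed.
#' @return an [eeg_tensor_dataset()].
#' @export
simulate_tensor_dataset <- function(n_per_class = 60, effect = 1.5,
                                    quadrant = "lower-left", transient = FALSE,
                                    grid = 16, t_len = 360, seed = 1) {
  half <- grid / 2
  rows <- switch(quadrant,
                 "lower-left" = , "lower-right" = (half + 1):grid,
                 "upper-left" = , "upper-right" = 1:half,
                 stop("unknown quadrant", call. = FALSE))
  cols <- switch(quadrant,
                 "lower-left" = , "upper-left" = 1:half,
                 (half + 1):grid)
  with_seed(seed, {
    # smooth spatial signature map inside the quadrant
    cr <- stats::runif(1, min(rows) + 2, max(rows) - 2)
    cc <- stats::runif(1, min(cols) + 2, max(cols) - 2)
    gx <- outer(seq_len(grid), seq_len(grid), function(r, c)
      exp(-((r - cr)^2 + (c - cc)^2) / (2 * 2.2^2)))
    mask <- matrix(0, grid, grid); mask[rows, cols] <- 1
    sig_map <- gx * mask
    sig_map <- sig_map / sqrt(mean(sig_map^2))

    n_bg <- 8L
    fs <- 120
    tt <- (seq_len(t_len) - 1) / fs
    w <- round(0.2 * t_len)

    N <- 2L * n_per_class
    tensors <- array(0, c(N, grid, grid, t_len))
    labels <- rep(c("expert", "novice"), each = n_per_class)
    for (i in seq_len(N)) {
      maps <- vapply(seq_len(n_bg), function(j) {
        r0 <- stats::runif(1, 3, grid - 2); c0 <- stats::runif(1, 3, grid - 2)
        m <- outer(seq_len(grid), seq_len(grid), function(r, c)
          exp(-((r - r0)^2 + (c - c0)^2) / (2 * 2.5^2)))
        as.vector(m / sqrt(mean(m^2)))
      }, numeric(grid * grid))
      series <- vapply(seq_len(n_bg), function(j)
        sin(2 * pi * stats::runif(1, 3, 18) * tt + stats::runif(1, 0, 2 * pi)),
        numeric(t_len))
      X <- maps %*% t(series) + 0.3 * matrix(stats::rnorm(grid * grid * t_len), grid * grid)
      f <- stats::runif(1, 8, 12)
      osc <- sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
      if (!transient) {
        if (labels[i] == "expert") {
          X <- X + effect * as.vector(sig_map) %*% t(osc)
        }
      } else {
        # equal whole-window energy: expert burst vs novice sustained
        if (labels[i] == "expert") {
          s0 <- sample.int(t_len - w, 1)
          t_sig <- numeric(t_len); t_sig[s0:(s0 + w - 1L)] <- 1
          X <- X + (effect / sqrt(w / t_len)) * as.vector(sig_map) %*% t(osc * t_sig)
        } else {
          X <- X + effect * as.vector(sig_map) %*% t(osc)
        }
      }
      tensors[i, , , ] <- array(X, c(grid, grid, t_len))
    }
    info <- tibble::tibble(label = labels,
                           subject = paste0(substr(labels, 1, 1),
                                            rep(seq_len(n_per_class), 2)),
                           trial = 1L, window = seq_len(N))
    eeg_tensor_dataset(tensors, info, fs = fs)
  })
}
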