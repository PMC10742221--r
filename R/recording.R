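#' Construct a continuous multichannel EEG recording
#'
#' The central container of the package: a samples-by-channels matrix of scalp
#' potentials in microvolts, with its sampling rate, channel labels, event
#' markers, and reference state. All downstream stages (preprocessing,
#' microstate segmentation, CSP, tensorization) consume and return this class.
#'
#' Event sample indices are 0-based offsets from the start of the recording
#' (sample 0 is t = 0 s), so an event at t seconds sits at `round(t * fs)`.
#' All sample intervals in the package are half-open `[start, end)`.
#'
#' @param data numeric matrix, `n_samples x n_channels`, in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector of unique channel labels, one per
#'   column of `data`.
#' @param events a data frame with columns `sample` (0-based index) and
#'   `label`, or `NULL` for none.
#' @param reference `"as-recorded"` or `"common-average"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names = colnames(data),
                          events = NULL, reference = c("as-recorded", "common-average")) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channel_names)) {
    channel_names <- sprintf("E%d", seq_len(ncol(data)))
  }
  if (length(channel_names) != ncol(data)) {
    stop("`channel_names` must have one entry per data column", call. = FALSE)
  }
  if (anyDuplicated(channel_names)) {
    stop("channel names must be unique", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  if (anyNA(data)) stop("recording data must not contain NA/NaN", call. = FALSE)
  if (is.null(events)) {
    events <- tibble::tibble(sample = integer(), label = character())
  } else {
    events <- tibble::as_tibble(events)
    stopifnot(all(c("sample", "label") %in% names(events)))
    events$sample <- as.integer(round(events$sample))
    events$label <- as.character(events$label)
    if (nrow(events) && (min(events$sample) < 0L || max(events$sample) >= nrow(data))) {
      stop("event sample indices must lie in [0, n_samples)", call. = FALSE)
    }
  }
  colnames(data) <- channel_names
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         events = events, reference = reference),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples x %d channels @ %g Hz (%.1f s), %d event(s), reference: %s\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs,
              nrow(x$events), x$reference))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_samples <- function(rec) nrow(rec$data)
n_channels <- function(rec) ncol(rec$data)

#' Duration of a recording in seconds
#' @param rec an [eeg_recording()].
#' @return length in seconds.
#' @export
rec_duration <- function(rec) n_samples(rec) / rec$fs

#' Construct an electrode montage
#'
#' Head-centred 3-D electrode positions (x = right ear, y = nasion, z = vertex),
#' normalized to the unit sphere. Used for spherical-spline interpolation, the
#' surface Laplacian, and the azimuthal equidistant grid projection.
#'
#' @param labels character vector of unique electrode labels.
#' @param positions numeric matrix `n x 3` of positions; each row is
#'   normalized to unit length.
#' @return An object of class `eeg_montage` with fields `labels` and
#'   `positions` (unit-norm rows).
#' @export
eeg_montage <- function(labels, positions) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("`positions` must be an n x 3 matrix", call. = FALSE)
  if (length(labels) != nrow(positions)) {
    stop("`labels` must match the number of position rows", call. = FALSE)
  }
  if (anyDuplicated(labels)) stop("montage labels must be unique", call. = FALSE)
  nrm <- sqrt(rowSums(positions^2))
  if (any(nrm == 0)) stop("electrode positions must be nonzero", call. = FALSE)
  positions <- positions / nrm
  rownames(positions) <- labels
  structure(list(labels = as.character(labels), positions = positions),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d electrodes: %s ...\n", length(x$labels),
              paste(utils::head(x$labels, 6), collapse = ", ")))
  invisible(x)
}

#' Reorder/subset a montage to match a set of channel labels
#' @param montage an [eeg_montage()].
#' @param labels channel labels to select, in order.
#' @return an `eeg_montage` restricted to `labels`.
#' @export
montage_subset <- function(montage, labels) {
  idx <- match(labels, montage$labels)
  if (anyNA(labels) || anyNA(idx)) {
    stop("label(s) absent from montage: ",
         paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  eeg_montage(montage$labels[idx], montage$positions[idx, , drop = FALSE])
}

#' A set of equal-shape task epochs
#'
#' @param epochs list of `n_samples x n_channels` matrices, all identical in
#'   shape.
#' @param fs sampling rate in Hz.
#' @param subject,trial,group optional annotations (recycled to the number of
#'   epochs).
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(epochs, fs, subject = NA_character_,
                       trial = NA_integer_, group = NA_character_) {
  stopifnot(is.list(epochs), length(epochs) >= 1L)
  d <- dim(epochs[[1]])
  ok <- vapply(epochs, function(e) identical(dim(e), d), logical(1))
  if (!all(ok)) stop("all epochs must share the same shape", call. = FALSE)
  n <- length(epochs)
  structure(
    list(epochs = epochs, fs = fs,
         info = tibble::tibble(subject = rep_len(as.character(subject), n),
                               trial = rep_len(as.integer(trial), n),
                               group = rep_len(as.character(group), n))),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$epochs[[1]])
  cat(sprintf("<eeg_epochs> %d epoch(s) of %d samples x %d channels @ %g Hz\n",
              length(x$epochs), d[1], d[2], x$fs))
  invisible(x)
}
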