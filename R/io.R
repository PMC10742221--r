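#' Read an EEG recording from disk
#'
#' Supports BrainVision triplets (`.vhdr`/`.vmrk`/`.eeg`, binary multiplexed
#' IEEE float32 or int16-with-resolution) and EDF+ files with annotations.
#' Data are returned in microvolts; event markers become rows of
#' `rec$events` with 0-based sample indices.
#'
#' @param path path to the `.vhdr` (BrainVision) or `.edf` file.
#' @param format `"brainvision"`, `"edf"`, or `"auto"` (by extension).
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "brainvision", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     vhdr = "brainvision", edf = "edf",
                     stop("cannot infer format from extension of ", path, call. = FALSE))
  }
  switch(format,
         brainvision = read_brainvision(path),
         edf = read_edf(path))
}

#' Write an EEG recording to disk
#'
#' The inverse of [read_recording()]: `read_recording(write_recording(rec))`
#' reproduces the data to within the format's quantization (exact for
#' float32 up to rounding at ~7 significant digits; int16 and EDF quantize to
#' their per-channel resolution).
#'
#' @param rec an [eeg_recording()]; must be free of NA/NaN.
#' @param path output path: basename for BrainVision (the three extensions are
#'   appended), full `.edf` path for EDF+.
#' @param format `"brainvision"` or `"edf"`.
#' @param binary_format for BrainVision: `"IEEE_FLOAT_32"` or `"INT_16"`.
#' @return the header/file path, invisibly.
#' @export
write_recording <- function(rec, path, format = c("brainvision", "edf"),
                            binary_format = c("IEEE_FLOAT_32", "INT_16")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "eeg_recording"))
  if (anyNA(rec$data) || any(!is.finite(rec$data))) {
    stop("refusing to write non-finite data", call. = FALSE)
  }
  switch(format,
         brainvision = write_brainvision(rec, path, match.arg(binary_format)),
         edf = write_edf(rec, path))
}

## ---- BrainVision ----------------------------------------------------------

write_brainvision <- function(rec, basename, binary_format = "IEEE_FLOAT_32") {
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eeg <- paste0(basename, ".eeg")
  nchan <- n_channels(rec)
  if (binary_format == "INT_16") {
    res <- pmax(apply(abs(rec$data), 2, max), .Machine$double.eps) / 32000
  } else {
    res <- rep(1, nchan)
  }
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", basename(eeg)),
    paste0("MarkerFile=", basename(vmrk)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nchan),
    sprintf("SamplingInterval=%.10g", 1e6 / rec$fs),
    "",
    "[Binary Infos]",
    paste0("BinaryFormat=", binary_format),
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%.12g,µV", seq_len(nchan), rec$channel_names, res)
  )
  writeLines(hdr, vhdr, useBytes = TRUE)

  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", basename(eeg)),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000"
  )
  if (nrow(rec$events)) {
    # marker positions are 1-based in the file
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(rec$events)) + 1L,
                        rec$events$label, rec$events$sample + 1L))
  }
  writeLines(mk, vmrk, useBytes = TRUE)

  con <- file(eeg, "wb")
  on.exit(close(con))
  x <- t(rec$data) # multiplexed: channels fastest
  if (binary_format == "INT_16") {
    q <- round(x / res) # res recycles down columns of t(data) = channels
    q <- pmax(pmin(q, 32767), -32768)
    writeBin(as.integer(q), con, size = 2L, endian = "little")
  } else {
    writeBin(as.vector(x), con, size = 4L, endian = "little")
  }
  invisible(vhdr)
}

parse_bv_ini <- function(lines) {
  sec <- NA_character_
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      out[[sec]] <- character()
    } else if (grepl("=", ln, fixed = TRUE) && !is.na(sec)) {
      key <- sub("=.*$", "", ln)
      val <- sub("^[^=]*=", "", ln)
      out[[sec]][key] <- val
    }
  }
  out
}

read_brainvision <- function(vhdr_path) {
  if (!file.exists(vhdr_path)) stop("no such file: ", vhdr_path, call. = FALSE)
  ini <- parse_bv_ini(readLines(vhdr_path, warn = FALSE, encoding = "UTF-8"))
  ci <- ini[["Common Infos"]]
  if (is.null(ci) || is.na(ci["NumberOfChannels"]) || is.na(ci["SamplingInterval"])) {
    stop("malformed BrainVision header: missing Common Infos", call. = FALSE)
  }
  nchan <- as.integer(ci["NumberOfChannels"])
  fs <- 1e6 / as.numeric(ci["SamplingInterval"])
  if (!identical(unname(toupper(ci["DataOrientation"])), "MULTIPLEXED")) {
    stop("only MULTIPLEXED BrainVision data are supported", call. = FALSE)
  }
  binfmt <- unname(toupper(ini[["Binary Infos"]]["BinaryFormat"]))
  chinfo <- ini[["Channel Infos"]]
  if (is.null(chinfo) || length(chinfo) < nchan) {
    stop("header integrity error: ", length(chinfo), " channel entries for ",
         nchan, " declared channels", call. = FALSE)
  }
  parts <- strsplit(unname(chinfo[seq_len(nchan)]), ",", fixed = TRUE)
  ch_names <- vapply(parts, `[`, "", 1L)
  res <- vapply(parts, function(p) {
    r <- suppressWarnings(as.numeric(p[3]))
    if (is.na(r) || r == 0) 1 else r
  }, 0)

  dir <- dirname(vhdr_path)
  eeg_path <- file.path(dir, ci["DataFile"])
  if (!file.exists(eeg_path)) stop("data file not found: ", eeg_path, call. = FALSE)
  bytes <- if (identical(binfmt, "INT_16")) 2L else 4L
  fsz <- file.size(eeg_path)
  if (fsz %% (bytes * nchan) != 0) {
    stop("integrity error: data size ", fsz, " bytes is not a multiple of ",
         bytes, " x ", nchan, " channels", call. = FALSE)
  }
  nsamp <- fsz / (bytes * nchan)
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  if (identical(binfmt, "INT_16")) {
    raw <- readBin(con, "integer", n = nsamp * nchan, size = 2L,
                   signed = TRUE, endian = "little")
    x <- matrix(as.double(raw), nrow = nchan) * res
  } else {
    raw <- readBin(con, "double", n = nsamp * nchan, size = 4L, endian = "little")
    x <- matrix(raw, nrow = nchan)
  }
  data <- t(x)

  events <- tibble::tibble(sample = integer(), label = character())
  vmrk_path <- file.path(dir, ci["MarkerFile"])
  if (!is.na(ci["MarkerFile"]) && file.exists(vmrk_path)) {
    mi <- parse_bv_ini(readLines(vmrk_path, warn = FALSE, encoding = "UTF-8"))[["Marker Infos"]]
    if (!is.null(mi)) {
      mparts <- strsplit(unname(mi), ",")
      keep <- vapply(mparts, function(p) length(p) >= 3 && p[1] != "New Segment", logical(1))
      if (any(keep)) {
        events <- tibble::tibble(
          sample = vapply(mparts[keep], function(p) as.integer(p[3]), 0L) - 1L,
          label = vapply(mparts[keep], function(p) if (nzchar(p[2])) p[2] else p[1], "")
        )
      }
    }
  }
  eeg_recording(data, fs, ch_names, events)
}

## ---- EDF+ -----------------------------------------------------------------

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  nchan <- n_channels(rec)
  ns <- nchan + 1L # + annotations channel
  nsamp <- n_samples(rec)
  rec_dur <- nsamp / rec$fs

  pmin_ <- apply(rec$data, 2, min)
  pmax_ <- apply(rec$data, 2, max)
  flat <- pmax_ - pmin_ < .Machine$double.eps
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767

  # annotation payload: one record holding all events as TALs
  tal <- paste0("+0\x14\x14")
  if (nrow(rec$events)) {
    tal <- paste0(tal, paste0(sprintf("+%.7g\x14%s\x14", rec$events$sample / rec$fs,
                                      rec$events$label), collapse = ""))
  }
  tal_raw <- c(charToRaw(tal), as.raw(0))
  if (length(tal_raw) %% 2 == 1) tal_raw <- c(tal_raw, as.raw(0))
  ann_spr <- length(tal_raw) / 2

  hdr_bytes <- 256L + 256L * ns
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(paste(edf_pad(x, width), collapse = ""),
                                     con, nchars = width * length(x), eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(hdr_bytes, 8); wr("EDF+C", 44); wr(1L, 8)
  wr(sprintf("%.6g", rec_dur), 8); wr(ns, 4)
  labels <- c(rec$channel_names, "EDF Annotations")
  wr(labels, 16); wr(rep("", ns), 80)
  wr(c(rep("uV", nchan), ""), 8)
  wr(c(sprintf("%.8g", pmin_), "-1"), 8)
  wr(c(sprintf("%.8g", pmax_), "1"), 8)
  wr(c(rep(dmin, nchan), dmin), 8)
  wr(c(rep(dmax, nchan), dmax), 8)
  wr(rep("", ns), 80)
  wr(c(rep(nsamp, nchan), ann_spr), 8)
  wr(rep("", ns), 32)

  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (ch in seq_len(nchan)) {
    dig <- round((rec$data[, ch] - pmin_[ch]) / scale[ch]) + dmin
    writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L, endian = "little")
  }
  writeBin(tal_raw, con)
  invisible(path)
}

read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width, n = 1L) {
    vapply(seq_len(n), function(i) trimws(readChar(con, width, useBytes = TRUE)), "")
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- rd(16, ns); rd(80, ns); rd(8, ns)
  pmin_ <- as.numeric(rd(8, ns)); pmax_ <- as.numeric(rd(8, ns))
  dmin <- as.numeric(rd(8, ns)); dmax <- as.numeric(rd(8, ns))
  rd(80, ns); spr <- as.integer(rd(8, ns)); rd(32, ns)
  if (is.na(hdr_bytes) || hdr_bytes != 256L + 256L * ns) {
    stop("malformed EDF header", call. = FALSE)
  }
  is_ann <- labels == "EDF Annotations"
  sig_idx <- which(!is_ann)
  nchan <- length(sig_idx)
  fs <- spr[sig_idx[1]] / rec_dur
  if (!all(abs(spr[sig_idx] / rec_dur - fs) < 1e-9)) {
    stop("mixed sampling rates are not supported", call. = FALSE)
  }
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  data <- matrix(0, spr[sig_idx[1]] * n_rec, nchan)
  ann_raw <- raw()
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      if (is_ann[s]) {
        ann_raw <- c(ann_raw, readBin(con, "raw", n = spr[s] * 2L))
      } else {
        dig <- readBin(con, "integer", n = spr[s], size = 2L,
                       signed = TRUE, endian = "little")
        j <- match(s, sig_idx)
        data[(r - 1L) * spr[s] + seq_len(spr[s]), j] <-
          (dig - dmin[s]) * scale[s] + pmin_[s]
      }
    }
  }
  events <- tibble::tibble(sample = integer(), label = character())
  if (length(ann_raw)) {
    txt <- strsplit(rawToChar(ann_raw[ann_raw != as.raw(0)]), "\x14", fixed = TRUE)[[1]]
    # pairs of (onset[, duration], label); empty labels are timestamps
    onsets <- c(); labs <- c()
    i <- 1
    while (i < length(txt)) {
      on_str <- sub("\x15.*$", "", txt[i])
      lab <- txt[i + 1]
      if (nzchar(lab)) { onsets <- c(onsets, as.numeric(on_str)); labs <- c(labs, lab) }
      i <- i + 2
    }
    if (length(onsets)) {
      events <- tibble::tibble(sample = as.integer(round(onsets * fs)), label = labs)
    }
  }
  eeg_recording(data, fs, labels[sig_idx], events)
}

## ---- Montage files --------------------------------------------------------

#' Load an electrode montage from a delimited text file
#'
#' Expects columns `label`, `x`, `y`, `z` (header optional, tab/whitespace
#' separated). Positions are normalized onto the unit sphere.
#'
#' @param path path to the montage table.
#' @return an [eeg_montage()].
#' @export
load_montage <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("label", first, ignore.case = TRUE)
  tab <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("montage table needs columns label, x, y, z", call. = FALSE)
  names(tab)[1:4] <- c("label", "x", "y", "z")
  eeg_montage(tab$label, as.matrix(tab[, c("x", "y", "z")]))
}

#' Write a montage to a TSV file
#' @param montage an [eeg_montage()].
#' @param path output path.
#' @export
write_montage <- function(montage, path) {
  df <- data.frame(label = montage$labels, montage$positions)
  names(df) <- c("label", "x", "y", "z")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
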