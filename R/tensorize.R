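# Topography-preserving tensorization: azimuthal equidistant projection of
# the montage onto a 16x16 grid, biharmonic-spline ("v4") frame
# interpolation, and 3 s / 1 s sliding-window segmentation at 120 Hz.

#' Project a montage onto a square grid (azimuthal equidistant)
#'
#' Projection centred at the vertex: radial grid distance is proportional to
#' the polar angle and azimuth is preserved, so electrodes at equal polar
#' angle land at equal distance from the grid centre. Coordinates are scaled
#' to fit the grid with a 1-cell margin; continuous coordinates are kept for
#' interpolation (rounding is only used for the injectivity check). Grid rows
#' run from the nasion (row 1) to the occiput (row `grid`), columns from left
#' (col 1) to right, so the lower-left quadrant is the left parieto-occipital
#' scalp.
#'
#' @param montage an [eeg_montage()].
#' @param grid grid size (default 16).
#' @param margin margin in cells kept free around the electrode cloud.
#' @return an object of class `grid_projection`: `coords` (`n x 2`, columns
#'   row/col, 0-based in `[0, grid-1]`), `grid`, `mask` (`grid x grid`
#'   logical, cells inside the electrode convex hull), `labels`.
#' @export
project_montage <- function(montage, grid = 16, margin = 1) {
  P <- montage$positions
  if (any(P[, 3] <= -1 + 1e-12)) {
    stop("electrode at the antipode of the projection centre", call. = FALSE)
  }
  theta <- acos(pmin(pmax(P[, 3], -1), 1)) # polar angle from vertex
  az <- atan2(P[, 2], P[, 1])
  x <- theta * cos(az) # toward right ear
  y <- theta * sin(az) # toward nasion
  ctr <- (grid - 1) / 2
  scale <- (grid - 1 - 2 * margin) / (2 * max(sqrt(x^2 + y^2)))
  col <- ctr + scale * x
  row <- ctr - scale * y # row grows toward the occiput
  coords <- cbind(row = row, col = col)
  rounded <- paste(round(row), round(col))
  if (anyDuplicated(rounded)) {
    warning("projection is not injective at this grid size: ",
            sum(duplicated(rounded)), " shared cell(s)", call. = FALSE)
  }
  hull <- grDevices::chull(col, row)
  bnd <- list(x = col[hull], y = row[hull])
  cells <- expand.grid(row = 0:(grid - 1), col = 0:(grid - 1))
  inside <- mgcv::in.out(cbind(c(bnd$x, bnd$x[1]), c(bnd$y, bnd$y[1])),
                         cbind(cells$col, cells$row))
  mask <- matrix(FALSE, grid, grid)
  mask[cbind(cells$row + 1L, cells$col + 1L)] <- inside
  # electrode cells always count as inside
  mask[cbind(pmin(pmax(round(row), 0), grid - 1) + 1L,
             pmin(pmax(round(col), 0), grid - 1) + 1L)] <- TRUE
  structure(list(coords = coords, grid = grid, mask = mask,
                 labels = montage$labels,
                 operator = NULL),
            class = "grid_projection")
}

# biharmonic Green's function in 2-D; G(0) = 0
green_biharm <- function(r) {
  out <- r^2 * (log(r) - 1)
  out[r == 0] <- 0
  out
}

# dense interpolation operator: values at electrodes -> values at `targets`
# (targets as n x 2 row/col). Exact collocation through the Green's matrix
# A = G(r_ij), augmented with a constant term (coefficients summing to zero)
# so that constant maps are reproduced exactly everywhere.
biharm_operator <- function(coords, targets) {
  D <- as.matrix(stats::dist(coords))
  if (any(D[upper.tri(D)] < 1e-9)) {
    stop("duplicate electrode coordinates in projection", call. = FALSE)
  }
  k <- nrow(coords)
  A <- rbind(cbind(green_biharm(D), 1), c(rep(1, k), 0))
  Dt <- sqrt(outer(targets[, 1], coords[, 1], "-")^2 +
               outer(targets[, 2], coords[, 2], "-")^2)
  B <- cbind(green_biharm(Dt), 1)
  (B %*% solve(A))[, seq_len(k), drop = FALSE]
}

proj_grid_operator <- function(proj) {
  if (!is.null(proj$operator)) return(proj$operator)
  g <- proj$grid
  cells <- cbind(rep(0:(g - 1), times = g), rep(0:(g - 1), each = g)) # row, col
  op <- biharm_operator(proj$coords, cells)
  op[!as.vector(proj$mask), ] <- 0
  op
}

#' Interpolate one topographic frame onto the grid
#'
#' Biharmonic (Green's function) scattered-data interpolation of a channel
#' vector at the projected electrode coordinates: exact at the electrodes,
#' smooth in between, zero outside the electrode convex hull.
#'
#' @param values numeric channel vector (same order as the projected
#'   montage).
#' @param proj a [project_montage()] result.
#' @return a `grid x grid` matrix.
#' @export
interpolate_frame <- function(values, proj) {
  op <- proj_grid_operator(proj)
  matrix(op %*% values, proj$grid, proj$grid)
}

#' Evaluate the biharmonic interpolant at arbitrary grid coordinates
#'
#' @param values channel vector.
#' @param proj a [project_montage()] result.
#' @param points `n x 2` matrix of (row, col) coordinates.
#' @return numeric vector of interpolated values.
#' @export
interpolate_at <- function(values, proj, points) {
  drop(biharm_operator(proj$coords, as.matrix(points)) %*% values)
}

#' Sliding-window segmentation of an epoch
#'
#' Maximal number of full windows of `window_s` seconds advancing by
#' `step_s`: for a span of `S` seconds that is `floor(S - window_s) + 1`
#' windows (at the default 3 s / 1 s).
#'
#' @param X `n x C` matrix (typically at 120 Hz).
#' @param fs sampling rate of `X`.
#' @param window_s window length in seconds (default 3).
#' @param step_s hop in seconds (default 1).
#' @return list of `window_s * fs` row matrices (possibly empty, with a
#'   warning, when the epoch is shorter than one window).
#' @export
window_segments <- function(X, fs, window_s = 3, step_s = 1) {
  X <- as.matrix(X)
  wlen <- round(window_s * fs)
  hop <- round(step_s * fs)
  if (nrow(X) < wlen) {
    warning("epoch shorter than one window: returning no segments", call. = FALSE)
    return(list())
  }
  starts <- seq(1L, nrow(X) - wlen + 1L, by = hop)
  lapply(starts, function(s) X[s:(s + wlen - 1L), , drop = FALSE])
}

#' Construct a labelled tensor dataset
#'
#' @param tensors `N x grid x grid x T` numeric array.
#' @param info tibble with one row per tensor: `label` ("expert"/"novice"),
#'   `subject`, `trial`, `window`.
#' @param fs temporal sampling rate of the tensors (Hz).
#' @param proj optional [project_montage()] used to build the tensors.
#' @return an object of class `eeg_tensor_dataset`.
#' @export
eeg_tensor_dataset <- function(tensors, info, fs = 120, proj = NULL) {
  stopifnot(length(dim(tensors)) == 4, nrow(info) == dim(tensors)[1])
  info <- tibble::as_tibble(info)
  stopifnot(all(c("label", "subject", "trial", "window") %in% names(info)))
  bad <- setdiff(unique(info$label), c("expert", "novice"))
  if (length(bad)) stop("labels must be 'expert'/'novice'", call. = FALSE)
  structure(list(tensors = tensors, info = info, fs = fs, proj = proj),
            class = "eeg_tensor_dataset")
}

#' @export
print.eeg_tensor_dataset <- function(x, ...) {
  d <- dim(x$tensors)
  cat(sprintf("<eeg_tensor_dataset> %d tensors of %dx%dx%d @ %g Hz (%d expert / %d novice)\n",
              d[1], d[2], d[3], d[4], x$fs,
              sum(x$info$label == "expert"), sum(x$info$label == "novice")))
  invisible(x)
}

#' Subset a tensor dataset by tensor index
#' @param dataset an [eeg_tensor_dataset()].
#' @param idx integer indices.
#' @return the subset dataset.
#' @export
tensor_subset <- function(dataset, idx) {
  eeg_tensor_dataset(dataset$tensors[idx, , , , drop = FALSE],
                     dataset$info[idx, , drop = FALSE],
                     fs = dataset$fs, proj = dataset$proj)
}

#' Build a topographic tensor dataset from preprocessed epochs
#'
#' Each epoch (already at the analysis rate, typically 250 Hz) is resampled
#' to `target_fs` (120 Hz), cut into sliding windows, and every window is
#' projected frame-by-frame onto the grid, yielding one
#' `grid x grid x (window_s * target_fs)` tensor per window with subject,
#' trial, and window annotations. The per-frame interpolation is a single
#' precomputed linear operator, so tensorization is linear in the input
#' signal.
#'
#' @param epoch_sets list of [eeg_epochs()] objects (one per subject-trial;
#'   group/subject/trial are read from their `info`).
#' @param montage an [eeg_montage()].
#' @param grid grid size (default 16).
#' @param target_fs tensor sampling rate (default 120).
#' @param window_s,step_s windowing parameters (default 3 and 1 s).
#' @return an [eeg_tensor_dataset()].
#' @export
build_tensor_dataset <- function(epoch_sets, montage, grid = 16,
                                 target_fs = 120, window_s = 3, step_s = 1) {
  proj <- NULL
  tensors <- list()
  rows <- list()
  for (es in epoch_sets) {
    if (is.null(es)) next
    if (is.null(proj)) {
      mon <- montage_subset(montage, colnames(es$epochs[[1]]) %||% montage$labels)
      proj <- project_montage(mon, grid = grid)
    }
    op <- proj_grid_operator(proj)
    for (i in seq_along(es$epochs)) {
      X <- es$epochs[[i]]
      if (es$fs != target_fs) {
        pq <- rate_ratio(target_fs, es$fs)
        X <- apply(X, 2, resample_poly, p = pq[1], q = pq[2])
      }
      segs <- window_segments(X, target_fs, window_s, step_s)
      for (w in seq_along(segs)) {
        frames <- segs[[w]] %*% t(op) # T x (grid*grid)
        tensors[[length(tensors) + 1L]] <-
          aperm(array(t(frames), c(grid, grid, nrow(frames))), c(1, 2, 3))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          label = es$info$group[i], subject = es$info$subject[i],
          trial = es$info$trial[i], window = w)
      }
    }
  }
  if (!length(tensors)) {
    return(eeg_tensor_dataset(array(0, c(0, grid, grid, round(window_s * target_fs))),
                              tibble::tibble(label = character(), subject = character(),
                                             trial = integer(), window = integer()),
                              fs = target_fs, proj = proj))
  }
  N <- length(tensors)
  tl <- dim(tensors[[1]])[3]
  arr <- array(0, c(N, grid, grid, tl))
  for (i in seq_len(N)) arr[i, , , ] <- tensors[[i]]
  eeg_tensor_dataset(arr, do.call(rbind, rows), fs = target_fs, proj = proj)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
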