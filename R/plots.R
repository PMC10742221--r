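# ggplot2 visualisations: interpolated scalp topographies, learning curves,
# saliency maps.

topo_df <- function(values, montage, grid = 32) {
  proj <- project_montage(montage, grid = grid)
  frame <- interpolate_frame(values, proj)
  df <- expand.grid(row = seq_len(grid), col = seq_len(grid))
  df$value <- as.vector(frame)
  df$value[!as.vector(proj$mask)] <- NA
  df
}

#' Plot one scalp topography
#'
#' Biharmonic-interpolated map of a channel vector on the projected scalp
#' grid (nasion at the top).
#'
#' @param values channel vector (montage order).
#' @param montage an [eeg_montage()].
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_topography <- function(values, montage, title = NULL) {
  df <- topo_df(values, montage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#a50026", na.value = "grey95") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = "µV") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.microstate_model <- function(object, montage, ...) {
  dfs <- lapply(seq_len(object$K), function(k) {
    df <- topo_df(object$prototypes[k, ], montage)
    df$state <- sprintf("state %d (GEV %.2f)", k, object$gev_per_state[k])
    df
  })
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#a50026", na.value = "grey95") +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~state) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.csp_model <- function(object, montage, branch = c("expert", "novice"), ...) {
  branch <- match.arg(branch)
  pat <- if (branch == "expert") object$patterns1[1, ] else object$patterns2[1, ]
  plot_topography(pat, montage,
                  title = sprintf("leading %s spatial pattern", branch))
}

#' @export
autoplot.cnn_model <- function(object, ...) {
  if (is.null(object$curves)) stop("model has no learning curves", call. = FALSE)
  df <- object$curves
  long <- rbind(
    data.frame(epoch = df$epoch, value = df$loss, what = "loss"),
    data.frame(epoch = df$epoch, value = df$train_acc, what = "train accuracy"),
    if (!all(is.na(df$val_acc)))
      data.frame(epoch = df$epoch, value = df$val_acc, what = "validation accuracy"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.saliency_map <- function(object, ...) {
  g <- nrow(object$grid)
  df <- expand.grid(row = seq_len(g), col = seq_len(g))
  df$value <- as.vector(object$grid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Grad-CAM (%s, %s)", object$layer,
                                  object$target_class),
                  x = NULL, y = NULL, fill = "saliency") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
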