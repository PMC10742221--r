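# broom-style tidiers for the package's fitted objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a microstate model
#'
#' One row per microstate prototype with its explained-variance share.
#'
#' @param x a [microstate_kmeans()] model.
#' @param ... unused.
#' @return tibble with `state`, `gev`.
#' @export
tidy.microstate_model <- function(x, ...) {
  tibble::tibble(state = seq_len(x$K), gev = x$gev_per_state)
}

#' @rdname tidy.microstate_model
#' @return for `glance`: one-row tibble with `K`, `gev_total`, `cv`.
#' @export
glance.microstate_model <- function(x, ...) {
  tibble::tibble(K = x$K, gev_total = x$gev_total, cv = x$cv)
}

#' Tidy a CSP model
#'
#' One row per spatial filter with its branch and generalized eigenvalue
#' (the class variance ratio along the filter).
#'
#' @param x a [fit_regularized_csp()] model.
#' @param ... unused.
#' @return tibble with `branch`, `filter`, `eigenvalue`.
#' @export
tidy.csp_model <- function(x, ...) {
  tibble::tibble(
    branch = rep(c("expert", "novice"), each = length(x$eigvals1)),
    filter = rep(seq_along(x$eigvals1), 2),
    eigenvalue = c(x$eigvals1, x$eigvals2))
}

#' @rdname tidy.csp_model
#' @return for `glance`: one-row tibble with `n_channels`, `alpha`, and the
#'   leading eigenvalue of each branch.
#' @export
glance.csp_model <- function(x, ...) {
  tibble::tibble(n_channels = nrow(x$C1), alpha = x$alpha,
                 top_eigenvalue_expert = x$eigvals1[1],
                 top_eigenvalue_novice = x$eigvals2[1])
}

#' Tidy a classifier report
#'
#' @param x a `classifier_report` from [classification_metrics()].
#' @param ... unused.
#' @return tibble with `metric`, `value`.
#' @export
tidy.classifier_report <- function(x, ...) {
  metrics <- c("accuracy", "precision", "sensitivity", "specificity",
               "f1", "mcc", "kappa")
  tibble::tibble(metric = metrics, value = unlist(x[metrics], use.names = FALSE))
}

#' @rdname tidy.classifier_report
#' @return for `glance`: one-row tibble with every metric plus `n_samples`.
#' @export
glance.classifier_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, precision = x$precision,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 f1 = x$f1, mcc = x$mcc, kappa = x$kappa,
                 n_samples = x$n_samples, degenerate = x$degenerate)
}

#' Glance at a trained CNN
#'
#' @param x a [cnn_train()] model.
#' @param ... unused.
#' @return one-row tibble with parameter count, epochs, and final losses.
#' @export
glance.cnn_model <- function(x, ...) {
  tibble::tibble(
    n_params = cnn_n_params(x),
    epochs = if (is.null(x$curves)) 0L else max(x$curves$epoch),
    final_loss = if (is.null(x$curves)) NA_real_ else utils::tail(x$curves$loss, 1),
    final_train_acc = if (is.null(x$curves)) NA_real_ else utils::tail(x$curves$train_acc, 1))
}
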