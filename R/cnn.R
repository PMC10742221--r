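# A compact 3-D CNN with temporal attentive pooling (TAP) for topographic
# EEG tensors, implemented directly in R: convolutions run as precomputed
# im2col index gathers plus BLAS matrix products, and the convolution
# backward pass scatters through a precomputed sparse matrix. This keeps the
# whole network differentiable end to end (needed for Grad-CAM) without any
# external deep-learning runtime.
#
# Architecture: three valid (unpadded) conv blocks (conv -> batch norm ->
# ReLU) with kernels/strides (2,2,10)/(2,2,4), (2,2,2)/(2,2,2),
# (2,2,3)/(2,2,2) and channel widths c1, 2*c1, 4*c1; TAP collapses the
# temporal axis by learned softmax attention; then FC -> BN -> ReLU ->
# dropout -> FC -> softmax. On a 16x16x360 input the feature shapes are
# 8x8x88, 4x4x44, 2x2x21 (derived, asserted at build time, and recorded in
# the model).

#' CNN configuration
#'
#' @param input_dim input tensor shape (height, width, time).
#' @param c1 channel width of the first conv layer; widths double per layer.
#' @param kernels,strides per-layer 3-vectors (height, width, time).
#' @param hidden width of the fully connected layer after TAP.
#' @param dropout dropout rate after the hidden layer.
#' @param l2 L2 regularization factor on fully connected kernels and biases.
#' @param batch_size,epochs,lr training protocol parameters.
#' @param seed integer seed controlling initialization, shuffling, dropout.
#' @return a list of class `cnn_config`.
#' @export
cnn_config <- function(input_dim = c(16, 16, 360), c1 = 16,
                       kernels = list(c(2, 2, 10), c(2, 2, 2), c(2, 2, 3)),
                       strides = list(c(2, 2, 4), c(2, 2, 2), c(2, 2, 2)),
                       hidden = 64, dropout = 0.5, l2 = 0.01,
                       batch_size = 32, epochs = 200, lr = 0.001, seed = 1) {
  stopifnot(length(kernels) == 3, length(strides) == 3,
            all(vapply(strides, function(s) all(s >= 1), TRUE)))
  structure(as.list(environment()), class = "cnn_config")
}

conv_out_dim <- function(in_dim, kernel, stride) {
  d <- floor((in_dim - kernel) / stride) + 1
  if (any(d < 1)) stop("kernel/stride do not fit the input", call. = FALSE)
  d
}

#' Derive the layer-by-layer feature shapes of the network
#'
#' @param config a [cnn_config()].
#' @return list of per-layer shapes: each element has `in_dim` (h, w, t, ch)
#'   and `out_dim`.
#' @export
cnn_shapes <- function(config) {
  dims <- c(config$input_dim, 1)
  widths <- config$c1 * c(1, 2, 4)
  out <- list()
  for (l in 1:3) {
    sp <- conv_out_dim(dims[1:3], config$kernels[[l]], config$strides[[l]])
    out[[l]] <- list(in_dim = dims, out_dim = c(sp, widths[l]))
    dims <- c(sp, widths[l])
  }
  out
}

# im2col gather indices for a (h,w,t,ch) column-major input volume
conv_indices <- function(in_dim, kernel, stride) {
  h <- in_dim[1]; w <- in_dim[2]; tt <- in_dim[3]; ch <- in_dim[4]
  od <- conv_out_dim(in_dim[1:3], kernel, stride)
  pos <- expand.grid(i = 0:(od[1] - 1), j = 0:(od[2] - 1), k = 0:(od[3] - 1))
  pat <- expand.grid(a = 0:(kernel[1] - 1), b = 0:(kernel[2] - 1),
                     c = 0:(kernel[3] - 1), ci = 0:(ch - 1))
  n_pos <- nrow(pos); L <- nrow(pat)
  base_h <- outer(pos$i * stride[1], pat$a, "+")
  base_w <- outer(pos$j * stride[2], pat$b, "+")
  base_t <- outer(pos$k * stride[3], pat$c, "+")
  base_c <- matrix(pat$ci, n_pos, L, byrow = TRUE)
  idx <- base_h + h * (base_w + w * (base_t + tt * base_c)) + 1L
  storage.mode(idx) <- "integer"
  idx
}

im2col <- function(Xb, idx) {
  B <- ncol(Xb)
  A <- Xb[as.vector(idx), , drop = FALSE]
  dim(A) <- c(nrow(idx), ncol(idx), B)
  A <- aperm(A, c(1, 3, 2))
  dim(A) <- c(nrow(idx) * B, ncol(idx))
  A
}

# (n_pos*B x ch) -> (n_pos*ch x B) feature layout and back
posb_to_feat <- function(Z, n_pos, B) {
  dim(Z) <- c(n_pos, B, ncol(Z))
  Z <- aperm(Z, c(1, 3, 2))
  dim(Z) <- c(n_pos * dim(Z)[2], B)
  Z
}
feat_to_posb <- function(Y, n_pos, B) {
  ch <- nrow(Y) / n_pos
  dim(Y) <- c(n_pos, ch, B)
  Y <- aperm(Y, c(1, 3, 2))
  dim(Y) <- c(n_pos * B, ch)
  Y
}

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize the CNN
#'
#' Uniform Glorot initialization for conv and FC kernels, zeros for biases,
#' ones for the TAP elementwise weight and the batch-norm scales.
#' Deterministic under `config$seed`.
#'
#' @param config a [cnn_config()].
#' @return an untrained model of class `cnn_model`.
#' @export
cnn_init <- function(config) {
  shapes <- cnn_shapes(config)
  with_seed(config$seed, {
    p <- list(); state <- list(); meta <- list()
    for (l in 1:3) {
      s <- shapes[[l]]
      idx <- conv_indices(s$in_dim, config$kernels[[l]], config$strides[[l]])
      n_pos <- nrow(idx); L <- ncol(idx)
      S <- Matrix::sparseMatrix(i = as.vector(idx),
                                j = seq_len(n_pos * L), x = 1,
                                dims = c(prod(s$in_dim), n_pos * L))
      out_ch <- s$out_dim[4]
      recept <- prod(config$kernels[[l]])
      p[[paste0("conv", l, "_W")]] <- glorot(L, out_ch, L, recept * out_ch)
      p[[paste0("conv", l, "_b")]] <- numeric(out_ch)
      p[[paste0("conv", l, "_gamma")]] <- rep(1, out_ch)
      p[[paste0("conv", l, "_beta")]] <- numeric(out_ch)
      state[[paste0("conv", l, "_mean")]] <- numeric(out_ch)
      state[[paste0("conv", l, "_var")]] <- rep(1, out_ch)
      meta[[l]] <- list(idx = idx, S = S, n_pos = n_pos, L = L,
                        in_dim = s$in_dim, out_dim = s$out_dim)
    }
    od <- shapes[[3]]$out_dim
    sp <- od[1] * od[2]; tl <- od[3]; ch <- od[4]
    p$tap_phi <- array(1, c(sp, tl, ch))
    p$tap_wc <- glorot(ch, 1, ch, 1)[, 1]
    p$tap_bc <- 0
    p$tap_Wt <- glorot(tl, tl, tl, tl)
    p$tap_bt <- numeric(tl)
    n_flat <- sp * ch
    p$fc1_W <- glorot(n_flat, config$hidden, n_flat, config$hidden)
    p$fc1_b <- numeric(config$hidden)
    p$fc1_gamma <- rep(1, config$hidden)
    p$fc1_beta <- numeric(config$hidden)
    state$fc1_mean <- numeric(config$hidden)
    state$fc1_var <- rep(1, config$hidden)
    p$fc2_W <- glorot(config$hidden, 2, config$hidden, 2)
    p$fc2_b <- numeric(2)
    structure(list(params = p, state = state, meta = meta, config = config,
                   shapes = shapes, tap_dim = c(sp, tl, ch),
                   classes = c("expert", "novice"), mu = 0, sdv = 1,
                   curves = NULL),
              class = "cnn_model")
  })
}

#' Number of trainable parameters
#' @param model a [cnn_init()] or [cnn_train()] model.
#' @return integer parameter count.
#' @export
cnn_n_params <- function(model) {
  sum(vapply(model$params, length, 0L))
}

bn_eps <- 1e-5

bn_forward <- function(Z, gamma, beta, mean_run, var_run, train, momentum = 0.9) {
  if (train) {
    mu <- colMeans(Z)
    v <- colMeans(Z^2) - mu^2
    new_mean <- momentum * mean_run + (1 - momentum) * mu
    new_var <- momentum * var_run + (1 - momentum) * v
  } else {
    mu <- mean_run; v <- var_run
    new_mean <- mean_run; new_var <- var_run
  }
  invstd <- 1 / sqrt(v + bn_eps)
  xhat <- sweep(sweep(Z, 2, mu), 2, invstd, `*`)
  out <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(out = out, xhat = xhat, invstd = invstd, gamma = gamma, train = train,
       mean_run = new_mean, var_run = new_var)
}

bn_backward <- function(dout, cache) {
  N <- nrow(dout)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, cache$gamma, `*`)
  if (!cache$train) {
    # eval mode: running stats are constants, BN is a fixed affine map
    dx <- sweep(dxhat, 2, cache$invstd, `*`)
  } else {
    t1 <- sweep(dxhat, 2, colSums(dxhat) / N)
    t2 <- sweep(cache$xhat, 2, colSums(dxhat * cache$xhat) / N, `*`)
    dx <- sweep(t1 - t2, 2, cache$invstd, `*`)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Full forward pass. Returns probabilities plus (optionally) every
# intermediate needed for the backward pass / Grad-CAM.
cnn_forward <- function(model, Xb, train = FALSE, keep = FALSE,
                        dropout_mask = NULL) {
  p <- model$params; st <- model$state
  B <- ncol(Xb)
  cache <- list(B = B)
  act <- Xb
  for (l in 1:3) {
    m <- model$meta[[l]]
    P <- im2col(act, m$idx)
    Z <- P %*% p[[paste0("conv", l, "_W")]]
    Z <- sweep(Z, 2, p[[paste0("conv", l, "_b")]], `+`)
    bn <- bn_forward(Z, p[[paste0("conv", l, "_gamma")]],
                     p[[paste0("conv", l, "_beta")]],
                     st[[paste0("conv", l, "_mean")]],
                     st[[paste0("conv", l, "_var")]], train)
    A <- pmax(bn$out, 0)
    feat <- posb_to_feat(A, m$n_pos, B)
    if (keep) {
      cache[[paste0("conv", l)]] <-
        list(P = P, bn = bn, relu_mask = bn$out > 0, feat = feat)
    }
    if (train) {
      st[[paste0("conv", l, "_mean")]] <- bn$mean_run
      st[[paste0("conv", l, "_var")]] <- bn$var_run
    }
    act <- feat
  }

  # TAP: spatial attentive pooling -> temporal softmax attention -> collapse
  sp <- model$tap_dim[1]; tl <- model$tap_dim[2]; ch <- model$tap_dim[3]
  Farr <- array(act, c(sp, tl, ch, B))
  Fphi <- Farr * as.vector(p$tap_phi)
  SAP <- colSums(Fphi) # (tl, ch, B)
  SAPm <- matrix(aperm(SAP, c(1, 3, 2)), tl * B, ch)
  G <- matrix(SAPm %*% p$tap_wc + p$tap_bc, tl, B)
  Aat <- p$tap_Wt %*% G + p$tap_bt
  alpha <- apply(Aat, 2, function(a) { a <- a - max(a); e <- exp(a); e / sum(e) })
  alpha <- matrix(alpha, tl, B)
  pooled <- matrix(0, sp * ch, B)
  for (b in seq_len(B)) {
    Fb <- matrix(aperm(array(Farr[, , , b], c(sp, tl, ch)), c(1, 3, 2)),
                 sp * ch, tl)
    pooled[, b] <- Fb %*% alpha[, b]
  }
  if (keep) cache$tap <- list(Farr = Farr, SAP = SAP, G = G, alpha = alpha,
                              pooled = pooled)

  Xfc <- t(pooled) # B x (sp*ch)
  Z1 <- sweep(Xfc %*% p$fc1_W, 2, p$fc1_b, `+`)
  bn1 <- bn_forward(Z1, p$fc1_gamma, p$fc1_beta, st$fc1_mean, st$fc1_var, train)
  H <- pmax(bn1$out, 0)
  if (train) {
    st$fc1_mean <- bn1$mean_run; st$fc1_var <- bn1$var_run
    if (is.null(dropout_mask)) {
      dropout_mask <- matrix(stats::rbinom(length(H), 1, 1 - model$config$dropout),
                             nrow(H), ncol(H)) / (1 - model$config$dropout)
    }
    Hd <- H * dropout_mask
  } else {
    dropout_mask <- NULL
    Hd <- H
  }
  logits <- sweep(Hd %*% p$fc2_W, 2, p$fc2_b, `+`)
  probs <- softmax_rows(logits)
  if (keep) {
    cache$fc <- list(Xfc = Xfc, bn1 = bn1, relu1 = bn1$out > 0, H = H,
                     Hd = Hd, dropout_mask = dropout_mask, logits = logits)
  }
  list(probs = probs, logits = logits, cache = cache, state = st)
}

# Backward pass from d(logits). Returns parameter gradients and, when
# `collect_input_grads`, the gradient at each conv block's output feature map
# and at the TAP output (for Grad-CAM).
cnn_backward <- function(model, dlogits, cache, collect_input_grads = FALSE) {
  p <- model$params
  B <- cache$B
  g <- list()
  input_grads <- list()

  fc <- cache$fc
  g$fc2_W <- crossprod(fc$Hd, dlogits)
  g$fc2_b <- colSums(dlogits)
  dHd <- dlogits %*% t(p$fc2_W)
  dH <- if (!is.null(fc$dropout_mask)) dHd * fc$dropout_mask else dHd
  dZbn <- dH * fc$relu1
  bnb <- bn_backward(dZbn, fc$bn1)
  g$fc1_gamma <- bnb$dgamma; g$fc1_beta <- bnb$dbeta
  g$fc1_W <- crossprod(fc$Xfc, bnb$dx)
  g$fc1_b <- colSums(bnb$dx)
  dXfc <- bnb$dx %*% t(p$fc1_W)
  dpooled <- t(dXfc) # (sp*ch) x B

  tap <- cache$tap
  sp <- model$tap_dim[1]; tl <- model$tap_dim[2]; ch <- model$tap_dim[3]
  if (collect_input_grads) input_grads$tap <- dpooled
  dFarr <- array(0, c(sp, tl, ch, B))
  g$tap_phi <- array(0, dim(p$tap_phi))
  g$tap_Wt <- matrix(0, tl, tl); g$tap_bt <- numeric(tl)
  g$tap_wc <- numeric(ch); g$tap_bc <- 0
  dG <- matrix(0, tl, B)
  for (b in seq_len(B)) {
    Fb <- array(tap$Farr[, , , b], c(sp, tl, ch))
    dP <- matrix(dpooled[, b], sp, ch)
    # dalpha and the direct F-gradient from the pooling sum
    dalpha <- vapply(seq_len(tl), function(tt)
      sum(array(Fb[, tt, ], c(sp, ch)) * dP), 0)
    dFb <- aperm(outer(dP, tap$alpha[, b]), c(1, 3, 2)) # sp x tl x ch
    a <- tap$alpha[, b]
    da <- a * (dalpha - sum(a * dalpha))
    g$tap_Wt <- g$tap_Wt + da %*% t(tap$G[, b, drop = FALSE])
    g$tap_bt <- g$tap_bt + da
    dG[, b] <- t(p$tap_Wt) %*% da
    SAPb <- array(tap$SAP[, , b], c(tl, ch))
    g$tap_wc <- g$tap_wc + drop(t(SAPb) %*% dG[, b])
    g$tap_bc <- g$tap_bc + sum(dG[, b])
    dSAP <- dG[, b] %o% p$tap_wc # tl x ch
    # broadcast back over the spatial axis
    dFphi <- aperm(array(dSAP, c(tl, ch, sp)), c(3, 1, 2))
    g$tap_phi <- g$tap_phi + dFphi * Fb
    dFarr[, , , b] <- dFb + dFphi * as.vector(p$tap_phi)
  }
  dact <- matrix(dFarr, sp * tl * ch, B)

  for (l in 3:1) {
    m <- model$meta[[l]]
    cv <- cache[[paste0("conv", l)]]
    if (collect_input_grads) input_grads[[paste0("conv", l)]] <- dact
    dA <- feat_to_posb(dact, m$n_pos, B)
    dZbn <- dA * cv$relu_mask
    bnb <- bn_backward(dZbn, cv$bn)
    g[[paste0("conv", l, "_gamma")]] <- bnb$dgamma
    g[[paste0("conv", l, "_beta")]] <- bnb$dbeta
    g[[paste0("conv", l, "_W")]] <- crossprod(cv$P, bnb$dx)
    g[[paste0("conv", l, "_b")]] <- colSums(bnb$dx)
    dP <- bnb$dx %*% t(p[[paste0("conv", l, "_W")]])
    dim(dP) <- c(m$n_pos, B, m$L)
    dP <- aperm(dP, c(1, 3, 2))
    dim(dP) <- c(m$n_pos * m$L, B)
    dact <- as.matrix(m$S %*% dP)
  }
  if (collect_input_grads) input_grads$input <- dact
  list(grads = g, input_grads = input_grads)
}

l2_params <- c("fc1_W", "fc1_b", "fc2_W", "fc2_b", "tap_Wt", "tap_bt",
               "tap_wc", "tap_bc")

batch_matrix <- function(tensors, idx, mu = 0, sdv = 1) {
  sub <- tensors[idx, , , , drop = FALSE]
  d <- dim(sub)
  m <- matrix(aperm(sub, c(2, 3, 4, 1)), d[2] * d[3] * d[4], d[1])
  (m - mu) / sdv
}

onehot <- function(labels, classes) {
  Y <- matrix(0, length(labels), length(classes))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  Y
}

#' Train the CNN on a tensor dataset
#'
#' Minimizes cross-entropy plus L2 (factor `config$l2`) on the fully
#' connected kernels and biases with Adam at `config$lr`, shuffled
#' mini-batches of `config$batch_size`, for `config$epochs` epochs. Inputs
#' are standardized by the training set's global mean and SD (stored in the
#' model). Weights are freshly initialized from `config$seed`, so a fixed
#' seed reproduces the run exactly (single-threaded BLAS).
#'
#' @param dataset an [eeg_tensor_dataset()].
#' @param config a [cnn_config()].
#' @param train_idx indices used for training (default: all tensors).
#' @param val_idx optional validation indices for per-epoch accuracy.
#' @param verbose print per-epoch progress.
#' @return a `cnn_model` with learning `curves` (tibble: epoch, loss,
#'   train_acc, val_acc).
#' @export
cnn_train <- function(dataset, config = cnn_config(), train_idx = NULL,
                      val_idx = NULL, verbose = FALSE) {
  if (is.null(train_idx)) train_idx <- seq_len(nrow(dataset$info))
  labels <- dataset$info$label[train_idx]
  if (length(unique(labels)) < 2) stop("training data must contain both classes", call. = FALSE)
  model <- cnn_init(config)
  model$mu <- mean(dataset$tensors[train_idx, , , ])
  model$sdv <- stats::sd(dataset$tensors[train_idx, , , ])
  if (model$sdv == 0) model$sdv <- 1
  Y_all <- onehot(labels, model$classes)

  adam_m <- lapply(model$params, function(x) x * 0)
  adam_v <- adam_m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  curves <- list()

  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(seq_along(train_idx))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0; ep_correct <- 0
      for (bt in batches) {
        Xb <- batch_matrix(dataset$tensors, train_idx[bt], model$mu, model$sdv)
        Y <- Y_all[bt, , drop = FALSE]
        fw <- cnn_forward(model, Xb, train = TRUE, keep = TRUE)
        model$state <- fw$state
        B <- length(bt)
        ce <- -sum(log(pmax(rowSums(fw$probs * Y), 1e-12))) / B
        dlogits <- (fw$probs - Y) / B
        bw <- cnn_backward(model, dlogits, fw$cache)
        g <- bw$grads
        l2 <- config$l2
        reg <- 0
        for (nm in l2_params) {
          reg <- reg + l2 * sum(model$params[[nm]]^2)
          g[[nm]] <- g[[nm]] + 2 * l2 * model$params[[nm]]
        }
        step <- step + 1L
        for (nm in names(model$params)) {
          gi <- g[[nm]]
          adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * gi
          adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * gi^2
          mhat <- adam_m[[nm]] / (1 - beta1^step)
          vhat <- adam_v[[nm]] / (1 - beta2^step)
          model$params[[nm]] <- model$params[[nm]] -
            config$lr * mhat / (sqrt(vhat) + eps)
        }
        ep_loss <- ep_loss + (ce + reg) * B
        pred <- model$classes[max.col(fw$probs)]
        ep_correct <- ep_correct + sum(pred == labels[bt])
      }
      val_acc <- NA_real_
      if (!is.null(val_idx) && length(val_idx)) {
        val_acc <- mean(cnn_predict(model, dataset, val_idx) ==
                          dataset$info$label[val_idx])
      }
      curves[[epoch]] <- tibble::tibble(
        epoch = epoch, loss = ep_loss / length(train_idx),
        train_acc = ep_correct / length(train_idx), val_acc = val_acc)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  train acc %.3f  val acc %s",
                        epoch, ep_loss / length(train_idx),
                        ep_correct / length(train_idx),
                        ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
      }
    }
  })
  model$curves <- do.call(rbind, curves)
  model
}

#' Predict class labels (or probabilities) for tensors
#'
#' @param model a trained [cnn_train()] model.
#' @param dataset an [eeg_tensor_dataset()].
#' @param idx tensor indices (default all).
#' @param type `"class"` or `"prob"`.
#' @param batch_size evaluation batch size.
#' @return character labels, or an `n x 2` probability matrix.
#' @export
cnn_predict <- function(model, dataset, idx = NULL, type = c("class", "prob"),
                        batch_size = 64) {
  type <- match.arg(type)
  if (is.null(idx)) idx <- seq_len(nrow(dataset$info))
  out <- matrix(0, length(idx), 2)
  for (chunk in split(seq_along(idx), ceiling(seq_along(idx) / batch_size))) {
    Xb <- batch_matrix(dataset$tensors, idx[chunk], model$mu, model$sdv)
    out[chunk, ] <- cnn_forward(model, Xb, train = FALSE)$probs
  }
  if (type == "prob") {
    colnames(out) <- model$classes
    return(out)
  }
  model$classes[max.col(out)]
}

#' Repeated cross-validation with a fixed holdout set
#'
#' Splits the windows 9:1 into train-validation and holdout (stratified by
#' label). For each of `n_repeats` repetitions a fresh `folds`-fold partition
#' of the 90% is drawn and, per fold, a freshly initialized model is trained
#' on the fold's training part; every fold's model is scored on the fixed
#' holdout, giving per-repeat mean, SD, and max of each metric.
#'
#' @param dataset an [eeg_tensor_dataset()].
#' @param config a [cnn_config()].
#' @param n_repeats repetitions (default 10).
#' @param folds folds per repetition (default 5).
#' @param holdout holdout fraction (must be > 0).
#' @param seed integer seed for the split plan and per-repeat streams.
#' @return list with `reports` (list over repeats of per-fold
#'   `classifier_report`s), `summary` (tibble: repeat, metric, mean, sd,
#'   max), and `holdout` (the holdout indices).
#' @export
cnn_evaluate_protocol <- function(dataset, config = cnn_config(),
                                  n_repeats = 10, folds = 5, holdout = 0.1,
                                  seed = 1) {
  if (holdout <= 0) stop("holdout fraction must be positive", call. = FALSE)
  n <- nrow(dataset$info)
  plan <- make_splits(n, holdout = holdout, folds = folds, seed = seed,
                      labels = dataset$info$label)
  trainval <- sort(unlist(plan$folds))
  reports <- list(); summaries <- list()
  for (r in seq_len(n_repeats)) {
    fold_id <- stratified_folds(dataset$info$label[trainval], folds,
                                seed = seed + 1000L * r)
    folds_idx <- lapply(seq_len(folds), function(f) trainval[fold_id == f])
    rep_reports <- list()
    for (f in seq_len(folds)) {
      tr <- setdiff(trainval, folds_idx[[f]])
      cfg <- config
      cfg$seed <- seed + 1000L * r + f
      model <- cnn_train(dataset, cfg, train_idx = tr)
      pred <- cnn_predict(model, dataset, plan$holdout)
      conf <- confusion(dataset$info$label[plan$holdout], pred)
      rep_reports[[f]] <- classification_metrics(conf)
    }
    reports[[r]] <- rep_reports
    sm <- summarize_repeats(rep_reports)
    sm$rep <- r
    summaries[[r]] <- sm
  }
  list(reports = reports, summary = do.call(rbind, summaries),
       holdout = plan$holdout)
}

#' Grad-CAM saliency for one tensor
#'
#' Gradient-weighted class activation mapping: the gradient of the target
#' class's logit is taken with respect to the chosen layer's feature map,
#' averaged over positions to give per-channel weights, and the weighted,
#' ReLU-rectified channel sum is the saliency map, bilinearly upsampled to
#' the input grid.
#'
#' @param model a trained [cnn_train()] model.
#' @param tensor one `grid x grid x T` array (or a dataset plus `idx`).
#' @param target_class `"expert"` or `"novice"`.
#' @param layer `"conv1"`, `"conv2"`, `"conv3"`, or `"tap"`.
#' @param idx tensor index when `tensor` is an [eeg_tensor_dataset()].
#' @return an object of class `saliency_map`: `heat` (the layer-resolution
#'   map, time axis retained for conv layers), `grid` (16 x 16 nonnegative
#'   map, time-averaged), `layer`, `target_class`.
#' @export
gradcam <- function(model, tensor, target_class = "expert",
                    layer = c("tap", "conv1", "conv2", "conv3"), idx = NULL) {
  layer <- match.arg(layer)
  if (inherits(tensor, "eeg_tensor_dataset")) {
    stopifnot(!is.null(idx))
    Xb <- batch_matrix(tensor$tensors, idx, model$mu, model$sdv)
  } else {
    Xb <- matrix(as.vector(tensor), ncol = 1)
    Xb <- (Xb - model$mu) / model$sdv
  }
  cls <- match(target_class, model$classes)
  fw <- cnn_forward(model, Xb, train = FALSE, keep = TRUE)
  dlogits <- matrix(0, ncol(Xb), 2)
  dlogits[, cls] <- 1
  bw <- cnn_backward(model, dlogits, fw$cache, collect_input_grads = TRUE)

  grid <- model$config$input_dim[1]
  if (layer == "tap") {
    sp <- model$tap_dim[1]; ch <- model$tap_dim[3]
    A <- array(fw$cache$tap$pooled[, 1], c(sp, ch))
    Gr <- array(bw$input_grads$tap[, 1], c(sp, ch))
    w <- colMeans(Gr)
    heat_flat <- pmax(A %*% w, 0)
    side <- sqrt(sp)
    heat <- matrix(heat_flat, side, side)
    up <- upsample_bilinear(heat, grid)
  } else {
    l <- as.integer(sub("conv", "", layer))
    od <- model$meta[[l]]$out_dim
    A <- array(fw$cache[[layer]]$feat[, 1], od)
    Gr <- array(bw$input_grads[[layer]][, 1], od)
    w <- apply(Gr, 4, mean)
    heat <- array(0, od[1:3])
    for (ci in seq_len(od[4])) heat <- heat + w[ci] * A[, , , ci]
    heat <- pmax(heat, 0)
    up <- upsample_bilinear(apply(heat, c(1, 2), mean), grid)
  }
  structure(list(heat = heat, grid = pmax(up, 0), layer = layer,
                 target_class = target_class),
            class = "saliency_map")
}

upsample_bilinear <- function(mat, out) {
  nr <- nrow(mat); nc <- ncol(mat)
  xi <- seq(1, nr, length.out = out)
  yi <- seq(1, nc, length.out = out)
  tmp <- apply(mat, 2, function(col) stats::approx(seq_len(nr), col, xout = xi)$y)
  tmp <- matrix(tmp, out, nc)
  t(apply(tmp, 1, function(row) stats::approx(seq_len(nc), row, xout = yi)$y))
}

#' Mean saliency per grid quadrant
#'
#' Convenience summary used to check that a planted spatial signature is
#' recovered: mean of the 16x16 saliency map over the four quadrants.
#'
#' @param sal a [gradcam()] result (or a 16x16 matrix).
#' @return named numeric vector: upper-left, upper-right, lower-left,
#'   lower-right.
#' @export
saliency_quadrants <- function(sal) {
  m <- if (inherits(sal, "saliency_map")) sal$grid else sal
  g <- nrow(m); h <- g / 2
  c("upper-left" = mean(m[1:h, 1:h]),
    "upper-right" = mean(m[1:h, (h + 1):g]),
    "lower-left" = mean(m[(h + 1):g, 1:h]),
    "lower-right" = mean(m[(h + 1):g, (h + 1):g]))
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> input %s, %d parameters%s\n",
              paste(x$config$input_dim, collapse = "x"), cnn_n_params(x),
              if (is.null(x$curves)) " (untrained)" else
                sprintf(", trained %d epochs (final loss %.4f)",
                        max(x$curves$epoch), utils::tail(x$curves$loss, 1))))
  invisible(x)
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map> layer %s, class %s; quadrant means: %s\n",
              x$layer, x$target_class,
              paste(sprintf("%s %.3g", names(saliency_quadrants(x)),
                            saliency_quadrants(x)), collapse = ", ")))
  invisible(x)
}
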