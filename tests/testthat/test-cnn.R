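test_that("feature shapes are derived correctly and the parameter count matches hand arithmetic", {
  cfg <- cnn_config()
  sh <- cnn_shapes(cfg)
  expect_equal(sh[[1]]$out_dim, c(8, 8, 88, 16))
  expect_equal(sh[[2]]$out_dim, c(4, 4, 44, 32))
  expect_equal(sh[[3]]$out_dim, c(2, 2, 21, 64))

  model <- cnn_init(cfg)
  hand <- (2 * 2 * 10 * 1 * 16 + 16) + (2 * 2 * 2 * 16 * 32 + 32) +
    (2 * 2 * 3 * 32 * 64 + 64) +            # conv kernels + biases
    2 * (16 + 32 + 64) +                    # conv batch-norm scale/shift
    (2 * 2 * 21 * 64) + 64 + 1 + 21 * 21 + 21 + # TAP: phi, wc, bc, Wt, bt
    (256 * 64 + 64) + 2 * 64 +              # FC1 + its batch norm
    (64 * 2 + 2)                            # FC2
  expect_equal(cnn_n_params(model), hand)
  expect_error(cnn_shapes(cnn_config(input_dim = c(2, 2, 5))), "do not fit")
})

test_that("forward pass yields probability rows and is symmetric on zero input", {
  model <- cnn_init(cnn_config(seed = 5))
  set.seed(5)
  Xb <- matrix(rnorm(prod(model$config$input_dim) * 4), ncol = 4)
  probs <- eegskill:::cnn_forward(model, Xb, train = FALSE)$probs
  expect_equal(rowSums(probs), rep(1, 4), tolerance = 1e-6)
  p0 <- eegskill:::cnn_forward(model, 0 * Xb, train = FALSE)$probs
  expect_equal(as.vector(p0), rep(0.5, 8))
})

test_that("the convolution layers match a direct triple-loop convolution", {
  cfg <- cnn_config(input_dim = c(6, 6, 12), c1 = 3,
                    kernels = list(c(2, 2, 3), c(2, 2, 2), c(1, 1, 1)),
                    strides = list(c(2, 2, 2), c(1, 1, 2), c(1, 1, 1)),
                    hidden = 4, seed = 2)
  model <- cnn_init(cfg)
  set.seed(3)
  x <- array(rnorm(6 * 6 * 12), c(6, 6, 12, 1))
  fw <- eegskill:::cnn_forward(model, matrix(as.vector(x), ncol = 1),
                               train = FALSE, keep = TRUE)
  W <- model$params$conv1_W # (2*2*3*1) x 3, patch order h,w,t,ch
  got <- array(fw$cache$conv1$feat[, 1], c(3, 3, 5, 3))
  for (oc in 1:3) {
    for (i in 1:3) for (j in 1:3) for (k in 1:5) {
      patch <- x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j),
                 (2 * k - 1):(2 * k + 1), 1]
      z <- sum(as.vector(patch) * W[, oc]) + model$params$conv1_b[oc]
      # undo this layer's eval-mode batch norm (running stats at init: 0/1)
      zbn <- max(z * model$params$conv1_gamma[oc] /
                   sqrt(1 + eegskill:::bn_eps), 0)
      expect_equal(got[i, j, k, oc], zbn, tolerance = 1e-10)
    }
  }
})

test_that("TAP matches a loop-based oracle and its limiting attention cases", {
  cfg <- cnn_config(input_dim = c(16, 16, 60), c1 = 2, hidden = 4,
                    dropout = 0, seed = 7)
  model <- cnn_init(cfg)
  set.seed(8)
  # randomize phi and attention weights so the oracle is non-trivial
  model$params$tap_phi <- array(rnorm(length(model$params$tap_phi)),
                                dim(model$params$tap_phi))
  model$params$tap_Wt <- matrix(rnorm(length(model$params$tap_Wt)) * 0.5,
                                nrow(model$params$tap_Wt))
  Xb <- matrix(rnorm(prod(cfg$input_dim) * 2), ncol = 2)
  fw <- eegskill:::cnn_forward(model, Xb, train = FALSE, keep = TRUE)
  tap <- fw$cache$tap
  sp <- model$tap_dim[1]; tl <- model$tap_dim[2]; ch <- model$tap_dim[3]

  for (b in 1:2) {
    Fb <- array(tap$Farr[, , , b], c(sp, tl, ch))
    phi <- model$params$tap_phi
    # index-by-index evaluation of SAP, attention, and the pooled output
    SAPo <- matrix(0, tl, ch)
    for (tt in 1:tl) for (cc in 1:ch) {
      SAPo[tt, cc] <- sum(Fb[, tt, cc] * phi[, tt, cc])
    }
    g <- as.vector(SAPo %*% model$params$tap_wc) + model$params$tap_bc
    a <- model$params$tap_Wt %*% g + model$params$tap_bt
    alpha <- exp(a - max(a)); alpha <- alpha / sum(alpha)
    pooled_o <- matrix(0, sp, ch)
    for (tt in 1:tl) pooled_o <- pooled_o + Fb[, tt, ] * alpha[tt]
    expect_equal(as.vector(tap$alpha[, b]), as.vector(alpha), tolerance = 1e-10)
    expect_equal(tap$pooled[, b], as.vector(pooled_o), tolerance = 1e-10)
    expect_equal(sum(tap$alpha[, b]), 1, tolerance = 1e-6)
    expect_true(all(tap$alpha[, b] >= 0))
  }

  # forcing uniform attention -> temporal mean of F
  mu <- model
  mu$params$tap_Wt <- matrix(0, tl, tl)
  mu$params$tap_bt <- numeric(tl)
  fwu <- eegskill:::cnn_forward(mu, Xb, train = FALSE, keep = TRUE)
  Fb <- array(fwu$cache$tap$Farr[, , , 1], c(sp, tl, ch))
  expect_equal(fwu$cache$tap$pooled[, 1],
               as.vector(apply(Fb, c(1, 3), mean)), tolerance = 1e-10)

  # one-hot attention at t* -> the t* slice
  oh <- model
  tstar <- tl
  oh$params$tap_Wt <- matrix(0, tl, tl)
  oh$params$tap_bt <- replace(numeric(tl), tstar, 50)
  fwo <- eegskill:::cnn_forward(oh, Xb, train = FALSE, keep = TRUE)
  Fb <- array(fwo$cache$tap$Farr[, , , 1], c(sp, tl, ch))
  expect_equal(fwo$cache$tap$pooled[, 1], as.vector(Fb[, tstar, ]),
               tolerance = 1e-8)
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- cnn_config(input_dim = c(16, 16, 60), c1 = 2, hidden = 5,
                    dropout = 0, seed = 3)
  model <- cnn_init(cfg)
  set.seed(11)
  B <- 3
  Xb <- matrix(rnorm(prod(cfg$input_dim) * B), ncol = B)
  Y <- rbind(c(1, 0), c(0, 1), c(1, 0))
  loss_fn <- function(m) {
    fw <- eegskill:::cnn_forward(m, Xb, train = TRUE, keep = TRUE)
    -sum(log(pmax(rowSums(fw$probs * Y), 1e-12))) / B
  }
  fw <- eegskill:::cnn_forward(model, Xb, train = TRUE, keep = TRUE)
  bw <- eegskill:::cnn_backward(model, (fw$probs - Y) / B, fw$cache)
  h <- 1e-5
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    pick <- if (length(p) <= 4) seq_along(p) else sort(sample.int(length(p), 4))
    for (i in pick) {
      mp <- model; mp$params[[nm]][i] <- p[i] + h
      mm <- model; mm$params[[nm]][i] <- p[i] - h
      fd <- (loss_fn(mp) - loss_fn(mm)) / (2 * h)
      an <- bw$grads[[nm]][i]
      expect_lt(abs(fd - an) / max(1e-4, abs(fd), abs(an)), 1e-4)
    }
  }
})

test_that("training is deterministic under a fixed seed and rejects single-class data", {
  ds <- simulate_tensor_dataset(n_per_class = 8, seed = 13)
  cfg <- cnn_config(epochs = 1, batch_size = 8, seed = 21)
  m1 <- cnn_train(ds, cfg)
  m2 <- cnn_train(ds, cfg)
  expect_identical(m1$curves$loss[1], m2$curves$loss[1])
  expect_identical(m1$params$fc2_W, m2$params$fc2_W)

  only_experts <- tensor_subset(ds, which(ds$info$label == "expert"))
  expect_error(cnn_train(only_experts, cfg), "both classes")
})

test_that("the repeated-CV protocol sizes its holdout at 10% and runs end to end", {
  # holdout arithmetic at the full cohort scale
  plan <- make_splits(11340, holdout = 0.1, folds = 5, seed = 1)
  expect_length(plan$holdout, 1134)

  ds <- simulate_tensor_dataset(n_per_class = 10, seed = 17)
  cfg <- cnn_config(epochs = 2, batch_size = 8, seed = 5)
  res <- suppressWarnings(cnn_evaluate_protocol(ds, cfg, n_repeats = 1,
                                                folds = 2, holdout = 0.2,
                                                seed = 3))
  expect_length(res$reports, 1)
  expect_length(res$reports[[1]], 2)
  expect_s3_class(res$reports[[1]][[1]], "classifier_report")
  expect_equal(nrow(res$summary), 7)
  expect_length(res$holdout, 4)
  expect_error(cnn_evaluate_protocol(ds, cfg, holdout = 0), "positive")
})

test_that("Grad-CAM maps are nonnegative and finite at every layer", {
  ds <- simulate_tensor_dataset(n_per_class = 6, seed = 19)
  cfg <- cnn_config(epochs = 2, batch_size = 6, seed = 9)
  m <- cnn_train(ds, cfg)
  for (layer in c("tap", "conv1", "conv2", "conv3")) {
    sal <- gradcam(m, ds, target_class = "expert", layer = layer, idx = 1)
    expect_true(all(sal$grid >= 0))
    expect_true(all(is.finite(sal$grid)))
    expect_equal(dim(sal$grid), c(16, 16))
  }
  q <- saliency_quadrants(gradcam(m, ds, "novice", "tap", idx = 8))
  expect_length(q, 4)
})
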