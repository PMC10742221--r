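test_that("class scatter is X'X summed over epochs, permutation-invariant", {
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  expect_equal(class_scatter(list(Q)), diag(4))
  expect_equal(class_scatter(list(matrix(c(1, 2), 2, 1)))[1, 1], 5)
  set.seed(1)
  X <- matrix(rnorm(30 * 4), 30)
  expect_equal(class_scatter(list(X)), class_scatter(list(X[sample(30), ])))
  # trace normalization
  expect_equal(sum(diag(class_scatter(list(X), trace_norm = TRUE))), 1)
})

test_that("microstate conditioning retains exactly the requested samples", {
  eps <- list(matrix(rnorm(40), 10, 4))
  seg_all2 <- list(rep(2L, 10))
  expect_identical(microstate_condition(eps, seg_all2, 2)[[1]], eps[[1]])
  seg_alt <- list(rep(c(2L, 4L), 5))
  kept <- microstate_condition(eps, seg_alt, 4)[[1]]
  expect_equal(nrow(kept), 5)
  expect_equal(kept, eps[[1]][seq(2, 10, 2), ])
  expect_error(microstate_condition(eps, seg_alt, 7), "never occurs")
  # auto picks the epoch's dominant state
  seg_dom <- list(c(rep(3L, 7), rep(1L, 3)))
  expect_equal(nrow(microstate_condition(eps, seg_dom, "auto")[[1]]), 7)
})

test_that("regularized CSP matches closed forms and a dense generalized-eigensolver oracle", {
  m <- fit_regularized_csp(diag(c(4, 1)), diag(2), alpha = 0)
  expect_equal(abs(m$W1[, 1]), c(1, 0))
  expect_equal(m$eigvals1[1], 4)

  m_eq <- fit_regularized_csp(diag(3), diag(3), alpha = 0)
  expect_equal(m_eq$eigvals1, rep(1, 3))

  set.seed(2)
  for (rep_i in 1:5) {
    C1 <- crossprod(matrix(rnorm(100 * 6), 100))
    C2 <- crossprod(matrix(rnorm(100 * 6), 100))
    alpha <- 0.1
    mod <- fit_regularized_csp(C1, C2, alpha = alpha)
    # oracle: symmetric-whitening generalized eigensolve of C1 w = l (C2+aI) w
    R <- chol(C2 + alpha * diag(6))
    Ms <- t(solve(R)) %*% C1 %*% solve(R)
    eo <- eigen((Ms + t(Ms)) / 2, symmetric = TRUE)
    Wo <- solve(R) %*% eo$vectors
    Wo <- Wo %*% diag(1 / sqrt(colSums(Wo^2)))
    expect_lt(max(abs(eo$values - mod$eigvals1)), 1e-8)
    mism <- vapply(1:6, function(j)
      min(max(abs(Wo[, j] - mod$W1[, j])), max(abs(Wo[, j] + mod$W1[, j]))), 0)
    expect_lt(max(mism), 1e-8)
    # eigenvalue = projected variance ratio
    w <- mod$W1[, 1]
    expect_equal(drop(t(w) %*% C1 %*% w / (t(w) %*% (C2 + alpha * diag(6)) %*% w)),
                 mod$eigvals1[1], tolerance = 1e-10)
  }
  expect_error(fit_regularized_csp(matrix(rnorm(9), 3), diag(3)), "symmetric")
})

test_that("CSP features are log-variances with the stated scaling law", {
  set.seed(3)
  C1 <- crossprod(matrix(rnorm(80 * 4), 80)); C2 <- crossprod(matrix(rnorm(80 * 4), 80))
  mod <- fit_regularized_csp(C1, C2, alpha = 0.1)
  ep <- matrix(rnorm(500 * 4), 500)
  f <- csp_features(ep, mod)
  expect_length(f, 2)
  expect_equal(csp_features(3 * ep, mod), f + 2 * log(3))
  # whitened projections give zero features
  W <- cbind(mod$W1[, 1], mod$W2[, 1])
  proj <- ep %*% W
  epw <- ep %*% W %*% diag(1 / sqrt(colMeans(proj^2)))
  modw <- mod; modw$W1 <- diag(2)[, 1, drop = FALSE]; modw$W2 <- diag(2)[, 2, drop = FALSE]
  expect_equal(csp_features(epw, modw), c(0, 0), tolerance = 1e-12)
})

test_that("LDA separates separated clouds, is at chance on identical ones, survives zero variance", {
  set.seed(4)
  X <- rbind(matrix(rnorm(40 * 2), 40), sweep(matrix(rnorm(40 * 2), 40), 2, c(8, 8), `+`))
  y <- rep(c("novice", "expert"), each = 40)
  model <- lda_fit(X, y)
  expect_equal(mean(predict(model, X) == y), 1)
  expect_identical(model$classes, c("expert", "novice"))

  # identical class distributions, n = 200, 10-fold CV ~ chance
  accs <- replicate(5, {
    Xc <- matrix(rnorm(200 * 3), 200)
    yc <- rep(c("expert", "novice"), each = 100)
    folds <- make_splits(200, holdout = 0.5, folds = 2, seed = sample.int(1e6, 1),
                         labels = yc)
    tr <- sort(unlist(folds$folds)); te <- folds$holdout
    mean(predict(lda_fit(Xc[tr, ], yc[tr]), Xc[te, ]) == yc[te])
  })
  expect_lt(abs(mean(accs) - 0.5), 0.1)

  Xz <- cbind(X, 0)
  expect_no_error(lda_fit(Xz, y))
  expect_error(lda_fit(X, rep("expert", 80)), "two classes")

  # independent reference: MASS::lda agrees on the predicted labels
  set.seed(5)
  Xr <- rbind(matrix(rnorm(60 * 3), 60),
              sweep(matrix(rnorm(60 * 3), 60), 2, c(2, 1, -1), `+`))
  yr <- rep(c("novice", "expert"), each = 60)
  ours <- predict(lda_fit(Xr, yr, shrinkage = 0), Xr)
  ref <- as.character(predict(MASS::lda(Xr, grouping = yr))$class)
  expect_gt(mean(ours == ref), 0.98)
})

test_that("cross-validated CSP+LDA refits per fold and reports pooled confusion", {
  flat <- flatten_epochs(fixture_epoch_sets(n_per_group = 3, trials = 2,
                                            snr_db = 10, seed = 301))
  rep1 <- crossvalidate_csp_lda(flat$epochs, flat$labels, folds = 3, seed = 1)
  expect_s3_class(rep1, "classifier_report")
  expect_equal(rep1$n_samples, 12)
  expect_gte(rep1$accuracy, 0.9)
  expect_error(crossvalidate_csp_lda(flat$epochs, flat$labels, folds = 7),
               "at least")
})

test_that("Cohen's kappa matches its defining arithmetic", {
  expect_equal(cohen_kappa(matrix(c(50, 0, 0, 50), 2)), 1)
  expect_equal(cohen_kappa(matrix(c(25, 25, 25, 25), 2)), 0)
  expect_equal(cohen_kappa(matrix(c(30, 10, 10, 30), 2)), 0.5)
})
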