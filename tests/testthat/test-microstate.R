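test_that("GFP is the per-sample population SD across channels", {
  expect_equal(gfp(matrix(c(3, 3, 3), 1)), 0)
  expect_equal(gfp(matrix(c(1, -1), 1)), 1)
  set.seed(1)
  X <- matrix(rnorm(20 * 6), 20)
  expect_equal(gfp(5 * X), 5 * gfp(X)) # homogeneity
})

test_that("GFP peak picking enforces distance and rejects outlier peaks", {
  # peak heights {1,1,1,10}: mean 3.25, population SD 3.897, threshold 7.147
  g <- rep(0.1, 200)
  g[c(20, 60, 100, 140)] <- c(1, 1, 1, 10)
  kept <- pick_gfp_peaks(g, fs = 1000, min_distance_ms = 2)
  expect_identical(kept, c(20L, 60L, 100L))

  # two maxima 4 ms apart at 250 Hz (1 sample) -> larger kept
  g2 <- rep(0, 50)
  g2[c(20, 21)] <- c(0.5, 0.8)
  kept2 <- pick_gfp_peaks(g2, fs = 250, min_distance_ms = 10, reject_sd = 10)
  expect_identical(kept2, 21L)

  expect_error(pick_gfp_peaks(seq_len(100), fs = 250), "no GFP peaks")

  # subsampling to n_peaks is seeded and deterministic
  set.seed(2)
  g3 <- abs(rnorm(5000)) + 1
  k1 <- pick_gfp_peaks(g3, 250, n_peaks = 20, seed = 7)
  expect_length(k1, 20)
  expect_identical(k1, pick_gfp_peaks(g3, 250, n_peaks = 20, seed = 7))
})

test_that("modified K-means recovers prototypes, ignores polarity, reproduces under seed", {
  mon <- fixture_montage()
  bank <- make_prototype_bank(mon, 4, seed = 2)
  set.seed(3)
  a <- rnorm(200)
  a[abs(a) < 0.1] <- 0.5
  X1 <- a %*% t(bank[1, ])
  m1 <- microstate_kmeans(X1, 1, n_init = 5, seed = 1)
  expect_equal(abs(sum(m1$prototypes[1, ] * bank[1, ])), 1, tolerance = 1e-9)
  expect_equal(m1$gev_total, 1, tolerance = 1e-9)

  lab_true <- rep(1:2, each = 100)
  amp <- rnorm(200) * sample(c(-1, 1), 200, TRUE)
  amp[abs(amp) < 0.2] <- 1
  X2 <- amp * bank[1:2, ][lab_true, ] + matrix(rnorm(200 * 32), 200) * 1e-3
  m2 <- microstate_kmeans(X2, 2, n_init = 10, seed = 3)
  expect_equal(m2$gev_total, 1, tolerance = 1e-3)

  # global sign flip leaves prototypes identical up to sign
  m2f <- microstate_kmeans(-X2, 2, n_init = 10, seed = 3)
  expect_equal(abs(rowSums(m2$prototypes * m2f$prototypes)), c(1, 1),
               tolerance = 1e-9)

  expect_identical(microstate_kmeans(X2, 2, n_init = 1, seed = 9)$prototypes,
                   microstate_kmeans(X2, 2, n_init = 1, seed = 9)$prototypes)
  expect_error(microstate_kmeans(X2[1:3, ], 5), "exceeds")
})

test_that("K-means assignments match exhaustive-enumeration clustering on 12 maps", {
  mon <- fixture_montage()
  bank <- make_prototype_bank(mon, 2, seed = 6)
  # orthogonalize the two prototypes exactly
  p1 <- bank[1, ]
  p2 <- bank[2, ] - sum(bank[2, ] * p1) * p1
  p2 <- p2 - mean(p2); p2 <- p2 / sqrt(sum(p2^2))
  set.seed(7)
  lab_true <- rep(1:2, each = 6)
  amp <- c(-1.2, 0.8, 1.5, -0.7, 1.1, 0.9, 1.3, -0.6, 0.8, 1.4, -1.0, 0.7)
  maps <- amp * rbind(p1, p2)[lab_true, ] + matrix(rnorm(12 * 32), 12) * 1e-3

  # oracle: best of all 2^12 polarity-invariant labelings by residual variance
  best_lab <- NULL; best_res <- Inf
  Xc <- maps - rowMeans(maps)
  for (code in 0:(2^12 - 1)) {
    lab <- as.integer(intToBits(code)[1:12]) + 1L
    if (length(unique(lab)) < 2) next
    res <- 0
    for (k in 1:2) {
      S <- crossprod(Xc[lab == k, , drop = FALSE])
      res <- res + sum(diag(S)) - eigen(S, symmetric = TRUE, only.values = TRUE)$values[1]
    }
    if (res < best_res) { best_res <- res; best_lab <- lab }
  }
  m <- microstate_kmeans(maps, 2, n_init = 20, seed = 8)
  r2 <- tcrossprod(Xc / sqrt(rowSums(Xc^2)), m$prototypes)^2
  lab_est <- max.col(r2)
  agree <- max(mean(lab_est == best_lab), mean(lab_est == 3 - best_lab))
  expect_equal(agree, 1)
  # sanity: the oracle finds the planted split (up to class relabelling)
  expect_equal(max(mean(best_lab == lab_true), mean(best_lab == 3 - lab_true)), 1)
})

test_that("GEV matches an independent evaluation of its formula and is invariant", {
  mon <- fixture_montage()
  bank <- make_prototype_bank(mon, 3, seed = 9)
  set.seed(10)
  X <- matrix(rnorm(20 * 32), 20)
  model <- structure(list(prototypes = bank, K = 3), class = "microstate_model")
  labels <- sample(1:3, 20, TRUE)

  # brute-force reimplementation of GEV = sum (gfp_t corr_t)^2 / sum gfp_t^2
  num <- 0; den <- 0
  for (t in 1:20) {
    x <- X[t, ] - mean(X[t, ])
    g <- sqrt(mean(x^2))
    a <- bank[labels[t], ]
    r <- sum(x * (a - mean(a))) /
      sqrt(sum((x)^2) * sum((a - mean(a))^2))
    num <- num + (g * r)^2
    den <- den + g^2
  }
  expect_equal(gev(X, model, labels), num / den, tolerance = 1e-12)

  expect_equal(gev(-X, model, labels), gev(X, model, labels))   # polarity
  expect_equal(gev(4 * X, model, labels), gev(X, model, labels)) # common gain

  # noiseless prototype data and orthogonal assignments
  a1 <- (1:20 / 10) %*% t(bank[1, ])
  expect_equal(gev(a1, model, rep(1L, 20)), 1, tolerance = 1e-12)
  p_orth <- bank[2, ] - sum(bank[2, ] * bank[1, ]) * bank[1, ]
  p_orth <- p_orth - mean(p_orth); p_orth <- p_orth / sqrt(sum(p_orth^2))
  model_o <- structure(list(prototypes = rbind(bank[1, ], p_orth), K = 2),
                       class = "microstate_model")
  expect_equal(gev(a1, model_o, rep(2L, 20)), 0, tolerance = 1e-12)
})

test_that("the CV criterion is minimized at the planted number of microstates", {
  mon <- fixture_montage()
  bank <- make_prototype_bank(mon, 6, seed = 11)
  set.seed(12)
  lab <- sample(1:6, 1500, TRUE)
  amp <- rnorm(1500); amp[abs(amp) < 0.3] <- 0.5
  X <- amp * bank[lab, ] + matrix(rnorm(1500 * 32), 1500) * 0.02
  fit <- select_microstate_model(X, K_range = 2:8, n_init = 5, seed = 13)
  scan <- attr(fit, "scan")
  expect_identical(scan$K[which.min(scan$cv)], 6L)
  expect_identical(fit$K, 6L)
  expect_true(fit$sorted)
  expect_equal(order(fit$gev_per_state, decreasing = TRUE), 1:6)
  # GEV grows (weakly) with K on these data
  expect_true(all(diff(scan$gev_total) > -1e-6))
  # fixed range returns that K
  expect_identical(select_microstate_model(X, K_range = 3, n_init = 2, seed = 1)$K, 3L)
  expect_error(select_microstate_model(X, K_range = integer(0)), "empty")

  # pure-noise data: no deep minimum beyond small K
  Xn <- matrix(rnorm(800 * 32), 800)
  fitn <- select_microstate_model(Xn, K_range = 2:6, n_init = 3, seed = 14)
  scn <- attr(fitn, "scan")
  rel_drop <- -diff(scn$cv) / scn$cv[-length(scn$cv)]
  expect_true(all(rel_drop < 0.08))
})

test_that("the CV small-sample correction diverges as K approaches the channel count", {
  mon <- fixture_montage()
  bank <- make_prototype_bank(mon, 2, seed = 15)
  X <- matrix(rnorm(50 * 32), 50)
  model31 <- structure(list(prototypes = matrix(rnorm(31 * 32), 31), K = 31),
                       class = "microstate_model")
  expect_warning(v <- cv_criterion(X, model31), "diverges")
  expect_identical(v, Inf)
})

test_that("backfitting recovers noiseless labels and smoothing removes intrusions", {
  mon <- fixture_montage()
  bank <- make_prototype_bank(mon, 2, seed = 16)
  model <- structure(list(prototypes = bank, K = 2), class = "microstate_model")
  set.seed(17)

  lab_true <- rep(c(1L, 2L, 1L, 2L), each = 25)
  amp <- runif(100, 0.5, 2) * sample(c(-1, 1), 100, TRUE)
  X <- amp * bank[lab_true, ]
  seg <- backfit(X, model)
  expect_identical(seg$labels, lab_true)
  expect_equal(seg$gev, 1, tolerance = 1e-12)
  # polarity tracks the sample sign up to one global flip per state
  for (k in 1:2) {
    agree <- seg$polarity[lab_true == k] == sign(amp)[lab_true == k]
    expect_true(all(agree) || all(!agree))
  }

  # single-sample intrusion dissolved by 30 ms smoothing at 250 Hz
  lab_i <- c(rep(1L, 50), 2L, rep(1L, 50))
  Xi <- (1 + runif(101)) * bank[lab_i, ]
  s_sm <- backfit(Xi, model, smooth_window_ms = 30, fs = 250)
  expect_identical(s_sm$labels, rep(1L, 101))

  # without smoothing, labels are the raw argmax and backfitting is idempotent
  s0 <- backfit(Xi, model)
  expect_identical(s0$labels, lab_i)
  expect_identical(backfit(Xi, model)$labels, s0$labels)

  expect_error(backfit(X[, 1:10], model), "mismatch")
})
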