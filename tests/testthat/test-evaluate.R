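test_that("confusion matrices count TP/FP/FN/TN with expert as positive", {
  conf <- confusion(c("expert", "expert", "expert", "novice", "novice"),
                    c("expert", "expert", "expert", "novice", "novice"))
  expect_equal(unclass(conf), matrix(c(3L, 0L, 0L, 2L), 2, 2), ignore_attr = TRUE)
  all_pos <- confusion(c("expert", "expert", "expert", "novice", "novice"),
                       rep("expert", 5))
  expect_equal(as.vector(all_pos), c(3L, 0L, 2L, 0L)) # TP FN FP TN column-major
  expect_error(confusion(character(0), character(0)), "non-empty")
  expect_error(confusion(c("a", "b", "c"), c("a", "b", "c")), "two-class")
})

test_that("metrics agree with an independent brute-force oracle on 1000 random matrices", {
  oracle <- function(tp, fp, fn, tn) {
    div <- function(a, b) if (b == 0) 0 else a / b
    prec <- div(tp, tp + fp); rec <- div(tp, tp + fn)
    list(accuracy = div(tp + tn, tp + fp + fn + tn),
         precision = prec, sensitivity = rec,
         specificity = div(tn, fp + tn),
         f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec),
         mcc = {
           d <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
           if (d == 0) 0 else (tp * tn - fp * fn) / d
         })
  }
  set.seed(6)
  for (i in 1:1000) {
    v <- rpois(4, lambda = sample(c(0.5, 3, 20), 1))
    if (sum(v) == 0) v[1] <- 1
    rep_ <- suppressWarnings(classification_metrics(v))
    orc <- oracle(v[1], v[2], v[3], v[4])
    for (m in names(orc)) {
      expect_equal(rep_[[m]], orc[[m]], tolerance = 1e-12)
    }
    expect_equal(rep_$n_samples, sum(v))
  }
})

test_that("worked metric examples and degenerate conventions hold", {
  perfect <- classification_metrics(matrix(c(50, 0, 0, 50), 2))
  for (m in c("accuracy", "precision", "sensitivity", "specificity", "f1",
              "mcc", "kappa")) {
    expect_equal(perfect[[m]], 1)
  }
  r <- classification_metrics(c(30, 10, 10, 30))
  expect_equal(r$precision, 0.75); expect_equal(r$sensitivity, 0.75)
  expect_equal(r$f1, 0.75); expect_equal(r$mcc, 0.5)
  expect_equal(r$accuracy, 0.75); expect_equal(r$specificity, 0.75)
  expect_false(r$degenerate)

  # all predicted novice: sensitivity 0, specificity 1, MCC 0 by convention
  expect_warning(d <- classification_metrics(c(0, 0, 50, 50)), "zero-denominator")
  expect_equal(d$sensitivity, 0)
  expect_equal(d$specificity, 1)
  expect_equal(d$mcc, 0)
  expect_true(d$degenerate)
})

test_that("MCC is invariant under class relabelling; F1 is not", {
  set.seed(7)
  for (i in 1:20) {
    v <- rpois(4, 10) + 1 # TP FP FN TN
    a <- suppressWarnings(classification_metrics(v))
    b <- suppressWarnings(classification_metrics(v[c(4, 3, 2, 1)])) # swap classes
    expect_equal(a$mcc, b$mcc, tolerance = 1e-12)
  }
  asym <- classification_metrics(c(40, 2, 10, 5))
  swapped <- classification_metrics(c(5, 10, 2, 40))
  expect_false(isTRUE(all.equal(asym$f1, swapped$f1)))
})

test_that("repeat summaries report mean, SD, and max per metric", {
  r1 <- classification_metrics(c(45, 5, 5, 45))
  expect_equal(summarize_repeats(list(r1))$sd, rep(0, 7))
  s2 <- summarize_repeats(list(r1, r1))
  expect_equal(s2$mean[s2$metric == "accuracy"], r1$accuracy)
  expect_equal(s2$sd, rep(0, 7))

  r2 <- classification_metrics(c(40, 10, 10, 40))
  r3 <- classification_metrics(c(50, 0, 10, 40))
  s3 <- summarize_repeats(list(r1, r2, r3))
  accs <- c(r1$accuracy, r2$accuracy, r3$accuracy)
  row <- s3[s3$metric == "accuracy", ]
  expect_equal(row$mean, mean(accs))
  expect_equal(row$sd, stats::sd(accs))
  expect_equal(row$max, max(accs))
})

test_that("split plans are disjoint, exhaustive, balanced, and deterministic", {
  plan <- make_splits(100, holdout = 0.1, folds = 5, seed = 3)
  expect_length(plan$holdout, 10)
  expect_equal(lengths(plan$folds), rep(18, 5))
  expect_length(intersect(plan$holdout, unlist(plan$folds)), 0)
  expect_setequal(c(plan$holdout, unlist(plan$folds)), 1:100)
  expect_identical(plan, make_splits(100, holdout = 0.1, folds = 5, seed = 3))

  # stratification balances labels
  labs <- rep(c("expert", "novice"), c(30, 70))
  plan_s <- make_splits(100, 0.1, 5, seed = 4, labels = labs)
  expect_equal(sum(labs[plan_s$holdout] == "expert"), 3)
  expect_error(make_splits(50, holdout = 0), "holdout")
  expect_error(make_splits(50, holdout = 0.1, folds = 1), "folds")
})

test_that("tidiers return well-formed tibbles", {
  r <- classification_metrics(c(30, 10, 10, 30))
  td <- generics::tidy(r)
  expect_equal(nrow(td), 7)
  expect_named(td, c("metric", "value"))
  gl <- generics::glance(r)
  expect_equal(gl$accuracy, 0.75)
  expect_equal(gl$n_samples, 80)
})
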