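test_that("correlation filter drops the hub of a correlated triple", {
  set.seed(2)
  n <- 200
  f1 <- rnorm(n)
  f2 <- f1 + rnorm(n, sd = 0.12)          # r(f1,f2) ~ 0.99
  f3 <- f1 + rnorm(n, sd = 0.22)          # r(f1,f3) ~ 0.97
  X <- cbind(f1 = f1, f2 = f2, f3 = f3)
  stopifnot(abs(cor(f1, f2)) > 0.98, abs(cor(f1, f3)) > 0.96)
  kept <- correlation_filter(X, cutoff = 0.95)
  # f1 correlates highly with both others -> dropped first; f2 and f3
  # correlate less with each other
  if (abs(cor(f2, f3)) <= 0.95) {
    expect_setequal(kept, c("f2", "f3"))
  } else {
    expect_false("f1" %in% kept)
  }
})

test_that("correlation filter keeps orthogonal features, dedupes constants", {
  set.seed(3)
  X <- matrix(rnorm(100 * 4), 100, dimnames = list(NULL, paste0("f", 1:4)))
  expect_setequal(correlation_filter(X), paste0("f", 1:4))
  # identical pair: exactly one kept
  X2 <- cbind(a = X[, 1], b = X[, 1])
  expect_length(correlation_filter(X2), 1)
  # constants excluded from correlation but kept (unless duplicated)
  X3 <- cbind(X[, 1:2], c1 = rep(5, 100), c2 = rep(5, 100))
  kept <- correlation_filter(X3)
  expect_true("f1" %in% kept && "f2" %in% kept)
  expect_length(intersect(kept, c("c1", "c2")), 1)
})

test_that("greedy filter agrees with an independent reference routine", {
  skip_if_not_installed("caret")
  for (s in 1:5) {
    set.seed(s)
    n <- 120
    base <- matrix(rnorm(n * 6), n)
    X <- cbind(base,
               base[, 1:3] + matrix(rnorm(n * 3, sd = 0.1), n))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    kept <- correlation_filter(X, cutoff = 0.9)
    drop_ref <- caret::findCorrelation(cor(X), cutoff = 0.9,
                                       exact = TRUE, names = TRUE)
    expect_setequal(kept, setdiff(colnames(X), drop_ref))
  }
})

test_that("adaptive LASSO keeps an overwhelming effect, rejects pure noise", {
  set.seed(10)
  n <- 400
  y <- rep(c("positive", "unlabeled"), each = n / 2)
  X <- cbind(signal = rnorm(n) + 3 * (y == "positive"),
             matrix(rnorm(n * 12), n,
                    dimnames = list(NULL, paste0("noise", 1:12))))
  res <- adaptive_lasso_selection(X, y, reps = 10, folds = 5, seed = 2)
  expect_equal(res$frequencies[["signal"]], 1)
  expect_true("signal" %in% res$selected)

  Xnull <- matrix(rnorm(n * 20), n,
                  dimnames = list(NULL, paste0("n", 1:20)))
  res0 <- adaptive_lasso_selection(Xnull, y, reps = 10, folds = 5,
                                   seed = 3)
  expect_lte(length(res0$selected), 1)  # <= 5% of 20 features
  # keep_fraction = 0 degenerates to the union over repetitions
  resu <- adaptive_lasso_selection(X[, 1:5], y, reps = 3, folds = 4,
                                   keep_fraction = 0, seed = 4)
  expect_setequal(resu$selected,
                  names(resu$frequencies)[resu$frequencies > 0])
})

test_that("RF importance puts planted features before the elbow", {
  set.seed(20)
  n <- 250
  y <- rep(c("positive", "unlabeled"), c(80, 170))
  X <- cbind(s1 = rnorm(n) + 2.5 * (y == "positive"),
             s2 = rnorm(n) + 2.5 * (y == "positive"),
             matrix(rnorm(n * 50), n,
                    dimnames = list(NULL, paste0("noise", 1:50))))
  res <- rf_importance_selection(X, y, reps = 3, folds = 3, seed = 5,
                                 ntree = 100)
  expect_true(all(c("s1", "s2") %in% res$selected))
  expect_lte(length(res$selected), 10)
  res2 <- rf_importance_selection(X, y, reps = 3, folds = 3, seed = 5,
                                  ntree = 100)
  expect_identical(res$selected, res2$selected)
})

test_that("elbow on a strictly linear decay keeps a minimal selection", {
  expect_equal(netprio:::elbow_cut(seq(10, 1, length.out = 20)), 1L)
  expect_equal(netprio:::elbow_cut(c(5, 4)), 2L)
  # convex curve with a sharp knee after the second point
  expect_equal(netprio:::elbow_cut(c(10, 9.5, 0.3, 0.25, 0.2, 0.15)), 2L)
})

test_that("selection cascade is monotone and reproducible", {
  fix <- generate_feature_fixture(n = 200, n_informative = 3,
                                  n_noise = 40, effect = 2, seed = 6)
  cfg <- selection_config(ig_reps = 5, null_perms = 5, lasso_reps = 8,
                          lasso_folds = 5, rf_reps = 2, rf_folds = 3,
                          rf_ntree = 100)
  res <- select_features(fix$features, fix$labels, cfg, seed = 9,
                         category = "planted")
  expect_true(all(res$kept_after_correlation %in% res$kept_after_ig))
  expect_true(all(res$final %in% res$kept_after_correlation))
  expect_true(all(res$lasso_selected %in% res$kept_after_correlation))
  expect_true(all(res$rf_selected %in% res$kept_after_correlation))
  expect_setequal(res$final, union(res$lasso_selected, res$rf_selected))
  res2 <- select_features(fix$features, fix$labels, cfg, seed = 9,
                          category = "planted")
  expect_identical(res$final, res2$final)
  expect_gte(length(intersect(res$final, fix$informative)), 2)
})

test_that("cascade returns a valid empty result when nothing survives", {
  set.seed(30)
  y <- rep(c("positive", "unlabeled"), each = 40)
  X <- matrix(rnorm(80 * 6), 80, dimnames = list(NULL, paste0("f", 1:6)))
  cfg <- selection_config(ig_reps = 3, ig_threshold = 10)  # unreachable
  res <- select_features(X, y, cfg, seed = 1)
  expect_length(res$kept_after_ig, 0)
  expect_length(res$final, 0)
})
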