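make_cluster_data <- function(n0 = 40, n1 = 38, delta = 5, seed = 51) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n0 * 5), n0, 5),
             matrix(rnorm(n1 * 5, mean = delta), n1, 5))
  df <- as.data.frame(X)
  names(df) <- paste0("pse_", c("I", "II", "III", "IV", "V"))
  df$label <- rep(c(0L, 1L), c(n0, n1))
  df
}

test_that("scores binarize at the no-sickness boundary", {
  expect_identical(binarize_score(c(0, 1)), c(0L, 0L))
  expect_identical(binarize_score(c(2, 3, 4, 5)), rep(1L, 4))
  expect_error(binarize_score(6), "0..5")
  expect_error(binarize_score(-1), "0..5")
  expect_error(binarize_score(1.5), "0..5")
})

test_that("cross-validation partitions are balanced, disjoint, and seeded", {
  df <- make_cluster_data(40, 38)
  rep1 <- cross_validate_svm(df, svm_config(seed = 7))
  sizes <- sort(vapply(rep1$per_fold, function(f) sum(unlist(f)), 0),
                decreasing = TRUE)
  expect_equal(sizes, c(16, 16, 16, 15, 15))
  expect_equal(rep1$tp + rep1$fp + rep1$tn + rep1$fn, 78)

  rep2 <- cross_validate_svm(df, svm_config(seed = 7))
  expect_identical(rep1[c("tp", "fp", "tn", "fn", "per_fold")],
                   rep2[c("tp", "fp", "tn", "fn", "per_fold")])

  expect_error(cross_validate_svm(df[df$label == 1, ], svm_config()),
               "single-class")
  expect_error(cross_validate_svm(df[1:3, ], svm_config()), "folds")
})

test_that("well-separated clusters classify perfectly, permuted labels at chance", {
  df <- make_cluster_data(40, 38, delta = 5, seed = 52)
  rep <- cross_validate_svm(df, svm_config(seed = 1))
  expect_equal(rep$accuracy, 1.0)

  accs <- numeric(20)
  for (r in 1:20) {
    dfp <- df
    set.seed(5200 + r)
    dfp$label <- sample(dfp$label)
    accs[r] <- cross_validate_svm(dfp, svm_config(seed = r))$accuracy
  }
  expect_gte(mean(accs), 0.35)
  expect_lte(mean(accs), 0.65)
})

test_that("confusion metrics follow their definitions and report NA when undefined", {
  # any split of the 10 errors leaves accuracy at 68/78
  for (fp in c(0, 4, 10)) {
    m <- confusion_metrics(tp = 36, fp = fp, tn = 32, fn = 10 - fp)
    expect_equal(m$accuracy, 68 / 78)
  }
  m <- confusion_metrics(1, 1, 1, 1)
  expect_equal(unlist(m), c(accuracy = 0.5, precision = 0.5,
                            recall = 0.5, f1 = 0.5))
  perfect <- confusion_metrics(10, 0, 5, 0)
  expect_equal(perfect$accuracy, 1.0)
  expect_equal(perfect$f1, 1.0)

  no_pred_pos <- confusion_metrics(0, 0, 5, 3)
  expect_true(is.na(no_pred_pos$precision))
  expect_error(confusion_metrics(0, 0, 0, 0), "all-zero")
  expect_error(confusion_metrics(-1, 0, 1, 0), "nonnegative")
})

test_that("feature-label correlations recover sign, direction, and band order", {
  df <- data.frame(pse_I = c(0, 0, 1, 1, 0, 1),
                   pse_II = c(1, 1, 0, 0, 1, 0),
                   pse_III = rep(0.5, 6),
                   label = c(0, 0, 1, 1, 0, 1))
  r <- feature_label_correlation(df)
  expect_equal(unname(r[c("I", "II")]), c(1, -1))
  expect_true(is.na(r[["III"]]))
  expect_error(feature_label_correlation(df[1:2, ]), "at least 3")

  # generator ground truth: the strongly-broadened band correlates more
  cfg <- synthetic_config()
  rows <- lapply(1:40, function(i) {
    label <- i %% 2L
    ep <- simulate_hemo_epoch(cfg, label, seed = 6000 + i)
    f <- extract_features(make_hemo(ep$delta_hbo, cfg$fs_hz), 1)
    data.frame(pse_I = f$values[["I"]], pse_V = f$values[["V"]],
               label = label)
  })
  r2 <- feature_label_correlation(do.call(rbind, rows))
  expect_gt(r2[["I"]], r2[["V"]])
})

test_that("evaluation report prints a 2x2 confusion table", {
  df <- make_cluster_data(20, 20, seed = 53)
  rep <- cross_validate_svm(df, svm_config(seed = 2))
  out <- capture.output(print(rep))
  expect_true(any(grepl("pred 0", out)))
  expect_true(any(grepl("accuracy", out)))
})
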