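test_that("confusion metrics match hand arithmetic and conventions", {
  perfect <- classification_metrics(c(TP = 10, FP = 0, TN = 10, FN = 0))
  expect_equal(unname(perfect), rep(1, 5))
  inverted <- classification_metrics(c(TP = 0, FP = 10, TN = 0, FN = 10))
  expect_equal(unname(inverted[c("acc", "mcc")]), c(0, -1))
  got <- classification_metrics(c(TP = 8, FP = 2, TN = 7, FN = 3))
  expect_equal(unname(got), unname(oracle_metrics(8, 2, 7, 3)),
               tolerance = 1e-12)
  expect_error(classification_metrics(c(TP = -1, FP = 0, TN = 0, FN = 0)),
               "negative")
  expect_warning(z <- classification_metrics(c(TP = 0, FP = 0, TN = 5, FN = 0)),
                 "F1 undefined")
  expect_equal(unname(z[c("f1", "mcc")]), c(0, 0))
})

test_that("metrics agree with the formula oracle on random confusion matrices", {
  set.seed(99)
  for (i in 1:500) {
    cnt <- sample(0:50, 4, replace = TRUE)
    if (sum(cnt[c(1, 2, 4)]) == 0) cnt[1] <- 1  # keep F1 defined
    got <- classification_metrics(c(TP = cnt[1], FP = cnt[2],
                                    TN = cnt[3], FN = cnt[4]))
    want <- oracle_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(got[c("acc", "f1", "mcc")], want[c("acc", "f1", "mcc")],
                 tolerance = 1e-12)
  }
})

test_that("counts derive correctly from label vectors", {
  pred <- c("positive", "positive", "negative", "negative", "positive")
  truth <- c("positive", "negative", "negative", "positive", "positive")
  expect_equal(confusion_counts(pred, truth),
               c(TP = 2L, FP = 1L, TN = 1L, FN = 1L))
})

test_that("ROC/AUC behaves at the extremes and under orientation flips", {
  labs <- rep(c("positive", "negative"), each = 50)
  sc <- c(runif(50, -1, -0.5), runif(50, 0, 1))
  r <- roc_auc(sc, labs, positives_low = TRUE)
  expect_equal(r$auc, 1.0)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  r2 <- roc_auc(sc, labs, positives_low = FALSE)
  expect_equal(r2$auc, 1 - r$auc, tolerance = 1e-12)

  set.seed(3)
  labs3 <- sample(rep(c("positive", "negative"), each = 1000))
  sc3 <- runif(2000, -1, 1)
  expect_equal(roc_auc(sc3, labs3)$auc, 0.5, tolerance = 0.05)
  expect_error(roc_auc(sc, rep("positive", 100)), "both classes")
})

test_that("AUC equals the normalized Mann-Whitney statistic on tie-free data", {
  set.seed(17)
  labs <- rep(c("positive", "negative"), c(40, 60))
  sc <- c(rnorm(40, -0.4, 0.3), rnorm(60, 0.2, 0.3))
  auc <- roc_auc(sc, labs, positives_low = TRUE)$auc
  w <- stats::wilcox.test(sc[labs == "negative"], sc[labs == "positive"],
                          exact = TRUE)$statistic
  expect_equal(auc, unname(w) / (40 * 60), tolerance = 1e-9)
})

test_that("overlap and coverage follow their set definitions", {
  labs <- rep(c("positive", "negative"), c(10, 10))
  same <- cbind(a = c(rep(TRUE, 6), rep(FALSE, 14)),
                b = c(rep(TRUE, 6), rep(FALSE, 14)))
  oc <- overlap_coverage(same, labs, "positive")
  expect_equal(oc$pairwise$overlap, 0.6)
  expect_equal(oc$pairwise$coverage, 0.6)
  expect_equal(unname(oc$recall), c(0.6, 0.6))
  expect_true(is.na(oc$all_inclusive))

  disjoint <- cbind(a = c(rep(TRUE, 5), rep(FALSE, 15)),
                    b = c(rep(FALSE, 5), rep(TRUE, 5), rep(FALSE, 10)))
  oc2 <- overlap_coverage(disjoint, labs, "positive")
  expect_equal(oc2$pairwise$overlap, 0)
  expect_equal(oc2$pairwise$coverage, 1.0)

  # three predictors on a 10-positive toy table, by explicit enumeration
  calls <- cbind(a = c(rep(TRUE, 4), rep(FALSE, 6), rep(FALSE, 10)),
                 b = c(rep(FALSE, 2), rep(TRUE, 4), rep(FALSE, 14)),
                 c = c(rep(TRUE, 2), rep(FALSE, 4), rep(TRUE, 3), FALSE,
                       rep(FALSE, 10)))
  oc3 <- overlap_coverage(calls, labs, "positive")
  expect_equal(oc3$pairwise$overlap[oc3$pairwise$pair == "a+b"], 2 / 10)
  expect_equal(oc3$pairwise$coverage[oc3$pairwise$pair == "a+b"], 6 / 10)
  expect_equal(oc3$all_inclusive, 9 / 10)
  expect_true(all(oc3$all_inclusive >= oc3$pairwise$coverage))
  expect_error(overlap_coverage(calls, rep("negative", 20), "positive"),
               "no samples")
})

test_that("overlap + coverage = recall_A + recall_B on random call tables", {
  set.seed(23)
  for (i in 1:20) {
    n <- 40
    calls <- matrix(runif(n * 3) < 0.5, ncol = 3,
                    dimnames = list(NULL, c("x", "y", "z")))
    labs <- sample(c("positive", "negative"), n, replace = TRUE,
                   prob = c(0.4, 0.6))
    for (cls in c("positive", "negative")) {
      oc <- overlap_coverage(calls, labs, cls)
      for (j in seq_len(nrow(oc$pairwise))) {
        pair <- strsplit(oc$pairwise$pair[j], "+", fixed = TRUE)[[1]]
        expect_equal(oc$pairwise$overlap[j] + oc$pairwise$coverage[j],
                     sum(oc$recall[pair]), tolerance = 1e-12)
      }
    }
  }
})

test_that("default-cutoff calls use the strictly-below convention", {
  sc <- rbind(c(-0.5, -0.3, 0.0, 0.9), c(-0.42, -0.19, 0.03, 0.93))
  colnames(sc) <- predictor_ids()
  rec <- make_records(sc)
  calls <- default_cutoff_calls(rec)
  expect_equal(unname(calls[1, ]), c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(unname(calls[2, ]), rep(FALSE, 4))  # just above each cutoff
})
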