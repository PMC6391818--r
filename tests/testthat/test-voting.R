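test_that("threshold sets enforce their ordering invariants", {
  expect_error(threshold_set("miranda", 0.5, 0.9, 0.2, 0.8), "ordering")
  expect_error(threshold_set("miranda", -0.5, 0.1, 0.3, 0.2), "ordering")
  ts <- threshold_set(c("miranda", "mirdb"), c(-0.5, -0.6), c(0.5, 0.6),
                      c(-0.2, -0.3), c(0.2, 0.3))
  expect_s3_class(ts, "threshold_set")
  d4 <- d4_thresholds()
  expect_equal(d4$predictors, predictor_ids())
  expect_equal(unname(d4$t_true_1),  c(-0.179, -0.702, -0.449, 0.896))
  expect_equal(unname(d4$t_false_2), c(0.199, -0.269, -0.107, 0.972))
})

test_that("vote counting follows the strictly-below / strictly-above rule", {
  ts <- sym_thresholds(c("miranda", "mirdb"))
  expect_equal(vote_counts(c(miranda = -0.9, mirdb = -0.8), ts, 1),
               c(N_T = 2L, N_F = 0L))
  expect_equal(vote_counts(c(miranda = 0.9, mirdb = -0.9), ts, 1),
               c(N_T = 1L, N_F = 1L))
  expect_equal(vote_counts(c(miranda = 0, mirdb = 0), ts, 1),
               c(N_T = 0L, N_F = 0L))
  # scores exactly at a cutoff abstain
  expect_equal(vote_counts(c(miranda = -0.5, mirdb = 0.5), ts, 1),
               c(N_T = 0L, N_F = 0L))
  expect_error(vote_counts(c(miranda = 0.1), ts), "missing scaled score")
})

test_that("significance distances aggregate excursions beyond step-2 cutoffs", {
  ts <- sym_thresholds(c("miranda", "mirdb"), t1 = 0.5, t2 = 0.25)
  d <- significance_distances(c(miranda = -0.55, mirdb = -0.25), ts)
  expect_equal(unname(d), c(0.3, 0))
  d2 <- significance_distances(c(miranda = -0.55, mirdb = -0.55), ts)
  expect_equal(unname(d2["d_T2"]), 0.3 * sqrt(2), tolerance = 1e-9)
  expect_equal(unname(significance_distances(c(miranda = 0, mirdb = 0.2), ts)),
               c(0, 0))
  d3 <- significance_distances(c(miranda = -0.55, mirdb = -0.55), ts,
                               aggregate = "sum")
  expect_equal(unname(d3["d_T2"]), 0.6)
})

test_that("the three resolution stages fire in the documented order", {
  ts <- sym_thresholds(c("miranda", "mirdb", "pita", "targetscan"))
  s <- c(miranda = -0.9, mirdb = -0.8, pita = -0.7, targetscan = 0.9)
  dec <- tree_classify(s, ts)   # N_T1 = 3 > N_F1 = 1
  expect_equal(dec$label, "true"); expect_equal(dec$stage, "step1")

  ts2 <- sym_thresholds(c("miranda", "mirdb", "pita"))
  s2 <- c(miranda = -0.9, mirdb = 0.9, pita = 0.3)  # 1:1 then 1:2
  dec2 <- tree_classify(s2, ts2)
  expect_equal(dec2$encoding[["N_T1"]], 1)
  expect_equal(dec2$encoding[["N_F1"]], 1)
  expect_equal(dec2$label, "false"); expect_equal(dec2$stage, "step2")

  s3 <- c(miranda = -0.75, mirdb = 0.55)  # tied counts, d_T2 0.5 > d_F2 0.3
  dec3 <- tree_classify(s3, sym_thresholds(c("miranda", "mirdb")))
  expect_equal(dec3$label, "true"); expect_equal(dec3$stage, "significance")
  expect_equal(unname(dec3$encoding[c("d_T2", "d_F2")]), c(0.5, 0.3))

  # exact distance tie (all abstain) resolves to the configured side
  s4 <- c(miranda = 0, mirdb = 0)
  expect_equal(tree_classify(s4, sym_thresholds(c("miranda", "mirdb")))$label,
               "false")
  expect_equal(tree_classify(s4, sym_thresholds(c("miranda", "mirdb")),
                             tie = "true")$label, "true")
})

test_that("tree_classify matches the flowchart oracle exhaustively (n = 2)", {
  grid <- seq(-1, 1, by = 0.1)
  ts <- sym_thresholds(c("miranda", "mirdb"), t1 = 0.55, t2 = 0.25)
  for (a in grid) for (b in grid) {
    s <- c(miranda = a, mirdb = b)
    expect_identical(tree_classify(s, ts)$label, oracle_tree(s, ts))
  }
})

test_that("tree_classify matches the flowchart oracle on random inputs (n = 3, 4)", {
  set.seed(101)
  for (preds in list(c("miranda", "mirdb", "pita"), predictor_ids())) {
    ts <- random_thresholds(preds)
    S <- matrix(runif(2000 * length(preds), -1, 1), ncol = length(preds),
                dimnames = list(NULL, preds))
    impl <- tree_classify_matrix(make_records(S), ts)
    want <- apply(S, 1, function(r) oracle_tree(as.list(r), ts))
    expect_identical(impl, unname(want))
    # both aggregation rules agree with the oracle
    impl_sum <- tree_classify_matrix(make_records(S), ts, aggregate = "sum")
    want_sum <- apply(S, 1, function(r) oracle_tree(as.list(r), ts, "sum"))
    expect_identical(impl_sum, unname(want_sum))
  }
})

test_that("lowering one score never flips a true decision to false", {
  set.seed(77)
  for (i in 1:200) {
    preds <- predictor_ids()[1:sample(2:4, 1)]
    ts <- random_thresholds(preds)
    s <- stats::setNames(runif(length(preds), -1, 1), preds)
    if (tree_classify(s, ts)$label != "true") next
    j <- sample(length(preds), 1)
    s[j] <- runif(1, -1, s[j])
    expect_identical(tree_classify(s, ts)$label, "true")
  }
})

test_that("relaxing thresholds never loses votes (count consistency)", {
  set.seed(55)
  for (i in 1:100) {
    preds <- predictor_ids()[1:sample(2:4, 1)]
    ts <- random_thresholds(preds)
    s <- stats::setNames(runif(length(preds), -1, 1), preds)
    v1 <- vote_counts(s, ts, 1); v2 <- vote_counts(s, ts, 2)
    expect_lte(v1["N_T"], v2["N_T"])
    expect_lte(v1["N_F"], v2["N_F"])
    expect_lte(v1["N_T"] + v1["N_F"], length(preds))
  }
})

test_that("feature encoding has width n + 6 and is deterministic", {
  for (preds in list(predictor_ids(), c("miranda", "mirdb", "pita"),
                     c("pita", "targetscan"))) {
    ts <- sym_thresholds(preds)
    s <- stats::setNames(seq(-0.8, 0.4, length.out = length(preds)), preds)
    v <- encode_features(s, ts)
    expect_length(v, length(preds) + 6L)
    expect_identical(v, encode_features(s, ts))
  }
  # scores at mid-interval with symmetric thresholds: all-zero encoding tail
  ts <- sym_thresholds(c("miranda", "mirdb"))
  v <- encode_features(c(miranda = 0, mirdb = 0), ts)
  expect_equal(v[3:8], rep(0, 6))
})

test_that("vectorized encoding agrees with the scalar path", {
  set.seed(31)
  preds <- c("miranda", "pita", "targetscan")
  ts <- random_thresholds(preds)
  S <- matrix(runif(150, -1, 1), ncol = 3, dimnames = list(NULL, preds))
  E <- encode_matrix(make_records(S), ts)
  for (i in c(1, 17, 50)) {
    expect_equal(unname(E[i, ]),
                 encode_features(stats::setNames(S[i, ], preds), ts))
  }
})
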