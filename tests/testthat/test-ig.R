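test_that("information gain reproduces hand-computed contingency values", {
  # perfect separator of a balanced set recovers the full parent entropy
  expect_equal(information_gain(c("positive", "positive", "negative", "negative"),
                                c(-0.9, -0.8, 0.8, 0.9), 0), 1.0)
  # identical scores are uninformative at any cutoff
  expect_equal(information_gain(c("positive", "positive", "negative", "negative"),
                                rep(0.2, 4), 0.2), 0)
  # split (1 pos, 0 neg | 0 pos, 3 neg): child entropies vanish
  labs <- c("positive", "negative", "negative", "negative")
  sc <- c(-0.9, -0.5, 0.2, 0.7)
  want <- -(0.25 * log2(0.25) + 0.75 * log2(0.75))
  expect_equal(information_gain(labs, sc, -0.7), want, tolerance = 1e-12)
  expect_equal(information_gain(labs, sc, -0.7), oracle_ig(labs, sc, -0.7),
               tolerance = 1e-12)
})

test_that("information gain matches the contingency-entropy oracle on random instances", {
  set.seed(2024)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    labs <- sample(c("positive", "negative"), n, replace = TRUE)
    sc <- round(runif(n, -1, 1), 2)   # ties included
    x <- runif(1, -1.1, 1.1)
    expect_equal(information_gain(labs, sc, x), oracle_ig(labs, sc, x),
                 tolerance = 1e-12)
  }
})

test_that("information gain is bounded and monotone-transform invariant", {
  set.seed(5)
  labs <- sample(c("positive", "negative"), 60, replace = TRUE)
  sc <- runif(60, -1, 1)
  base <- -sum(prop.table(table(labs)) * log2(prop.table(table(labs))))
  for (x in seq(-1, 1, by = 0.25)) {
    ig <- information_gain(labs, sc, x)
    expect_gte(ig, 0); expect_lte(ig, base + 1e-12)
    # a strictly monotone transform preserving split membership at x
    expect_equal(information_gain(labs, sc^3, x^3), ig, tolerance = 1e-12)
  }
  # grid ends with one empty side give zero gain
  expect_equal(information_gain(labs, sc, 2), 0)
})

test_that("the IG curve peaks at the separator and vanishes under shuffling", {
  set.seed(46)
  labs <- rep(c("positive", "negative"), each = 50)
  sc <- c(runif(50, -1, -0.3), runif(50, 0.3, 1))
  curve <- ig_curve(labs, sc, grid_resolution = 200)
  base <- curve$base_entropy
  expect_equal(max(curve$ig), base, tolerance = 1e-12)
  # the maximum sits in the empty margin between the two classes
  argmax <- curve$grid[which.max(curve$ig)]
  expect_gte(argmax, max(sc[labs == "positive"]))
  expect_lte(argmax, min(sc[labs == "negative"]))

  set.seed(8)
  labs2 <- sample(rep(c("positive", "negative"), each = 500))
  sc2 <- runif(1000, -1, 1)
  curve2 <- ig_curve(labs2, sc2, grid_resolution = 200, midpoints = FALSE)
  expect_lt(max(curve2$ig), 0.05)

  expect_length(ig_curve(labs, sc, grid_resolution = 10,
                         midpoints = FALSE)$ig, 10L)
  expect_warning(c0 <- ig_curve(rep("negative", 20), runif(20)), "one class")
  expect_true(all(c0$ig == 0))
})

test_that("spike extraction ranks local maxima and handles edge shapes", {
  mk <- function(grid, ig) structure(list(grid = grid, ig = ig,
                                          base_entropy = max(ig)),
                                     class = "ig_curve")
  single <- mk(seq(-1, 1, length.out = 21),
               exp(-((seq(-1, 1, length.out = 21) + 0.2)^2) * 20))
  expect_equal(find_spikes(single, 1)$score, -0.2, tolerance = 0.1)

  # two equal-height peaks: the smaller score ranks first
  g <- seq(-1, 1, length.out = 41)
  twin <- mk(g, pmax(exp(-200 * (g + 0.5)^2), exp(-200 * (g - 0.5)^2)))
  expect_equal(find_spikes(twin, 1)$score, -0.5, tolerance = 0.03)

  mono <- mk(g, g + 1)
  expect_warning(sp <- find_spikes(mono, 4), "candidate")
  expect_equal(sp$score[1], 1)

  # plateaus merge into one candidate
  plat <- mk(g, c(rep(0, 10), rep(1, 5), rep(0, 26)))
  expect_warning(sp2 <- find_spikes(plat, 4), "candidate")
  expect_equal(nrow(sp2[sp2$ig == 1, ]), 1L)
})

test_that("threshold tuning recovers a planted cutoff within one grid step", {
  set.seed(13)
  n <- 400
  # predictor 1 separates perfectly at -0.3; predictor 2 is pure noise
  labs <- rep(c("positive", "negative"), c(80, 320))
  s1 <- c(runif(80, -1, -0.35), runif(320, -0.25, 1))
  s2 <- runif(n, -1, 1)
  rec <- make_records(cbind(miranda = s1, mirdb = s2), labels = labs)
  init <- default_thresholds(c("miranda", "mirdb"))
  fit <- tune_thresholds(rec, init, grid_resolution = 200)
  step <- 2 / 199
  # the tuned stringent true cutoff of the informative predictor sits at
  # the planted boundary (within one grid step of the gap (-0.35, -0.25))
  expect_gte(fit$thresholds$t_true_1[["miranda"]], -0.35 - step)
  expect_lte(fit$thresholds$t_true_1[["miranda"]], -0.25 + step)
  # tuning starts at the generic defaults and can only improve
  expect_gte(fit$accuracy,
             mean((tree_classify_matrix(rec, init) == "true") ==
                  (rec$label == "positive")))
})

test_that("tuning never degrades accuracy and preserves the ordering invariants", {
  set.seed(21)
  sim <- simulate_interactions(sim_config(n_samples = 500, seed = 4,
                                          missingness = c("D2-4" = 1)))
  rec <- sim$truth[sim$truth$subset == "D2-4", ]
  evaluator <- function(ts) {
    calls <- tree_classify_matrix(rec, ts)
    mean((calls == "true") == (rec$label == "positive"))
  }
  for (i in 1:3) {
    init <- random_thresholds(c("mirdb", "pita"))
    fit <- tune_thresholds(rec, init, evaluator, grid_resolution = 100)
    expect_gte(fit$accuracy, evaluator(init))
    expect_silent(validate_thresholds(fit$thresholds))
  }
})

test_that("an already-optimal threshold set is returned unchanged", {
  labs <- rep(c("positive", "negative"), each = 20)
  sc <- c(rep(-0.8, 20), rep(0.8, 20))
  rec <- make_records(cbind(miranda = sc, mirdb = sc), labels = labs)
  init <- sym_thresholds(c("miranda", "mirdb"), t1 = 0.5, t2 = 0.25)
  fit <- tune_thresholds(rec, init, grid_resolution = 50)
  expect_equal(fit$accuracy, 1.0)
  # accuracy is already perfect, so every accepted move keeps it perfect
  expect_true(all(fit$history$accuracy[fit$history$accepted] == 1))
})
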