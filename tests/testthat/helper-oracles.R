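# Independent oracles, written as literal transcriptions of the procedure
# definitions; deliberately loop-based and separate from the package's
# vectorized implementations.

# flowchart transcription of the two-step significance-voting tree
oracle_tree <- function(scores, ts, aggregate = "euclidean", tie = "false") {
  n_t1 <- 0L; n_f1 <- 0L; n_t2 <- 0L; n_f2 <- 0L
  ct <- c(); cf <- c()
  for (p in ts$predictors) {
    s <- scores[[p]]
    if (s < ts$t_true_1[[p]]) n_t1 <- n_t1 + 1L
    if (s > ts$t_false_1[[p]]) n_f1 <- n_f1 + 1L
    if (s < ts$t_true_2[[p]]) n_t2 <- n_t2 + 1L
    if (s > ts$t_false_2[[p]]) n_f2 <- n_f2 + 1L
    ct <- c(ct, max(0, ts$t_true_2[[p]] - s))
    cf <- c(cf, max(0, s - ts$t_false_2[[p]]))
  }
  if (n_t1 > n_f1) return("true")
  if (n_f1 > n_t1) return("false")
  if (n_t2 > n_f2) return("true")
  if (n_f2 > n_t2) return("false")
  d_t <- if (aggregate == "euclidean") sqrt(sum(ct^2)) else sum(ct)
  d_f <- if (aggregate == "euclidean") sqrt(sum(cf^2)) else sum(cf)
  if (d_t > d_f) return("true")
  if (d_f > d_t) return("false")
  tie
}

# contingency-table entropy computation of information gain
oracle_ig <- function(labels, scores, x) {
  ent <- function(v) {
    tab <- table(v)
    p <- tab / sum(tab)
    -sum(ifelse(p > 0, p * log2(p), 0))
  }
  side <- scores > x
  h_parent <- ent(labels)
  h_child <- 0
  for (g in c(TRUE, FALSE)) {
    idx <- side == g
    if (any(idx)) h_child <- h_child + mean(idx) * ent(labels[idx])
  }
  h_parent - h_child
}

# direct-formula confusion metrics
oracle_metrics <- function(tp, fp, tn, fn) {
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  c(sens = tp / (tp + fn), spec = tn / (tn + fp),
    acc = (tp + tn) / (tp + fp + tn + fn),
    f1 = 2 * tp / (2 * tp + fp + fn),
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den)
}

# a symmetric threshold set handy for grid tests
sym_thresholds <- function(preds, t1 = 0.5, t2 = 0.25) {
  threshold_set(preds, t_true_1 = rep(-t1, length(preds)),
                t_false_1 = rep(t1, length(preds)),
                t_true_2 = rep(-t2, length(preds)),
                t_false_2 = rep(t2, length(preds)))
}

# a random valid threshold set
random_thresholds <- function(preds) {
  n <- length(preds)
  q <- t(replicate(n, sort(stats::runif(4, -1, 1))))
  threshold_set(preds, t_true_1 = q[, 1], t_true_2 = q[, 2],
                t_false_2 = q[, 3], t_false_1 = q[, 4])
}

# build a scaled records frame for a fixed predictor combination
make_records <- function(scaled, labels = NULL) {
  preds <- colnames(scaled)
  df <- data.frame(mirna_id = sprintf("m%d", seq_len(nrow(scaled))),
                   gene_id = sprintf("g%d", seq_len(nrow(scaled))))
  for (p in predictor_ids()) {
    if (p %in% preds) {
      df[[p]] <- unscale_score(p, scaled[, p])
      df[[paste0("scaled_", p)]] <- scaled[, p]
    } else {
      df[[p]] <- NA_real_
      df[[paste0("scaled_", p)]] <- NA_real_
    }
  }
  if (!is.null(labels)) df$label <- labels
  df
}
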