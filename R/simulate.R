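#' Configuration of the synthetic interaction-score generator
#'
#' The generator emulates whole-genome prediction dumps at the score
#' level: per-predictor scores in native ranges, true interactions
#' shifted toward the strong end of the axis, predictor complementarity
#' (a fraction of positives carries signal in a single predictor only),
#' and availability patterns covering all eleven routable subsets.
#'
#' Defaults reproduce the structure the method assumes: a ~1:10 class
#' imbalance (`positive_fraction = 0.08`), mask frequencies proportional
#' to the published non-redundant subset sizes, truncated-Gaussian score
#' noise.
#'
#' @param n_samples Number of miRNA:mRNA pairs to draw.
#' @param positive_fraction Fraction of true interactions (default 0.08).
#' @param effect_size Scaled-score shift of detectable positives toward
#'   -1 (default 0.9).
#' @param complementarity Fraction of positives detectable by exactly one
#'   of the present predictors (default 0.6); the remaining positives
#'   carry an attenuated shift (`effect_size * shared_attenuation`) on
#'   every present predictor, so their evidence must be combined.
#' @param shared_attenuation Attenuation of the shift for shared-signal
#'   positives (default 0.5).
#' @param missingness Named probability vector over availability
#'   patterns: the eleven subset names and optionally the four predictor
#'   ids for unroutable single-score records. Default: proportional to
#'   the published non-redundant subset sizes.
#' @param noise_sd Gaussian noise s.d. on the scaled axis (default 0.25).
#' @param negative_centers Scaled-score mode(s) of the negative
#'   population (default 0.3); several centers give a mixture, handy for
#'   spike-rich information-gain curves.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 2000L, positive_fraction = 0.08,
                       effect_size = 0.9, complementarity = 0.6,
                       shared_attenuation = 0.5, missingness = NULL,
                       noise_sd = 0.25, negative_centers = 0.3,
                       seed = 1L) {
  if (is.null(missingness)) {
    sizes <- c("D4" = 22446, "D3-1" = 9271, "D3-2" = 2478, "D3-3" = 5529,
               "D3-4" = 2984, "D2-1" = 892, "D2-2" = 974, "D2-3" = 429,
               "D2-4" = 810, "D2-5" = 430, "D2-6" = 363)
    missingness <- sizes / sum(sizes)
  }
  known <- c(names(subset_keys()), predictor_ids())
  if (!all(names(missingness) %in% known))
    stop("unknown availability pattern(s): ",
         paste(setdiff(names(missingness), known), collapse = ", "))
  if (any(missingness < 0) || abs(sum(missingness) - 1) > 1e-8)
    stop("missingness probabilities must be non-negative and sum to 1")
  if (positive_fraction < 0 || positive_fraction > 1)
    stop("positive_fraction must lie in [0, 1]")
  if (complementarity < 0 || complementarity > 1)
    stop("complementarity must lie in [0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(list(n_samples = as.integer(n_samples),
                 positive_fraction = positive_fraction,
                 effect_size = effect_size,
                 complementarity = complementarity,
                 shared_attenuation = shared_attenuation,
                 missingness = missingness, noise_sd = noise_sd,
                 negative_centers = negative_centers,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.pattern_predictors <- function(name) {
  if (name %in% names(subset_keys())) subset_predictors(name) else name
}

#' Generate a synthetic score table and positive-pair list
#'
#' Scores are drawn on the scaled axis (truncated to \[-1, 1\]) and
#' mapped back to each predictor's native range — miRDB therefore scores
#' high-is-better in the raw output, as the real predictor does.
#' Byte-identical output under identical config and seed.
#'
#' @param config A `sim_config`.
#' @param score_path,pairs_path Optional TSV output paths.
#' @return List: `scores` (raw records data frame with `NA` for absent
#'   scores), `pairs` (positive-pair data frame), `truth` (records with
#'   scaled columns and labels, for direct use in tests).
#' @export
simulate_interactions <- function(config, score_path = NULL,
                                  pairs_path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  mirna_id <- sprintf("mir-%04d", seq_len(n))
  gene_id <- sprintf("gene-%04d", seq_len(n))
  pattern <- sample(names(config$missingness), n, replace = TRUE,
                    prob = config$missingness)
  positive <- stats::runif(n) < config$positive_fraction
  scaled <- matrix(NA_real_, n, 4, dimnames = list(NULL, predictor_ids()))
  centers <- config$negative_centers
  for (i in seq_len(n)) {
    preds <- .pattern_predictors(pattern[i])
    mu <- centers[sample.int(length(centers), length(preds), replace = TRUE)]
    if (positive[i]) {
      if (stats::runif(1) < config$complementarity) {
        carrier <- preds[sample.int(length(preds), 1L)]
        mu[preds == carrier] <- mu[preds == carrier] - config$effect_size
      } else {
        mu <- mu - config$effect_size * config$shared_attenuation
      }
    }
    scaled[i, preds] <- pmin(1, pmax(-1, stats::rnorm(length(preds), mu,
                                                      config$noise_sd)))
  }
  raw <- scaled
  for (p in predictor_ids()) raw[, p] <- unscale_score(p, scaled[, p])
  scores <- data.frame(mirna_id = mirna_id, gene_id = gene_id,
                       raw, check.names = FALSE)
  class(scores) <- c("metadann_records", "data.frame")
  pairs <- data.frame(mirna_id = mirna_id[positive],
                      gene_id = gene_id[positive])
  truth <- scores
  for (p in predictor_ids()) truth[[paste0("scaled_", p)]] <- scaled[, p]
  truth$label <- ifelse(positive, "positive", "negative")
  truth$subset <- pattern
  truth$subset[!pattern %in% names(subset_keys())] <- NA
  if (!is.null(score_path)) write_score_table(scores, score_path)
  if (!is.null(pairs_path))
    utils::write.table(pairs, pairs_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(scores = scores, pairs = pairs, truth = truth)
}

#' A small hand-checkable fixture table
#'
#' A fixed 24-row scaled, labeled table (hard-coded, not sampled)
#' spanning all eleven routable availability patterns plus one
#' single-score record. Under the shipped D4 thresholds the row
#' `mir-tie`/`gene-tie` ties at both vote steps and is resolved by
#' significance voting (d_T2 = 0.567 > d_F2 = 0.469, hence "true").
#'
#' @return A records data frame with raw, scaled, `label` and `subset`
#'   columns.
#' @export
worked_fixture <- function() {
  # per-predictor archetype scores on the scaled axis
  strong <- c(miranda = -0.9, mirdb = -0.9, pita = -0.8, targetscan = 0.5)
  weak <- c(miranda = 0.9, mirdb = 0.5, pita = 0.5, targetscan = 0.99)
  rows <- list()
  add <- function(id, preds, values, label) {
    r <- stats::setNames(rep(NA_real_, 4), predictor_ids())
    r[preds] <- values[preds]
    rows[[length(rows) + 1L]] <<- c(list(id = id, label = label), as.list(r))
  }
  pats <- subset_keys()
  for (nm in names(pats)) {
    add(paste0(nm, "-pos"), pats[[nm]], strong, "positive")
    add(paste0(nm, "-neg"), pats[[nm]], weak, "negative")
  }
  # two-step tie resolved by significance voting (see docs)
  add("tie", predictor_ids(),
      c(miranda = -0.5, mirdb = 0.2, pita = -0.15, targetscan = 0.97),
      "positive")
  add("single", "miranda", strong, "negative")   # unroutable: one score only
  tab <- do.call(rbind, lapply(rows, function(r)
    data.frame(mirna_id = paste0("mir-", r$id), gene_id = paste0("gene-", r$id),
               miranda = r$miranda, mirdb = r$mirdb, pita = r$pita,
               targetscan = r$targetscan, label = r$label)))
  for (p in predictor_ids()) {
    tab[[paste0("scaled_", p)]] <- tab[[p]]
    tab[[p]] <- unscale_score(p, tab[[p]])
  }
  tab <- assign_subsets(tab)
  class(tab) <- c("metadann_records", "data.frame")
  tab
}
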