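#' Construct a dual-threshold set for one module
#'
#' Each predictor in a module carries four cutoffs on the scaled axis: a
#' 1st-step (stringent) and a 2nd-step (relaxed) threshold for calling
#' "true", and likewise for calling "false". Because predicted
#' interactions score low on the scaled axis, true thresholds lie below
#' false thresholds, and the stringent true threshold is the smallest:
#' `t_true_1 <= t_true_2 < t_false_2 <= t_false_1` per predictor.
#'
#' @param predictors Character vector of predictor ids (canonical order).
#' @param t_true_1,t_false_1,t_true_2,t_false_2 Numeric vectors (one value
#'   per predictor) of scaled cutoffs.
#' @return An object of class `threshold_set`: a list of the five fields.
#' @export
threshold_set <- function(predictors, t_true_1, t_false_1, t_true_2,
                          t_false_2) {
  n <- length(predictors)
  stopifnot(n >= 1, length(t_true_1) == n, length(t_false_1) == n,
            length(t_true_2) == n, length(t_false_2) == n)
  ts <- list(predictors = predictors,
             t_true_1 = stats::setNames(as.numeric(t_true_1), predictors),
             t_false_1 = stats::setNames(as.numeric(t_false_1), predictors),
             t_true_2 = stats::setNames(as.numeric(t_true_2), predictors),
             t_false_2 = stats::setNames(as.numeric(t_false_2), predictors))
  class(ts) <- "threshold_set"
  validate_thresholds(ts)
  ts
}

#' Validate threshold ordering
#'
#' Checks `t_true_1 <= t_true_2 < t_false_2 <= t_false_1` for every
#' predictor; relaxing a threshold can then never lose a vote.
#' @param ts A `threshold_set`.
#' @return `ts` invisibly; errors when an ordering constraint fails.
#' @export
validate_thresholds <- function(ts) {
  bad <- !(ts$t_true_1 <= ts$t_true_2 & ts$t_true_2 < ts$t_false_2 &
           ts$t_false_2 <= ts$t_false_1)
  if (any(bad))
    stop("threshold ordering violated for predictor(s): ",
         paste(ts$predictors[bad], collapse = ", "))
  invisible(ts)
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("Dual thresholds (scaled axis) for:", paste(x$predictors, collapse = ", "), "\n")
  m <- rbind(`true, step 1` = x$t_true_1, `true, step 2` = x$t_true_2,
             `false, step 2` = x$t_false_2, `false, step 1` = x$t_false_1)
  print(round(m, 3))
  invisible(x)
}

#' Default thresholds from the scaled default cutoffs
#'
#' A generic starting point for tuning: the 1st-step cutoffs sit one
#' `margin` inside the predictor's scaled default cutoff, 2nd-step cutoffs
#' at the default cutoff itself (true side) and mirrored about it (false
#' side).
#'
#' @param predictors Predictor ids.
#' @param margin Gap between stringent and relaxed cutoffs (default 0.15).
#' @return A `threshold_set`.
#' @export
default_thresholds <- function(predictors, margin = 0.15) {
  cut <- scaled_default_cutoffs()[predictors]
  threshold_set(predictors,
                t_true_1 = pmax(-1, cut - margin),
                t_false_1 = pmin(1, cut + 2 * margin),
                t_true_2 = cut,
                t_false_2 = pmin(1, cut + margin))
}

#' Read / write threshold sets as JSON
#'
#' Threshold sets are serialized keyed by module name, each holding the
#' predictor ids and the four cutoff vectors.
#'
#' @param sets Named list of `threshold_set` objects (names = module names).
#' @param path JSON file path.
#' @return `read_thresholds`: named list of `threshold_set`s.
#' @export
write_thresholds <- function(sets, path) {
  payload <- lapply(sets, function(ts) list(
    predictors = ts$predictors,
    t_true_1 = unname(ts$t_true_1), t_false_1 = unname(ts$t_false_1),
    t_true_2 = unname(ts$t_true_2), t_false_2 = unname(ts$t_false_2)))
  jsonlite::write_json(payload, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_thresholds
#' @param path JSON file path.
#' @export
read_thresholds <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(payload, function(x)
    threshold_set(x$predictors, x$t_true_1, x$t_false_1, x$t_true_2,
                  x$t_false_2))
}

#' Published D4 thresholds
#'
#' The tuned dual thresholds of the four-predictor module, shipped as a
#' packaged fixture (miRanda, miRDB, PITA, TargetScan order).
#' @return A `threshold_set`.
#' @export
d4_thresholds <- function() {
  read_thresholds(system.file("extdata", "thresholds_d4.json",
                              package = "metadann"))[["D4"]]
}

#' Count true/false votes at one threshold level
#'
#' Predictor p votes true at level L iff its scaled score is strictly
#' below `t_true_L(p)`, votes false iff strictly above `t_false_L(p)`, and
#' abstains otherwise.
#'
#' @param scores Named numeric vector of scaled scores covering every
#'   predictor in `ts`.
#' @param ts A `threshold_set`.
#' @param level 1 (stringent) or 2 (relaxed).
#' @return Named integer vector `c(N_T, N_F)`.
#' @export
vote_counts <- function(scores, ts, level = 1L) {
  s <- .module_scores(scores, ts)
  tt <- if (level == 1L) ts$t_true_1 else ts$t_true_2
  tf <- if (level == 1L) ts$t_false_1 else ts$t_false_2
  c(N_T = sum(s < tt), N_F = sum(s > tf))
}

.module_scores <- function(scores, ts) {
  s <- scores[ts$predictors]
  if (any(is.na(s)))
    stop("missing scaled score for predictor(s): ",
         paste(ts$predictors[is.na(s)], collapse = ", "))
  s
}

#' Significance distances beyond the 2nd-step thresholds
#'
#' Per predictor, the excursion of the score beyond its relaxed cutoff:
#' `c_T(p) = max(0, t_true_2(p) - score)` on the true side and
#' `c_F(p) = max(0, score - t_false_2(p))` on the false side; abstaining
#' predictors contribute zero. The aggregate is the Euclidean norm by
#' default, or the plain sum when `aggregate = "sum"`.
#'
#' @inheritParams vote_counts
#' @param aggregate `"euclidean"` (default) or `"sum"`.
#' @return Named numeric vector `c(d_T2, d_F2)`.
#' @export
significance_distances <- function(scores, ts,
                                   aggregate = c("euclidean", "sum")) {
  aggregate <- match.arg(aggregate)
  s <- .module_scores(scores, ts)
  cT <- pmax(0, ts$t_true_2 - s)
  cF <- pmax(0, s - ts$t_false_2)
  if (aggregate == "euclidean")
    c(d_T2 = sqrt(sum(cT^2)), d_F2 = sqrt(sum(cF^2)))
  else
    c(d_T2 = sum(cT), d_F2 = sum(cF))
}

#' Per-predictor signed threshold distances (diagnostics)
#'
#' Signed distances of each score from its 1st-level (`b`) and 2nd-level
#' (`c`) true/false cutoffs. Exposed for inspection; not part of the
#' network's feature vector.
#'
#' @inheritParams vote_counts
#' @return A data frame with one row per predictor.
#' @export
threshold_distances <- function(scores, ts) {
  s <- .module_scores(scores, ts)
  data.frame(predictor = ts$predictors,
             b_true = unname(ts$t_true_1 - s),
             b_false = unname(s - ts$t_false_1),
             c_true = unname(ts$t_true_2 - s),
             c_false = unname(s - ts$t_false_2),
             row.names = NULL)
}

#' Dual-threshold two-step significance-voting decision tree
#'
#' Step 1 compares true and false vote counts under the stringent
#' cutoffs; a strict majority decides. On a tie the relaxed cutoffs are
#' used. On a second tie, significance voting decides: the side whose
#' scores lie further beyond the relaxed cutoffs (larger aggregate
#' distance) wins; an exact distance tie — including the fully abstaining
#' case 0 == 0 — resolves to false, the majority class.
#'
#' @inheritParams significance_distances
#' @param tie Label returned on an exact significance tie (default
#'   `"false"`).
#' @return A list of class `tree_decision`: `label` (`"true"`/`"false"`),
#'   `stage` (`"step1"`, `"step2"` or `"significance"`), and `encoding`
#'   (named vector `N_T1, N_F1, N_T2, N_F2, d_T2, d_F2`).
#' @export
tree_classify <- function(scores, ts, aggregate = c("euclidean", "sum"),
                          tie = c("false", "true")) {
  aggregate <- match.arg(aggregate)
  tie <- match.arg(tie)
  v1 <- vote_counts(scores, ts, 1L)
  v2 <- vote_counts(scores, ts, 2L)
  d <- significance_distances(scores, ts, aggregate)
  enc <- c(N_T1 = unname(v1["N_T"]), N_F1 = unname(v1["N_F"]),
           N_T2 = unname(v2["N_T"]), N_F2 = unname(v2["N_F"]),
           d_T2 = unname(d["d_T2"]), d_F2 = unname(d["d_F2"]))
  if (v1["N_T"] != v1["N_F"]) {
    label <- if (v1["N_T"] > v1["N_F"]) "true" else "false"
    stage <- "step1"
  } else if (v2["N_T"] != v2["N_F"]) {
    label <- if (v2["N_T"] > v2["N_F"]) "true" else "false"
    stage <- "step2"
  } else {
    stage <- "significance"
    label <- if (d["d_T2"] > d["d_F2"]) "true"
             else if (d["d_T2"] < d["d_F2"]) "false"
             else tie
  }
  structure(list(label = label, stage = stage, encoding = enc),
            class = "tree_decision")
}

#' @export
print.tree_decision <- function(x, ...) {
  cat("tree decision:", x$label, "(resolved at", x$stage, ")\n")
  print(round(x$encoding, 4))
  invisible(x)
}

#' Encode a record for the neural network
#'
#' Feature vector = the module's scaled scores in canonical predictor
#' order followed by the six voting-tree quantities
#' `N_T1, N_F1, N_T2, N_F2, d_T2, d_F2`; length n + 6, i.e. 10, 9 or 8
#' for 4-, 3- or 2-predictor modules.
#'
#' @inheritParams significance_distances
#' @return Numeric feature vector of length `length(ts$predictors) + 6`.
#' @export
encode_features <- function(scores, ts, aggregate = c("euclidean", "sum")) {
  aggregate <- match.arg(aggregate)
  s <- .module_scores(scores, ts)
  dec <- tree_classify(scores, ts, aggregate)
  unname(c(s, dec$encoding))
}

#' Encode many records at once
#'
#' Vectorized [encode_features()] over the rows of a scaled records data
#' frame restricted to the module's predictors.
#'
#' @param records Scaled records data frame.
#' @param ts A `threshold_set`.
#' @inheritParams significance_distances
#' @return Numeric matrix, one row per record, `n + 6` columns.
#' @export
encode_matrix <- function(records, ts, aggregate = c("euclidean", "sum")) {
  aggregate <- match.arg(aggregate)
  S <- as.matrix(records[, paste0("scaled_", ts$predictors), drop = FALSE])
  colnames(S) <- ts$predictors
  if (any(is.na(S))) stop("missing scaled scores for this module")
  n <- length(ts$predictors)
  tt1 <- matrix(ts$t_true_1, nrow(S), n, byrow = TRUE)
  tf1 <- matrix(ts$t_false_1, nrow(S), n, byrow = TRUE)
  tt2 <- matrix(ts$t_true_2, nrow(S), n, byrow = TRUE)
  tf2 <- matrix(ts$t_false_2, nrow(S), n, byrow = TRUE)
  NT1 <- rowSums(S < tt1); NF1 <- rowSums(S > tf1)
  NT2 <- rowSums(S < tt2); NF2 <- rowSums(S > tf2)
  cT <- tt2 - S; cT[cT < 0] <- 0
  cF <- S - tf2; cF[cF < 0] <- 0
  if (aggregate == "euclidean") {
    dT <- sqrt(rowSums(cT^2)); dF <- sqrt(rowSums(cF^2))
  } else {
    dT <- rowSums(cT); dF <- rowSums(cF)
  }
  cbind(S, N_T1 = NT1, N_F1 = NF1, N_T2 = NT2, N_F2 = NF2,
        d_T2 = dT, d_F2 = dF)
}

#' Vectorized tree classification over records
#'
#' @inheritParams encode_matrix
#' @param tie Label on an exact significance tie.
#' @return Character vector of `"true"`/`"false"` calls.
#' @export
tree_classify_matrix <- function(records, ts,
                                 aggregate = c("euclidean", "sum"),
                                 tie = c("false", "true")) {
  aggregate <- match.arg(aggregate)
  tie <- match.arg(tie)
  E <- encode_matrix(records, ts, aggregate)
  NT1 <- E[, "N_T1"]; NF1 <- E[, "N_F1"]
  NT2 <- E[, "N_T2"]; NF2 <- E[, "N_F2"]
  dT <- E[, "d_T2"]; dF <- E[, "d_F2"]
  out <- ifelse(NT1 != NF1, ifelse(NT1 > NF1, "true", "false"),
         ifelse(NT2 != NF2, ifelse(NT2 > NF2, "true", "false"),
         ifelse(dT != dF, ifelse(dT > dF, "true", "false"), tie)))
  unname(out)
}
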