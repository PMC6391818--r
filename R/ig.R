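.entropy_bits <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Information gain of a single score cutoff
#'
#' Splits the labeled set into the group with score strictly above `x`
#' and the group with score at or below `x`, and returns the parent
#' entropy minus the split-weighted child entropies, in bits. Empty
#' groups contribute zero.
#'
#' @param labels Character or logical vector; `"positive"`/`TRUE` marks a
#'   positive sample.
#' @param scores Numeric scores, same length as `labels`.
#' @param x Candidate cutoff.
#' @return Information gain in bits (between 0 and the parent entropy).
#' @export
information_gain <- function(labels, scores, x) {
  stopifnot(length(labels) == length(scores), length(labels) >= 1,
            is.finite(x))
  pos <- .as_positive(labels)
  parent <- .entropy_bits(c(sum(pos), sum(!pos)))
  hi <- scores > x
  n <- length(scores)
  child <- 0
  for (side in list(hi, !hi)) {
    if (!any(side)) next
    child <- child + mean(side) * .entropy_bits(c(sum(pos[side]), sum(!pos[side])))
  }
  parent - child
}

.as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  labels %in% c("positive", "true", "1", "TRUE")
}

#' Information-gain curve over a score grid
#'
#' Evaluates [information_gain()] on an even grid spanning the observed
#' score range; for small sets (fewer than 5000 samples) the midpoints
#' between consecutive observed scores are added, so that every
#' achievable split is represented exactly.
#'
#' @inheritParams information_gain
#' @param grid_resolution Number of even grid points (at least 10,
#'   default 1000).
#' @param midpoints Add observed-score midpoints for small sets.
#' @return An object of class `ig_curve`: list with `grid`, `ig`,
#'   `base_entropy`.
#' @export
ig_curve <- function(labels, scores, grid_resolution = 1000L,
                     midpoints = length(scores) < 5000L) {
  stopifnot(grid_resolution >= 10L)
  pos <- .as_positive(labels)
  base <- .entropy_bits(c(sum(pos), sum(!pos)))
  rng <- range(scores)
  grid <- seq(rng[1], rng[2], length.out = grid_resolution)
  if (midpoints) {
    s <- sort(unique(scores))
    if (length(s) > 1) grid <- c(grid, (s[-1] + s[-length(s)]) / 2)
  }
  grid <- sort(unique(grid))
  if (base == 0) {
    warning("all samples belong to one class; information gain is identically zero")
    ig <- rep(0, length(grid))
  } else {
    # O(n log n): sort once, cumulative class counts give every split's IG
    ord <- order(scores)
    s_sorted <- scores[ord]
    p_cum <- cumsum(.as_positive(labels)[ord])
    n <- length(scores)
    n_pos <- p_cum[n]
    ig <- vapply(grid, function(x) {
      k <- findInterval(x, s_sorted)   # samples with score <= x
      lo_pos <- if (k == 0) 0 else p_cum[k]
      lo <- c(lo_pos, k - lo_pos)
      hi <- c(n_pos - lo_pos, (n - k) - (n_pos - lo_pos))
      child <- (k / n) * .entropy_bits(lo) + ((n - k) / n) * .entropy_bits(hi)
      base - child
    }, numeric(1))
  }
  structure(list(grid = grid, ig = ig, base_entropy = base),
            class = "ig_curve")
}

#' @export
print.ig_curve <- function(x, ...) {
  cat("information-gain curve:", length(x$grid), "grid points, base entropy",
      round(x$base_entropy, 4), "bits, max IG", round(max(x$ig), 4), "\n")
  invisible(x)
}

#' @export
plot.ig_curve <- function(x, ...) {
  graphics::plot(x$grid, x$ig, type = "l", xlab = "scaled score",
                 ylab = "information gain (bits)", ...)
  invisible(x)
}

#' Spike candidates of an information-gain curve
#'
#' Local maxima of the curve after merging plateaus (runs of equal IG
#' count as one candidate, represented by the run's smallest score),
#' ranked by IG descending; ties rank the smaller score first. When the
#' curve has fewer than `k` local maxima, all are returned with a
#' warning; a monotone curve yields its maximal endpoint.
#'
#' @param curve An `ig_curve`.
#' @param k Number of candidates wanted (default 4).
#' @return Data frame with columns `score` and `ig`, at most `k` rows.
#' @export
find_spikes <- function(curve, k = 4L) {
  stopifnot(k >= 1L)
  ig <- curve$ig
  grid <- curve$grid
  # merge plateaus: keep one representative (smallest score) per run
  run <- c(TRUE, diff(ig) != 0)
  rep_idx <- which(run)
  rig <- ig[rep_idx]
  m <- length(rig)
  if (m == 1L) {
    peaks <- 1L
  } else {
    left <- c(Inf, rig[-m])    # endpoints count as peaks when maximal
    right <- c(rig[-1], -Inf)
    peaks <- which(rig > left & rig > right | (seq_len(m) == 1L & rig > right) |
                   (seq_len(m) == m & rig > left))
    peaks <- unique(peaks)
    if (!length(peaks)) peaks <- which.max(rig)
  }
  cand <- data.frame(score = grid[rep_idx[peaks]], ig = rig[peaks])
  cand <- cand[order(-cand$ig, cand$score), , drop = FALSE]
  if (nrow(cand) < k)
    warning("only ", nrow(cand), " spike candidate(s) found (asked for ", k, ")")
  out <- utils::head(cand, k)
  rownames(out) <- NULL
  out
}

# Admissibility of one candidate value for one (phase, predictor) slot,
# with repair of the dependent 2nd-level threshold when needed.
# Returns the repaired threshold_set or NULL when the move cannot be made
# admissible.
.apply_move <- function(ts, phase, pred, value, candidates) {
  t1t <- ts$t_true_1; t2t <- ts$t_true_2
  t1f <- ts$t_false_1; t2f <- ts$t_false_2
  repair <- function(current, lo, hi) {
    # nearest admissible candidate in (lo, hi); fall back to mid-interval
    ok <- candidates[candidates >= lo & candidates < hi]
    if (length(ok)) return(ok[which.min(abs(ok - current))])
    if (lo < hi) return((lo + hi) / 2)
    NA_real_
  }
  if (phase == "step1_true") {
    t1t[pred] <- value
    if (t2t[pred] < value) {           # dependent relaxed threshold dragged up
      t2t[pred] <- repair(t2t[pred], value, t2f[pred])
    }
  } else if (phase == "step2_true") {
    if (value < t1t[pred] || value >= t2f[pred]) return(NULL)
    t2t[pred] <- value
  } else if (phase == "step1_false") {
    t1f[pred] <- value
    if (t2f[pred] > value) {
      t2f[pred] <- repair(t2f[pred], t2t[pred] + 1e-9, value + 1e-12)
      if (!is.na(t2f[pred]) && t2f[pred] > value) t2f[pred] <- value
    }
  } else if (phase == "step2_false") {
    if (value > t1f[pred] || value <= t2t[pred]) return(NULL)
    t2f[pred] <- value
  }
  if (any(is.na(c(t1t, t2t, t1f, t2f)))) return(NULL)
  out <- try(threshold_set(ts$predictors, t1t, t1f, t2t, t2f), silent = TRUE)
  if (inherits(out, "try-error")) NULL else out
}

#' Coordinate-wise threshold tuning from information-gain spikes
#'
#' Four phases in fixed order — 1st-step true, 2nd-step true, 1st-step
#' false, 2nd-step false — each sweeping the predictors in canonical
#' order. The active cutoff steps through the spike candidates of that
#' predictor's information-gain curve (plus one grid step to either side
#' of each spike), visited in order of proximity to the current value. A
#' move is accepted when the evaluator's accuracy does not decrease;
#' after two consecutive strictly decreasing evaluations the parameter is
#' frozen. A candidate that violates the threshold ordering triggers
#' repair of the dependent 2nd-level cutoff (nearest admissible
#' candidate); irreparable moves are skipped. The returned set never
#' scores below the initial set.
#'
#' @param records Labeled, scaled records restricted to one module.
#' @param initial A valid `threshold_set` for the module.
#' @param evaluator Function `threshold_set -> accuracy`; the default
#'   scores the decision tree alone on `records`.
#' @param spike_k Spike candidates per predictor (default 4).
#' @param grid_resolution Grid size for the IG curves.
#' @param verbose Print accepted moves.
#' @return List: `thresholds` (tuned `threshold_set`), `accuracy`,
#'   `history` (data frame of evaluated moves).
#' @export
tune_thresholds <- function(records, initial, evaluator = NULL,
                            spike_k = 4L, grid_resolution = 200L,
                            verbose = FALSE) {
  validate_thresholds(initial)
  if (is.null(evaluator)) {
    evaluator <- function(ts) {
      calls <- tree_classify_matrix(records, ts)
      mean((calls == "true") == (.as_positive(records$label)))
    }
  }
  # per-predictor candidate pools: IG spikes +/- one grid step
  cands <- lapply(initial$predictors, function(p) {
    s <- records[[paste0("scaled_", p)]]
    curve <- ig_curve(records$label, s, grid_resolution = grid_resolution,
                      midpoints = FALSE)
    step <- diff(curve$grid[1:2])
    sp <- suppressWarnings(find_spikes(curve, spike_k))$score
    sort(unique(pmin(1, pmax(-1, c(sp, sp - step, sp + step)))))
  })
  names(cands) <- initial$predictors
  current <- initial
  best_acc <- evaluator(current)
  history <- list()
  slot_of <- c(step1_true = "t_true_1", step2_true = "t_true_2",
               step1_false = "t_false_1", step2_false = "t_false_2")
  for (phase in names(slot_of)) {
    for (pred in initial$predictors) {
      cur_val <- current[[slot_of[phase]]][pred]
      pool <- cands[[pred]][order(abs(cands[[pred]] - cur_val))]
      streak <- 0L
      for (val in pool) {
        if (isTRUE(all.equal(val, unname(current[[slot_of[phase]]][pred])))) next
        moved <- .apply_move(current, phase, pred, val, cands[[pred]])
        if (is.null(moved)) next
        acc <- evaluator(moved)
        history[[length(history) + 1L]] <-
          data.frame(phase = phase, predictor = pred, value = val,
                     accuracy = acc, accepted = acc >= best_acc)
        if (acc >= best_acc) {
          if (verbose && acc > best_acc)
            message(sprintf("%s/%s -> %.4f (acc %.4f)", phase, pred, val, acc))
          current <- moved
          best_acc <- acc
          streak <- 0L
        } else {
          streak <- streak + 1L
          if (streak >= 2L) break   # two consecutive decreases: freeze
        }
      }
    }
  }
  validate_thresholds(current)
  list(thresholds = current, accuracy = best_acc,
       history = if (length(history)) do.call(rbind, history)
                 else data.frame(phase = character(), predictor = character(),
                                 value = numeric(), accuracy = numeric(),
                                 accepted = logical()))
}
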