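#' Base predictor specifications
#'
#' The four base predictors whose numeric scores are the only inputs the
#' meta-predictor consumes: miRanda, miRDB, PITA and TargetScan. Each spec
#' records the predictor's native score range, its published default
#' true-prediction cutoff, and whether the score axis must be inverted so
#' that, after scaling, stronger predicted interactions always lie toward
#' -1. Only miRDB scores high-is-better and is therefore inverted.
#'
#' @format A named list with one entry per predictor, each a list with
#'   elements `id`, `native_range` (length-2 numeric, low < high),
#'   `default_cutoff` and `invert`.
#' @export
predictor_specs <- function() {
  list(
    miranda = list(id = "miranda", native_range = c(-1.364, -0.1),
                   default_cutoff = -1.0, invert = FALSE),
    mirdb = list(id = "mirdb", native_range = c(50, 100),
                 default_cutoff = 80, invert = TRUE),
    pita = list(id = "pita", native_range = c(-43.24, 21.4),
                default_cutoff = -10, invert = FALSE),
    targetscan = list(id = "targetscan", native_range = c(-9.05, 0),
                      default_cutoff = -0.36, invert = FALSE)
  )
}

#' Canonical predictor order
#'
#' miRanda, miRDB, PITA, TargetScan — the order used everywhere in the
#' package (feature vectors, threshold sets, subset definitions).
#' @return Character vector of the four predictor ids.
#' @export
predictor_ids <- function() c("miranda", "mirdb", "pita", "targetscan")

.get_spec <- function(predictor) {
  specs <- predictor_specs()
  if (is.list(predictor) && !is.null(predictor$id)) return(predictor)
  if (!is.character(predictor) || !predictor %in% names(specs))
    stop("unknown predictor: ", paste(predictor, collapse = ", "))
  specs[[predictor]]
}

#' Scale a raw predictor score onto the common (-1, 1) axis
#'
#' Applies the affine min-max map from the predictor's native range onto
#' \[-1, 1\]. For miRDB the raw score is first multiplied by -1 and the
#' native range mirrored, so that on the scaled axis every predictor scores
#' predicted interactions low (toward -1). Raw values outside the native
#' range are allowed (real predictor dumps exceed the published ranges) and
#' the result is clamped to \[-1, 1\].
#'
#' The published default cutoffs map to -0.424 (miRanda), -0.2 (miRDB),
#' 0.028 (PITA) and 0.920 (TargetScan) under this transformation.
#'
#' @param predictor Predictor id (one of `predictor_ids()`) or a spec list.
#' @param raw Numeric vector of raw scores; `NA` passes through as `NA`.
#' @param clamp Clamp out-of-range results to \[-1, 1\] (default `TRUE`).
#' @return Numeric vector of scaled scores.
#' @export
#' @examples
#' scale_score("miranda", -1.0)   # -0.424
#' scale_score("mirdb", 80)       # -0.2
scale_score <- function(predictor, raw, clamp = TRUE) {
  spec <- .get_spec(predictor)
  lo <- spec$native_range[1]
  hi <- spec$native_range[2]
  if (!is.numeric(c(lo, hi)) || lo >= hi)
    stop("degenerate native range for predictor ", spec$id)
  x <- as.numeric(raw)
  if (isTRUE(spec$invert)) {
    x <- -x
    r <- c(-hi, -lo)
  } else {
    r <- c(lo, hi)
  }
  out <- 2 * (x - r[1]) / (r[2] - r[1]) - 1
  if (clamp) out <- pmin(1, pmax(-1, out))
  out
}

#' Invert the scaling map
#'
#' Recovers the raw score from a scaled score; exact inverse of
#' [scale_score()] for raw values inside the native range.
#'
#' @inheritParams scale_score
#' @param scaled Numeric vector of scaled scores in \[-1, 1\].
#' @return Numeric vector of raw scores in the predictor's native units.
#' @export
unscale_score <- function(predictor, scaled) {
  spec <- .get_spec(predictor)
  lo <- spec$native_range[1]
  hi <- spec$native_range[2]
  if (isTRUE(spec$invert)) r <- c(-hi, -lo) else r <- c(lo, hi)
  x <- (as.numeric(scaled) + 1) / 2 * (r[2] - r[1]) + r[1]
  if (isTRUE(spec$invert)) x <- -x
  x
}

#' Scaled default cutoffs of the four base predictors
#'
#' Default true-prediction cutoffs after scaling: calls below these values
#' on the scaled axis count as predicted interactions.
#' @return Named numeric vector in canonical predictor order.
#' @export
scaled_default_cutoffs <- function() {
  specs <- predictor_specs()
  vapply(predictor_ids(), function(p)
    scale_score(p, specs[[p]]$default_cutoff), numeric(1))
}

# name -> predictor combination, canonical order within each combination
.subset_table <- list(
  "D4"   = c("miranda", "mirdb", "pita", "targetscan"),
  "D3-1" = c("miranda", "mirdb", "pita"),
  "D3-2" = c("miranda", "mirdb", "targetscan"),
  "D3-3" = c("miranda", "pita", "targetscan"),
  "D3-4" = c("mirdb", "pita", "targetscan"),
  "D2-1" = c("miranda", "mirdb"),
  "D2-2" = c("miranda", "pita"),
  "D2-3" = c("miranda", "targetscan"),
  "D2-4" = c("mirdb", "pita"),
  "D2-5" = c("mirdb", "targetscan"),
  "D2-6" = c("pita", "targetscan")
)

#' The eleven predictor-availability subsets
#'
#' Maps subset names (D4, D3-1..D3-4, D2-1..D2-6) to the predictor
#' combinations whose scores define them. Records with fewer than two
#' scored predictors belong to no subset and are not classified.
#'
#' @return Named list of character vectors (predictor ids per subset).
#' @export
subset_keys <- function() .subset_table

#' Predictors of one subset
#' @param name Subset name, e.g. `"D2-1"`.
#' @return Character vector of predictor ids in canonical order.
#' @export
subset_predictors <- function(name) {
  if (!name %in% names(.subset_table)) stop("unknown subset: ", name)
  .subset_table[[name]]
}

#' Assign a predictor-availability mask to its subset
#'
#' @param mask Logical vector of length 4 over the canonical predictor
#'   order (or a character vector of present predictor ids).
#' @return The subset name, or `NA_character_` when fewer than two scores
#'   are present.
#' @export
#' @examples
#' assign_subset(c(TRUE, TRUE, FALSE, FALSE))  # "D2-1"
assign_subset <- function(mask) {
  if (is.character(mask)) {
    present <- intersect(predictor_ids(), mask)
  } else {
    stopifnot(length(mask) == 4L)
    present <- predictor_ids()[as.logical(mask)]
  }
  if (length(present) < 2L) return(NA_character_)
  for (nm in names(.subset_table))
    if (identical(.subset_table[[nm]], present)) return(nm)
  NA_character_  # unreachable: every >=2 combination is listed
}
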