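#' Read a tab-separated predictor score table
#'
#' Expected columns: `mirna_id`, `gene_id` and one column per base
#' predictor (`miranda`, `mirdb`, `pita`, `targetscan`); any subset of the
#' predictor columns may be present. An empty cell, `NA`, `-` or `null`
#' marks an unscored prediction and becomes `NA`. Any other non-numeric
#' cell is an error naming the offending line.
#'
#' @param path Path to a TSV file with a header line.
#' @param missing_markers Strings treated as "no score".
#' @return A data frame with id columns and one numeric raw-score column
#'   per predictor present in the file (class `"metadann_records"`).
#' @export
read_score_table <- function(path,
                             missing_markers = c("", "NA", "-", "null")) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "")
  need <- c("mirna_id", "gene_id")
  if (!all(need %in% names(tab)))
    stop("score table must have columns mirna_id and gene_id")
  score_cols <- setdiff(names(tab), need)
  unknown <- setdiff(score_cols, predictor_ids())
  if (length(unknown))
    stop("unknown predictor column(s): ", paste(unknown, collapse = ", "))
  for (p in score_cols) {
    cell <- trimws(tab[[p]])
    miss <- cell %in% missing_markers
    num <- suppressWarnings(as.numeric(cell))
    bad <- !miss & is.na(num)
    if (any(bad))
      stop(sprintf("malformed numeric cell '%s' in column %s at line %d of %s",
                   cell[which(bad)[1]], p, which(bad)[1] + 1L, path))
    num[miss] <- NA_real_
    tab[[p]] <- num
  }
  out <- tab[, c(need, intersect(predictor_ids(), score_cols))]
  class(out) <- c("metadann_records", "data.frame")
  out
}

#' Read a positive-pair list
#'
#' Tab-separated export of experimentally validated miRNA:mRNA
#' interactions: columns `mirna_id`, `gene_id`. Callers combining several
#' databases simply concatenate the files first; membership in any one
#' source suffices for a positive label.
#'
#' @param path Path to a TSV file with a header line.
#' @return A data frame with columns `mirna_id`, `gene_id`.
#' @export
read_positive_pairs <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "")
  if (!all(c("mirna_id", "gene_id") %in% names(tab)))
    stop("positive-pair table must have columns mirna_id and gene_id")
  tab[, c("mirna_id", "gene_id")]
}

#' Write records to TSV
#'
#' @param records A records data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

.raw_cols <- function(records) intersect(predictor_ids(), names(records))

.scaled_col <- function(p) paste0("scaled_", p)

#' Add scaled-score columns
#'
#' For each raw predictor column present, adds a `scaled_<predictor>`
#' column with the score mapped onto \[-1, 1\] via [scale_score()];
#' missing raw scores stay missing.
#'
#' @param records Records data frame with raw score columns.
#' @return The records with scaled columns added.
#' @export
scale_records <- function(records) {
  for (p in .raw_cols(records))
    records[[.scaled_col(p)]] <- scale_score(p, records[[p]])
  records
}

#' Availability mask of each record
#'
#' @param records Records data frame.
#' @return Logical matrix, one row per record, columns in canonical
#'   predictor order; `TRUE` where a raw score is present.
#' @export
record_masks <- function(records) {
  m <- sapply(predictor_ids(), function(p) {
    if (p %in% names(records)) !is.na(records[[p]]) else rep(FALSE, nrow(records))
  })
  m <- matrix(as.logical(m), nrow = nrow(records),
              dimnames = list(NULL, predictor_ids()))
  m
}

#' Label records against a positive-pair list
#'
#' A record is positive iff its (miRNA, gene) pair appears in the positive
#' list, otherwise negative.
#'
#' @param records Records data frame.
#' @param positive_pairs Data frame with columns `mirna_id`, `gene_id`.
#' @return Records with a `label` column (`"positive"`/`"negative"`).
#' @export
label_records <- function(records, positive_pairs) {
  key <- paste(records$mirna_id, records$gene_id, sep = "\r")
  pos <- if (is.null(positive_pairs) || nrow(positive_pairs) == 0) character(0)
         else paste(positive_pairs$mirna_id, positive_pairs$gene_id, sep = "\r")
  records$label <- ifelse(key %in% pos, "positive", "negative")
  records
}

#' Assign each record to its availability subset
#'
#' @param records Records data frame.
#' @return Records with a `subset` column (`NA` for records with fewer
#'   than two scores, which the meta-predictor does not classify).
#' @export
assign_subsets <- function(records) {
  m <- record_masks(records)
  records$subset <- apply(m, 1, assign_subset)
  records
}

#' Remove near-duplicate records
#'
#' Two records with identical availability masks are duplicates when every
#' shared scaled score differs by less than `tolerance` — by default 0.04,
#' i.e. 2\% of the width of the scaled \[-1, 1\] axis. Of each duplicate
#' pair one member is removed at random under `seed`; the survivors
#' contain no duplicate pair, so the operation is idempotent.
#'
#' @param records Scaled records data frame.
#' @param tolerance Per-predictor absolute difference below which two
#'   shared scaled scores count as equal (default 0.04).
#' @param seed Integer seed for the random choice of which member to drop.
#' @return Deduplicated records.
#' @export
deduplicate <- function(records, tolerance = 0.04, seed = 1L) {
  sc <- paste0("scaled_", .raw_cols(records))
  sc <- intersect(sc, names(records))
  if (!length(sc)) stop("deduplicate needs scaled score columns; run scale_records first")
  m <- record_masks(records)
  grp <- apply(m, 1, paste, collapse = "")
  keep <- logical(nrow(records))
  set.seed(seed)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    cols <- sc[m[idx[1], intersect(predictor_ids(), sub("^scaled_", "", sc))]]
    if (!length(cols)) { keep[idx] <- TRUE; next }
    ord <- idx[sample.int(length(idx))]  # random order decides which member survives
    X <- as.matrix(records[ord, cols, drop = FALSE])
    kept <- integer(0)
    for (i in seq_along(ord)) {
      dup <- FALSE
      if (length(kept)) {
        d <- abs(X[kept, , drop = FALSE] -
                 matrix(X[i, ], nrow = length(kept), ncol = ncol(X), byrow = TRUE))
        dup <- any(apply(d, 1, max) < tolerance)
      }
      if (!dup) kept <- c(kept, i)
    }
    keep[ord[kept]] <- TRUE
  }
  records[keep, , drop = FALSE]
}

#' Prepare a raw score table for training
#'
#' Convenience wrapper: scale, label, assign subsets, deduplicate.
#'
#' @inheritParams deduplicate
#' @inheritParams label_records
#' @return Prepared records data frame.
#' @export
prepare_records <- function(records, positive_pairs, tolerance = 0.04,
                            seed = 1L) {
  records <- scale_records(records)
  records <- label_records(records, positive_pairs)
  records <- assign_subsets(records)
  deduplicate(records, tolerance = tolerance, seed = seed)
}

#' Stratified train/test split
#'
#' Random partition stratified by label; 20\% of samples form the
#' independent test set by default.
#'
#' @param records Labeled records data frame.
#' @param test_fraction Fraction held out (strictly between 0 and 1).
#' @param seed Integer seed.
#' @return List with elements `train` and `test`.
#' @export
split_train_test <- function(records, test_fraction = 0.2, seed = 1L) {
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("test_fraction must be strictly between 0 and 1")
  if (is.null(records$label)) stop("records must be labeled")
  set.seed(seed)
  n <- nrow(records)
  test_idx <- integer(0)
  tab <- table(records$label)
  if (any(tab < 2)) {
    warning("a class has fewer than 2 members; falling back to a non-stratified split")
    test_idx <- sample(n, round(test_fraction * n))
  } else {
    for (cl in names(tab)) {
      idx <- which(records$label == cl)
      test_idx <- c(test_idx, sample(idx, round(test_fraction * length(idx))))
    }
  }
  list(train = records[setdiff(seq_len(n), test_idx), , drop = FALSE],
       test = records[sort(test_idx), , drop = FALSE])
}

#' Stratified cross-validation folds
#'
#' Five folds when the set has at least `size_threshold` records, three
#' otherwise; folds are stratified by label and of near-equal size.
#'
#' @param records Labeled records data frame.
#' @param seed Integer seed.
#' @param size_threshold Minimum size for five-fold splitting (default 1000).
#' @return Integer vector of fold ids (1..k), one per record.
#' @export
make_cv_folds <- function(records, seed = 1L, size_threshold = 1000L) {
  n <- nrow(records)
  k <- if (n >= size_threshold) 5L else 3L
  if (n < k) stop("fewer records (", n, ") than folds (", k, ")")
  if (is.null(records$label)) stop("records must be labeled")
  set.seed(seed)
  fold <- integer(n)
  for (cl in unique(records$label)) {
    idx <- which(records$label == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
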