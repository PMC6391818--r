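#' Fit the meta-predictor
#'
#' The main fitting function. Records are scaled, routed into the eleven
#' predictor-availability subsets, and one classification module is
#' trained per subset that has both classes. Three variants exist:
#' `"c1"`, the dual-threshold two-step significance-voting decision tree
#' alone (thresholds tuned from information-gain spikes); `"c2"`, a
#' neural network on the bare scaled scores; and `"dann"` (default), the
#' full model — tuned tree thresholds, then a network on the encoded
#' feature vector (scores plus the six voting quantities).
#'
#' Per subset, 20\% of samples are held out as an independent test set
#' and the remainder is used for threshold tuning and stratified 3- or
#' 5-fold cross-validation of the network; the per-fold models and
#' metrics are retained so cross-validated performance can be reported as
#' mean and s.d.
#'
#' @param records Labeled records data frame (raw scores suffice; scaled
#'   columns are added when absent).
#' @param variant `"dann"`, `"c1"` or `"c2"`.
#' @param tune Tune thresholds by [tune_thresholds()] (default `TRUE`);
#'   otherwise the generic [default_thresholds()] are used.
#' @param thresholds Optional named list of `threshold_set`s (by subset
#'   name) overriding tuning.
#' @param test_fraction Held-out fraction per subset (default 0.2).
#' @param size_threshold Subset size at or above which five CV folds are
#'   used instead of three (default 1000).
#' @param min_subset Smallest subset (with both classes) that gets a
#'   module (default 30).
#' @param epochs,learning_rate,patience Network training controls, see
#'   [ann_config()].
#' @param aggregate Significance-distance aggregation, `"euclidean"`
#'   (default) or `"sum"`.
#' @param seed Integer seed governing splits, tuning and training.
#' @return An object of class `metadann`; see [predict.metadann()],
#'   [summary.metadann()], [coef.metadann()].
#' @export
#' @examples
#' sim <- simulate_interactions(sim_config(n_samples = 600, seed = 7))
#' fit <- metadann(sim$truth, variant = "c1")
#' summary(fit)
metadann <- function(records, variant = c("dann", "c1", "c2"),
                     tune = TRUE, thresholds = NULL, test_fraction = 0.2,
                     size_threshold = 1000L, min_subset = 30L,
                     epochs = 300L, learning_rate = 0.05, patience = 50L,
                     aggregate = c("euclidean", "sum"), seed = 1L) {
  variant <- match.arg(variant)
  aggregate <- match.arg(aggregate)
  cl <- match.call()
  if (is.null(records$label)) stop("records must be labeled")
  if (!any(grepl("^scaled_", names(records)))) records <- scale_records(records)
  if (is.null(records$subset)) records <- assign_subsets(records)
  modules <- list()
  for (key in names(subset_keys())) {
    sub <- records[!is.na(records$subset) & records$subset == key, ,
                   drop = FALSE]
    if (nrow(sub) < min_subset || length(unique(sub$label)) < 2L) next
    modules[[key]] <- train_module(
      sub, key, variant = variant, tune = tune,
      thresholds = thresholds[[key]], test_fraction = test_fraction,
      size_threshold = size_threshold, epochs = epochs,
      learning_rate = learning_rate, patience = patience,
      aggregate = aggregate, seed = seed)
  }
  if (!length(modules))
    stop("no subset had enough labeled records to train a module")
  structure(list(modules = modules, variant = variant,
                 aggregate = aggregate, seed = seed, call = cl),
            class = "metadann")
}

#' Train one availability-specific module
#'
#' @param records Labeled, scaled records of a single availability
#'   pattern.
#' @param key Subset name (e.g. `"D2-1"`); inferred from the records'
#'   `subset` column when missing.
#' @inheritParams metadann
#' @return A list of class `metadann_module`: subset key, predictors,
#'   `thresholds`, `ann` (final network or `NULL` for `"c1"`), `cv`
#'   (per-fold metrics and models), `test` (held-out records and
#'   metrics), sizes.
#' @export
train_module <- function(records, key = NULL,
                         variant = c("dann", "c1", "c2"), tune = TRUE,
                         thresholds = NULL, test_fraction = 0.2,
                         size_threshold = 1000L, epochs = 300L,
                         learning_rate = 0.05, patience = 50L,
                         aggregate = c("euclidean", "sum"), seed = 1L) {
  variant <- match.arg(variant)
  aggregate <- match.arg(aggregate)
  if (is.null(key)) key <- records$subset[1]
  preds <- subset_predictors(key)
  if (length(unique(records$label)) < 2L)
    stop("module ", key, ": training data contains a single class")
  split <- split_train_test(records, test_fraction, seed = seed)
  train <- split$train
  ts <- thresholds
  if (is.null(ts)) {
    ts <- default_thresholds(preds)
    if (tune && variant != "c2")
      ts <- tune_thresholds(train, ts)$thresholds
  }
  features <- function(recs) {
    switch(variant,
           c2 = {
             M <- as.matrix(recs[, paste0("scaled_", preds), drop = FALSE])
             colnames(M) <- preds
             M
           },
           encode_matrix(recs, ts, aggregate))
  }
  mod <- list(key = key, predictors = preds, variant = variant,
              thresholds = ts, aggregate = aggregate, ann = NULL,
              cv = NULL, test = NULL,
              n_train = nrow(train), n_test = nrow(split$test))
  class(mod) <- "metadann_module"
  if (variant != "c1") {
    fold <- make_cv_folds(train, seed = seed, size_threshold = size_threshold)
    input_dim <- length(preds) + if (variant == "dann") 6L else 0L
    fold_models <- list(); fold_metrics <- list()
    for (k in sort(unique(fold))) {
      tr <- train[fold != k, , drop = FALSE]
      va <- train[fold == k, , drop = FALSE]
      cfg <- ann_config(input_dim, epochs = epochs,
                        learning_rate = learning_rate, patience = patience,
                        seed = seed + k)
      m <- ann_train(ann_init(cfg), features(tr), tr$label,
                     validation = list(X = features(va), labels = va$label))
      p <- ann_predict(m, features(va))
      fold_models[[k]] <- m
      fold_metrics[[k]] <- classification_metrics(p$label, va$label)
    }
    cvm <- do.call(rbind, fold_metrics)
    mod$cv <- list(folds = fold, models = fold_models,
                   metrics = as.data.frame(cvm),
                   mean = colMeans(cvm), sd = apply(cvm, 2, stats::sd))
    cfg <- ann_config(input_dim, epochs = epochs,
                      learning_rate = learning_rate, patience = patience,
                      seed = seed)
    mod$ann <- ann_train(ann_init(cfg), features(train), train$label)
  } else {
    # the tree needs no network; cross-validate the tree itself
    fold <- make_cv_folds(train, seed = seed, size_threshold = size_threshold)
    fold_metrics <- lapply(sort(unique(fold)), function(k) {
      va <- train[fold == k, , drop = FALSE]
      calls <- tree_classify_matrix(va, ts, aggregate)
      classification_metrics(calls, va$label)
    })
    cvm <- do.call(rbind, fold_metrics)
    mod$cv <- list(folds = fold, models = NULL,
                   metrics = as.data.frame(cvm),
                   mean = colMeans(cvm), sd = apply(cvm, 2, stats::sd))
  }
  if (nrow(split$test) && length(unique(split$test$label)) == 2L) {
    p <- predict_module(mod, split$test)
    mod$test <- list(records = split$test,
                     metrics = classification_metrics(p$label,
                                                      split$test$label))
  }
  mod
}

#' Classify records with one module
#'
#' Projects the records onto the module's predictors (their scaled
#' columns must be complete) and applies the module's variant.
#'
#' @param module A `metadann_module`.
#' @param records Scaled records data frame.
#' @return Data frame with `label` (`"positive"`/`"negative"`) and
#'   `score` (network p_true; `NA` for the tree-only variant).
#' @export
predict_module <- function(module, records) {
  if (module$variant == "c1") {
    calls <- tree_classify_matrix(records, module$thresholds,
                                  module$aggregate)
    return(data.frame(label = ifelse(calls == "true", "positive", "negative"),
                      score = NA_real_))
  }
  X <- if (module$variant == "c2") {
    M <- as.matrix(records[, paste0("scaled_", module$predictors),
                           drop = FALSE])
    colnames(M) <- module$predictors
    M
  } else {
    encode_matrix(records, module$thresholds, module$aggregate)
  }
  ann_predict(module$ann, X)
}

#' Route a record to its module
#'
#' @param object A fitted `metadann` object.
#' @param mask Logical availability mask (length 4, canonical order) or
#'   character vector of present predictor ids.
#' @return The matching `metadann_module`.
#' @export
route <- function(object, mask) {
  key <- assign_subset(mask)
  if (is.na(key))
    stop("record with fewer than two scores cannot be routed")
  mod <- object$modules[[key]]
  if (is.null(mod))
    stop("no module was trained for subset ", key)
  mod
}

#' Predict miRNA:mRNA interactions with a fitted meta-predictor
#'
#' Scales raw scores when needed, routes every record to the module
#' matching its availability pattern, and returns the module's call.
#'
#' @param object A `metadann` fit.
#' @param newdata Records data frame (raw or scaled scores).
#' @param ... Unused.
#' @return Data frame with `label`, `score` and `module` per record;
#'   records that cannot be routed (fewer than two scores, or no module
#'   trained for their pattern) get `NA`s.
#' @export
predict.metadann <- function(object, newdata, ...) {
  if (!any(grepl("^scaled_", names(newdata)))) newdata <- scale_records(newdata)
  if (is.null(newdata$subset)) newdata <- assign_subsets(newdata)
  out <- data.frame(label = rep(NA_character_, nrow(newdata)),
                    score = NA_real_, module = NA_character_)
  for (key in unique(stats::na.omit(newdata$subset))) {
    mod <- object$modules[[key]]
    if (is.null(mod)) next
    idx <- which(!is.na(newdata$subset) & newdata$subset == key)
    p <- predict_module(mod, newdata[idx, , drop = FALSE])
    out$label[idx] <- p$label
    out$score[idx] <- p$score
    out$module[idx] <- key
  }
  if (anyNA(out$label))
    warning(sum(is.na(out$label)), " record(s) could not be routed to a module")
  out
}

#' @export
print.metadann <- function(x, ...) {
  cat("meta-predictor (variant ", x$variant, ") with ",
      length(x$modules), " availability module(s): ",
      paste(names(x$modules), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Summarize a fitted meta-predictor
#'
#' @param object A `metadann` fit.
#' @param ... Unused.
#' @return Data frame, one row per module: sizes and cross-validated
#'   metrics (mean and s.d.) plus held-out test accuracy.
#' @export
summary.metadann <- function(object, ...) {
  rows <- lapply(object$modules, function(m) {
    data.frame(module = m$key, n_train = m$n_train, n_test = m$n_test,
               cv_acc = m$cv$mean["acc"], cv_acc_sd = m$cv$sd["acc"],
               cv_sens = m$cv$mean["sens"], cv_spec = m$cv$mean["spec"],
               cv_f1 = m$cv$mean["f1"], cv_mcc = m$cv$mean["mcc"],
               test_acc = if (is.null(m$test)) NA_real_
                          else m$test$metrics["acc"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary.metadann", "data.frame")
  out
}

#' @export
print.summary.metadann <- function(x, ...) {
  y <- x
  class(y) <- "data.frame"
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, 3)
  print(y)
  invisible(x)
}

#' Module thresholds of a fit
#'
#' @param object A `metadann` fit.
#' @param ... Unused.
#' @return Data frame of tuned cutoffs, one row per module and predictor.
#' @export
coef.metadann <- function(object, ...) {
  rows <- lapply(object$modules, function(m) {
    ts <- m$thresholds
    data.frame(module = m$key, predictor = ts$predictors,
               t_true_1 = unname(ts$t_true_1), t_true_2 = unname(ts$t_true_2),
               t_false_2 = unname(ts$t_false_2),
               t_false_1 = unname(ts$t_false_1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot cross-validated accuracy per module
#'
#' Bar chart of CV accuracy with one-s.d. whiskers.
#'
#' @param x A `metadann` fit.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.metadann <- function(x, ...) {
  s <- summary(x)
  bp <- graphics::barplot(s$cv_acc, names.arg = s$module, ylim = c(0, 1.05),
                          ylab = "cross-validated accuracy", ...)
  graphics::arrows(bp, pmax(0, s$cv_acc - s$cv_acc_sd),
                   bp, pmin(1, s$cv_acc + s$cv_acc_sd),
                   angle = 90, code = 3, length = 0.04)
  invisible(x)
}

#' Evaluate a module on a foreign subset
#'
#' Cross-subset evaluation: records of another availability pattern whose
#' predictor set contains the module's are projected onto the module's
#' predictors and scored.
#'
#' @param module A `metadann_module`.
#' @param records Labeled, scaled records of the foreign subset.
#' @return Named metrics vector as from [classification_metrics()].
#' @export
cross_subset_evaluate <- function(module, records) {
  if (is.null(records$subset)) records <- assign_subsets(records)
  foreign <- unique(stats::na.omit(records$subset))
  for (f in foreign)
    if (!all(module$predictors %in% subset_predictors(f)))
      stop("subset ", f, " lacks scores for module ", module$key)
  p <- predict_module(module, records)
  classification_metrics(p$label, records$label)
}

#' Merge associated subsets and retrain a module
#'
#' Every associated subset whose predictor set contains the target's is
#' projected onto the target's predictors, concatenated with the target
#' subset, re-deduplicated, and the target module is retrained on the
#' merged set. Merging toward a larger predictor set (which would drop
#' scores) is an error.
#'
#' @param records Prepared records (scaled, labeled, with `subset`).
#' @param target Target subset name (e.g. `"D3-1"`).
#' @param sources Names of the associated subsets to merge in.
#' @param ... Passed to [train_module()].
#' @param tolerance Dedup tolerance on the merged set (default 0.04).
#' @param seed Seed for dedup and retraining.
#' @return List: `module` (retrained on the merged set), `merged`
#'   (the merged records), `metrics_by_origin` (held-out metrics split by
#'   originating subset).
#' @export
merge_and_retrain <- function(records, target, sources, ...,
                              tolerance = 0.04, seed = 1L) {
  tpreds <- subset_predictors(target)
  for (s in sources)
    if (!all(tpreds %in% subset_predictors(s)))
      stop("cannot merge ", s, " into ", target,
           ": missing scores for ", paste(setdiff(tpreds, subset_predictors(s)),
                                          collapse = ", "))
  pool <- records[!is.na(records$subset) &
                  records$subset %in% unique(c(target, sources)), ,
                  drop = FALSE]
  pool$origin <- pool$subset
  # project onto the target predictors: blank all other score columns
  drop <- setdiff(predictor_ids(), tpreds)
  for (p in drop) {
    if (p %in% names(pool)) pool[[p]] <- NA_real_
    sc <- paste0("scaled_", p)
    if (sc %in% names(pool)) pool[[sc]] <- NA_real_
  }
  pool <- assign_subsets(pool)
  merged <- deduplicate(pool, tolerance = tolerance, seed = seed)
  module <- train_module(merged, key = target, seed = seed, ...)
  by_origin <- NULL
  if (!is.null(module$test)) {
    te <- module$test$records
    by_origin <- do.call(rbind, lapply(split(seq_len(nrow(te)), te$origin),
      function(idx) {
        p <- predict_module(module, te[idx, , drop = FALSE])
        as.data.frame(t(classification_metrics(p$label, te$label[idx])))
      }))
  }
  list(module = module, merged = merged, metrics_by_origin = by_origin)
}
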