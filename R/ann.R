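#' Configuration of the module network
#'
#' A fully connected net with two hidden layers of 10 and 20 tanh nodes
#' and a 2-node tanh output layer whose activations are exponentially
#' normalized to a probability pair (positive, negative). Input width is
#' the encoded feature length: 10, 9 or 8 for 4-, 3- or 2-predictor
#' modules (or the bare score width 2-4 for the scores-only variant).
#'
#' @param input_dim Number of input nodes.
#' @param hidden Hidden layer sizes (default `c(10, 20)`).
#' @param learning_rate Gradient-descent step size (default 0.05).
#' @param momentum Classical momentum coefficient (default 0.9).
#' @param epochs Maximum training epochs (default 500).
#' @param batch_size Mini-batch size; `NULL` (default) trains full-batch.
#' @param class_weighting `"inverse_frequency"` (default) weights each
#'   class by the inverse of its frequency, or `"none"`.
#' @param patience Early-stopping patience on validation accuracy, in
#'   epochs (default 50); ignored without a validation set.
#' @param seed Integer seed for weight initialization and batch order.
#' @return A list of class `ann_config`.
#' @export
ann_config <- function(input_dim, hidden = c(10L, 20L),
                       learning_rate = 0.05, momentum = 0.9,
                       epochs = 500L, batch_size = NULL,
                       class_weighting = c("inverse_frequency", "none"),
                       patience = 50L, seed = 1L) {
  if (!is.numeric(input_dim) || length(input_dim) != 1L || input_dim < 1)
    stop("input_dim must be a positive integer")
  class_weighting <- match.arg(class_weighting)
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden), output_dim = 2L,
                 activation = "tanh", learning_rate = learning_rate,
                 momentum = momentum, epochs = as.integer(epochs),
                 batch_size = if (is.null(batch_size)) NULL else as.integer(batch_size),
                 class_weighting = class_weighting,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "ann_config")
}

#' Initialize a network
#'
#' Weights drawn uniformly on a symmetric Glorot-style interval
#' \eqn{\pm\sqrt{6/(fan_{in}+fan_{out})}}, biases zero; deterministic
#' under the config seed.
#'
#' @param config An `ann_config`.
#' @return An `ann_model`: list of weight matrices `W` (one per layer),
#'   bias vectors `b`, the config, and an empty `train_report`.
#' @export
ann_init <- function(config) {
  dims <- c(config$input_dim, config$hidden, config$output_dim)
  set.seed(config$seed)
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1L)) {
    lim <- sqrt(6 / (dims[l] + dims[l + 1L]))
    W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1L], -lim, lim),
                     nrow = dims[l], ncol = dims[l + 1L])
    b[[l]] <- rep(0, dims[l + 1L])
  }
  structure(list(W = W, b = b, config = config,
                 train_report = data.frame(epoch = integer(), loss = numeric(),
                                           val_accuracy = numeric())),
            class = "ann_model")
}

#' @export
print.ann_model <- function(x, ...) {
  dims <- c(x$config$input_dim, x$config$hidden, x$config$output_dim)
  cat("feedforward tanh network", paste(dims, collapse = "-"),
      "with exponential-normalized output\n")
  if (nrow(x$train_report))
    cat("trained", max(x$train_report$epoch), "epochs; final loss",
        signif(utils::tail(x$train_report$loss, 1), 4), "\n")
  invisible(x)
}

# forward pass keeping intermediates for backprop
.ann_forward_full <- function(model, X) {
  A <- list(X)
  L <- length(model$W)
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% model$W[[l]] +
      matrix(model$b[[l]], nrow(A[[l]]), length(model$b[[l]]), byrow = TRUE)
    A[[l + 1L]] <- tanh(Z)   # every node, output layer included, is tanh
  }
  O <- A[[L + 1L]]
  E <- exp(O)
  P <- E / rowSums(E)        # exponential normalization of the two outputs
  list(A = A, O = O, P = P)
}

#' Forward pass
#'
#' All nodes, the two output nodes included, use the hyperbolic tangent;
#' the two output activations are then exponentially normalized so the
#' returned pair (p_true, p_false) lies in (0,1) and sums to one.
#'
#' @param model An `ann_model`.
#' @param x Numeric feature vector of length `input_dim`, or a matrix
#'   with one row per sample.
#' @return Named vector `c(p_true, p_false)`, or a two-column matrix for
#'   matrix input.
#' @export
ann_forward <- function(model, x) {
  if (is.null(dim(x))) {
    if (length(x) != model$config$input_dim)
      stop("feature length ", length(x), " != input_dim ",
           model$config$input_dim)
    P <- .ann_forward_full(model, matrix(x, nrow = 1))$P
    return(c(p_true = P[1, 1], p_false = P[1, 2]))
  }
  if (ncol(x) != model$config$input_dim)
    stop("feature width ", ncol(x), " != input_dim ", model$config$input_dim)
  P <- .ann_forward_full(model, x)$P
  colnames(P) <- c("p_true", "p_false")
  P
}

# gradients of mean weighted cross-entropy wrt all parameters
.ann_gradients <- function(model, X, Y, w) {
  fw <- .ann_forward_full(model, X)
  L <- length(model$W)
  n <- nrow(X)
  # dL/dO = (P - Y) * w / sum(w) (softmax + cross-entropy), then through tanh
  delta <- (fw$P - Y) * (w / sum(w)) * (1 - fw$O^2)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fw$A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) delta <- (delta %*% t(model$W[[l]])) * (1 - fw$A[[l]]^2)
  }
  loss <- -sum(w * rowSums(Y * log(pmax(fw$P, 1e-12)))) / sum(w)
  list(gW = gW, gb = gb, loss = loss)
}

.label_matrix <- function(labels) {
  pos <- .as_positive(labels)
  cbind(as.numeric(pos), as.numeric(!pos))  # positive -> [1,0], negative -> [0,1]
}

#' Train a network by backpropagation
#'
#' Minimizes cross-entropy between the exponential-normalized outputs and
#' the one-hot labels ([1,0] positive, [0,1] negative) by gradient
#' descent with momentum, full-batch by default. Inverse-frequency class
#' weights counter the strong class imbalance of interaction data. With a
#' validation set, training stops early when validation accuracy has not
#' improved for `patience` epochs and the best-scoring weights are
#' restored. Deterministic under the config seed.
#'
#' @param model An initialized `ann_model`.
#' @param X Feature matrix (rows = samples).
#' @param labels Labels (`"positive"`/`"negative"` or logical).
#' @param validation Optional list `list(X =, labels =)` for early
#'   stopping.
#' @return The trained `ann_model`, with `train_report` filled in.
#' @export
ann_train <- function(model, X, labels, validation = NULL) {
  cfg <- model$config
  X <- as.matrix(X)
  if (ncol(X) != cfg$input_dim) stop("feature width != input_dim")
  pos <- .as_positive(labels)
  if (length(unique(pos)) < 2L)
    stop("training set contains a single class")
  Y <- .label_matrix(labels)
  w <- rep(1, nrow(X))
  if (cfg$class_weighting == "inverse_frequency") {
    f <- mean(pos)
    w[pos] <- 1 / f
    w[!pos] <- 1 / (1 - f)
  }
  if (cfg$epochs == 0L) return(model)
  vW <- lapply(model$W, function(m) m * 0)
  vb <- lapply(model$b, function(v) v * 0)
  report <- vector("list", cfg$epochs)
  best <- list(acc = -Inf, W = model$W, b = model$b, since = 0L)
  set.seed(cfg$seed + 1L)
  n <- nrow(X)
  for (ep in seq_len(cfg$epochs)) {
    idx_list <- if (is.null(cfg$batch_size)) list(seq_len(n))
                else split(sample(n), ceiling(seq_len(n) / cfg$batch_size))
    loss <- 0
    for (idx in idx_list) {
      g <- .ann_gradients(model, X[idx, , drop = FALSE],
                          Y[idx, , drop = FALSE], w[idx])
      for (l in seq_along(model$W)) {
        vW[[l]] <- cfg$momentum * vW[[l]] - cfg$learning_rate * g$gW[[l]]
        vb[[l]] <- cfg$momentum * vb[[l]] - cfg$learning_rate * g$gb[[l]]
        model$W[[l]] <- model$W[[l]] + vW[[l]]
        model$b[[l]] <- model$b[[l]] + vb[[l]]
      }
      loss <- loss + g$loss * length(idx) / n
    }
    val_acc <- NA_real_
    if (!is.null(validation)) {
      P <- ann_forward(model, as.matrix(validation$X))
      val_acc <- mean((P[, 1] > 0.5) == .as_positive(validation$labels))
      if (val_acc > best$acc) {
        best <- list(acc = val_acc, W = model$W, b = model$b, since = 0L)
      } else {
        best$since <- best$since + 1L
      }
    }
    report[[ep]] <- data.frame(epoch = ep, loss = loss, val_accuracy = val_acc)
    if (!is.null(validation) && best$since >= cfg$patience) break
  }
  if (!is.null(validation) && is.finite(best$acc)) {
    model$W <- best$W
    model$b <- best$b
  }
  model$train_report <- do.call(rbind, report[!vapply(report, is.null, logical(1))])
  model
}

#' Predict with a trained network
#'
#' @param model A trained `ann_model`.
#' @param x Feature vector or matrix.
#' @return For a vector: list `label` (`"positive"`/`"negative"`) and
#'   `score` (= p_true). For a matrix: data frame of labels and scores.
#'   A score of exactly 0.5 is called negative.
#' @export
ann_predict <- function(model, x) {
  P <- ann_forward(model, x)
  if (is.null(dim(P)))
    return(list(label = if (P["p_true"] > 0.5) "positive" else "negative",
                score = unname(P["p_true"])))
  data.frame(label = ifelse(P[, 1] > 0.5, "positive", "negative"),
             score = P[, 1])
}

#' Serialize / restore a network as JSON
#'
#' Full double precision; a round trip reproduces forward outputs
#' exactly.
#'
#' @param model An `ann_model`.
#' @param path JSON file path.
#' @return `ann_read`: the restored `ann_model`.
#' @export
ann_write <- function(model, path) {
  payload <- list(
    config = unclass(model$config),
    W = lapply(model$W, function(m) list(dim = dim(m), data = as.numeric(m))),
    b = model$b)
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname ann_write
#' @export
ann_read <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- p$config
  config <- ann_config(cfg$input_dim, hidden = cfg$hidden,
                       learning_rate = cfg$learning_rate,
                       momentum = cfg$momentum, epochs = cfg$epochs,
                       batch_size = cfg$batch_size,
                       class_weighting = cfg$class_weighting,
                       patience = cfg$patience, seed = cfg$seed)
  W <- lapply(seq_len(nrow_or_len(p$W)), function(i) {
    wi <- if (is.data.frame(p$W)) list(dim = p$W$dim[[i]], data = p$W$data[[i]])
          else p$W[[i]]
    matrix(wi$data, nrow = wi$dim[1], ncol = wi$dim[2])
  })
  b <- if (is.list(p$b)) p$b else as.list(p$b)
  structure(list(W = W, b = lapply(b, as.numeric), config = config,
                 train_report = data.frame(epoch = integer(), loss = numeric(),
                                           val_accuracy = numeric())),
            class = "ann_model")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
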