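# Feedforward-network case/control classifier: min-max scaling, the
# 7-6-4-2 forward pass, full-batch gradient-descent training, ROC/AUC,
# stratified k-fold cross-validation, and text-file serialization.

#' Training hyperparameters
#'
#' @param lr Learning rate of full-batch gradient descent (default 0.05).
#' @param epochs Number of epochs (default 2000).
#' @param l2 L2 weight penalty (default 1e-4).
#' @param seed Seed for the uniform(-0.5, 0.5) weight initialization.
#' @param hidden Hidden-layer widths (default `c(6, 4)`; the reference
#'   architecture is input-6-4-2).
#' @return A named list of hyperparameters.
#' @export
ffnn_hyper <- function(lr = 0.05, epochs = 2000, l2 = 1e-4, seed = 1L,
                       hidden = c(6L, 4L)) {
  list(lr = lr, epochs = epochs, l2 = l2, seed = as.integer(seed),
       hidden = as.integer(hidden))
}

#' Min-max scale a feature table
#'
#' Maps each feature to `(x - min) / (max - min)` on `[0, 1]`; constant
#' features map to 0 and are flagged.
#'
#' @param X Sample-by-feature data frame or matrix.
#' @return List with `X` (scaled matrix) and `params` (data frame
#'   `feature`, `min`, `max`, `constant`).
#' @export
minmax_scale <- function(X) {
  X <- as.matrix(X)
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  params <- data.frame(feature = colnames(X) %||% as.character(seq_len(ncol(X))),
                       min = unname(mins), max = unname(maxs),
                       constant = unname(maxs == mins),
                       stringsAsFactors = FALSE)
  list(X = apply_minmax(X, params), params = params)
}

#' @rdname minmax_scale
#' @param params Scaling parameters returned by `minmax_scale`; applying
#'   stored parameters to the training data reproduces the scaled table.
#' @export
apply_minmax <- function(X, params) {
  X <- as.matrix(X)
  rng <- ifelse(params$constant, 1, params$max - params$min)
  out <- sweep(sweep(X, 2, params$min, "-"), 2, rng, "/")
  out[, params$constant] <- 0
  out
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)   # numerical stability; softmax is shift-invariant
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass of the feedforward network
#'
#' `Y = Softmax(W3' Sigmoid(W2' Sigmoid(W1' X + B1) + B2) + B3)`: two
#' sigmoid hidden layers (6 and 4 units) and a 2-unit softmax output, so
#' each output row sums to 1.  The predicted class is the argmax (ties
#' resolve to the first class).
#'
#' @param params An `ffnn_model` (weights `W1` 7x6, `W2` 6x4, `W3` 4x2;
#'   biases `B1`, `B2`, `B3`).
#' @param x A length-7 (already scaled) feature vector or an n-by-7
#'   matrix.
#' @return An n-by-2 matrix of class probabilities (a length-2 vector for
#'   vector input).
#' @export
ffnn_forward <- function(params, x) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(as.numeric(x), nrow = 1) else as.matrix(x)
  if (ncol(X) != nrow(params$W1))
    glyco_stop(sprintf("input has %d features; model expects %d",
                       ncol(X), nrow(params$W1)), "glycomig_parameter_error")
  A1 <- sigmoid(sweep(X %*% params$W1, 2, params$B1, "+"))
  A2 <- sigmoid(sweep(A1 %*% params$W2, 2, params$B2, "+"))
  P <- softmax_rows(sweep(A2 %*% params$W3, 2, params$B3, "+"))
  colnames(P) <- c("control", "case")
  if (vec) P[1, ] else P
}

#' Train the feedforward network
#'
#' Full-batch gradient descent on the mean cross-entropy with a small L2
#' penalty; weights initialized uniform(-0.5, 0.5) under the given seed,
#' so training is deterministic per seed.
#'
#' @param X Scaled sample-by-feature matrix (see [minmax_scale()]).
#' @param y Binary labels (0/1, logical, or a 2-level factor; the second
#'   level / 1 / TRUE is the "case" class).
#' @param hyper Hyperparameters from [ffnn_hyper()].
#' @return An `ffnn_model` list with the weight and bias matrices, the
#'   loss trace endpoints, and the hyperparameters.
#' @export
ffnn_train <- function(X, y, hyper = ffnn_hyper()) {
  X <- as.matrix(X)
  y <- label_to_binary(y)
  if (length(unique(y)) < 2L)
    glyco_stop("training labels contain a single class", "glycomig_parameter_error")
  n <- nrow(X); d <- ncol(X)
  h1 <- hyper$hidden[1]; h2 <- hyper$hidden[2]
  init <- with_seed(hyper$seed, list(
    W1 = matrix(runif(d * h1, -0.5, 0.5), d, h1),
    B1 = runif(h1, -0.5, 0.5),
    W2 = matrix(runif(h1 * h2, -0.5, 0.5), h1, h2),
    B2 = runif(h2, -0.5, 0.5),
    W3 = matrix(runif(h2 * 2L, -0.5, 0.5), h2, 2L),
    B3 = runif(2L, -0.5, 0.5)
  ))
  W1 <- init$W1; B1 <- init$B1; W2 <- init$W2; B2 <- init$B2
  W3 <- init$W3; B3 <- init$B3
  Y <- cbind(1 - y, y)          # one-hot: column 2 = case
  lr <- hyper$lr; l2 <- hyper$l2
  loss <- function(P) {
    -mean(log(pmax(rowSums(Y * P), 1e-12))) +
      l2 / 2 * (sum(W1^2) + sum(W2^2) + sum(W3^2))
  }
  initial_loss <- NA_real_
  for (epoch in seq_len(hyper$epochs)) {
    Z1 <- sweep(X %*% W1, 2, B1, "+");  A1 <- sigmoid(Z1)
    Z2 <- sweep(A1 %*% W2, 2, B2, "+"); A2 <- sigmoid(Z2)
    P <- softmax_rows(sweep(A2 %*% W3, 2, B3, "+"))
    if (epoch == 1L) initial_loss <- loss(P)
    dZ3 <- (P - Y) / n
    dW3 <- crossprod(A2, dZ3) + l2 * W3
    dB3 <- colSums(dZ3)
    dA2 <- dZ3 %*% t(W3)
    dZ2 <- dA2 * A2 * (1 - A2)
    dW2 <- crossprod(A1, dZ2) + l2 * W2
    dB2 <- colSums(dZ2)
    dA1 <- dZ2 %*% t(W2)
    dZ1 <- dA1 * A1 * (1 - A1)
    dW1 <- crossprod(X, dZ1) + l2 * W1
    dB1 <- colSums(dZ1)
    W1 <- W1 - lr * dW1; B1 <- B1 - lr * dB1
    W2 <- W2 - lr * dW2; B2 <- B2 - lr * dB2
    W3 <- W3 - lr * dW3; B3 <- B3 - lr * dB3
  }
  dimnames(W1) <- NULL
  Pfinal <- ffnn_forward(list(W1 = W1, B1 = B1, W2 = W2, B2 = B2,
                              W3 = W3, B3 = B3), X)
  final_loss <- -mean(log(pmax(rowSums(Y * Pfinal), 1e-12))) +
    l2 / 2 * (sum(W1^2) + sum(W2^2) + sum(W3^2))
  structure(
    list(W1 = W1, B1 = B1, W2 = W2, B2 = B2, W3 = W3, B3 = B3,
         feature_names = colnames(X), scaling = NULL, hyper = hyper,
         initial_loss = initial_loss, final_loss = final_loss),
    class = "ffnn_model")
}

label_to_binary <- function(y) {
  if (is.factor(y)) as.integer(y) - 1L
  else if (is.logical(y)) as.integer(y)
  else if (is.character(y)) as.integer(factor(y)) - 1L
  else as.integer(y)
}

#' @export
print.ffnn_model <- function(x, ...) {
  cat(sprintf("<ffnn_model> %d-%d-%d-2, loss %.4f -> %.4f\n",
              nrow(x$W1), ncol(x$W1), ncol(x$W2),
              x$initial_loss, x$final_loss))
  if (!is.null(x$feature_names))
    cat("features:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' ROC curve and AUC
#'
#' AUC in the Mann-Whitney form: the probability that a random positive
#' outscores a random negative, ties counted one half.  The ROC points
#' come from a sweep over the observed score thresholds.
#'
#' @param scores Numeric prediction scores (higher = more case-like).
#' @param labels Binary labels (1/TRUE = positive).
#' @return List with `auc` and `roc`, a data frame of `fpr`, `tpr`.
#' @export
roc_auc <- function(scores, labels) {
  y <- label_to_binary(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    glyco_stop("both classes must be present to compute AUC",
               "glycomig_parameter_error")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    fpr = vapply(thr, function(t) sum(scores >= t & y == 0L) / n0, numeric(1)),
    tpr = vapply(thr, function(t) sum(scores >= t & y == 1L) / n1, numeric(1)),
    threshold = thr)
  list(auc = auc, roc = roc)
}

# Stratified (or plain) assignment of n samples to k folds.
make_folds <- function(y, n_folds, seed, stratified = TRUE) {
  y <- label_to_binary(y)
  fold <- integer(length(y))
  with_seed(seed, {
    if (stratified) {
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      fold[sample(seq_along(y))] <- rep_len(seq_len(n_folds), length(y))
    }
  })
  fold
}

#' k-fold cross-validation of the network
#'
#' Random (by default class-stratified) partition into `n_folds` subsets;
#' each fold in turn is held out, the model is fitted on the remainder,
#' and the held-out fold's AUC is computed from the case-class
#' probability.  By default min-max scaling and F-test feature selection
#' are fitted inside each training fold; `paper_mode = TRUE` reproduces
#' the protocol that fits both on the full dataset before splitting
#' (information leakage, kept for comparability).
#'
#' @param X Raw sample-by-feature table.
#' @param y Binary labels.
#' @param n_folds Number of folds (default 5).
#' @param seed Seed controlling the partition and fold-model inits.
#' @param k Number of features to select by [f_rank_features()]; NULL
#'   uses all columns.
#' @param hyper [ffnn_hyper()].
#' @param stratified Stratify folds by class (default TRUE).
#' @param paper_mode Fit scaler/selection on the full data (default FALSE).
#' @return A `cv_result`: per-fold list (`test_idx`, `auc`, `roc`,
#'   `features`) and `mean_auc`, the mean over folds with defined AUC
#'   (a one-class test fold yields NA with a warning and is excluded).
#' @export
cross_validate <- function(X, y, n_folds = 5L, seed = 7L, k = NULL,
                           hyper = ffnn_hyper(), stratified = TRUE,
                           paper_mode = FALSE) {
  X <- as.data.frame(X, check.names = FALSE)
  y <- label_to_binary(y)
  fold <- make_folds(y, n_folds, seed, stratified)
  if (paper_mode) {
    sel_all <- if (!is.null(k)) f_rank_features(X, y, k)$feature else colnames(X)
    sc_all <- minmax_scale(X[, sel_all, drop = FALSE])
  }
  folds <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f; te <- !tr
    if (length(unique(y[tr])) < 2L)
      glyco_stop("a training fold contains a single class",
                 "glycomig_parameter_error")
    if (paper_mode) {
      sel <- sel_all
      Xtr <- sc_all$X[tr, , drop = FALSE]
      Xte <- sc_all$X[te, , drop = FALSE]
    } else {
      sel <- if (!is.null(k)) f_rank_features(X[tr, , drop = FALSE], y[tr], k)$feature
             else colnames(X)
      sc <- minmax_scale(X[tr, sel, drop = FALSE])
      Xtr <- sc$X
      Xte <- apply_minmax(X[te, sel, drop = FALSE], sc$params)
    }
    model <- ffnn_train(Xtr, y[tr],
                        modifyList(hyper, list(seed = child_seed(seed, f))))
    scores <- ffnn_forward(model, Xte)[, "case"]
    fold_auc <- if (length(unique(y[te])) < 2L) {
      warning(sprintf("fold %d test set has a single class; AUC undefined", f))
      list(auc = NA_real_, roc = NULL)
    } else roc_auc(scores, y[te])
    folds[[f]] <- list(test_idx = which(te), auc = fold_auc$auc,
                       roc = fold_auc$roc, features = sel)
  }
  aucs <- vapply(folds, `[[`, numeric(1), "auc")
  structure(list(folds = folds, fold_aucs = aucs,
                 mean_auc = mean(aucs, na.rm = TRUE),
                 seed = seed, n_folds = n_folds, paper_mode = paper_mode),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds (seed %d): AUCs %s; mean %.3f\n",
              x$n_folds, x$seed,
              paste(sprintf("%.3f", x$fold_aucs), collapse = ", "),
              x$mean_auc))
  invisible(x)
}

#' Fit the final model on the whole dataset
#'
#' Selects `k` features (when requested), fits the scaler, and trains on
#' all samples; the returned model carries the feature list and scaling
#' parameters so it can score raw feature tables.
#'
#' @inheritParams cross_validate
#' @return An `ffnn_model` with `feature_names` and `scaling` set.
#' @export
fit_final <- function(X, y, k = NULL, hyper = ffnn_hyper()) {
  X <- as.data.frame(X, check.names = FALSE)
  y <- label_to_binary(y)
  sel <- if (!is.null(k)) f_rank_features(X, y, k)$feature else colnames(X)
  sc <- minmax_scale(X[, sel, drop = FALSE])
  model <- ffnn_train(sc$X, y, hyper)
  model$feature_names <- sel
  model$scaling <- sc$params
  model
}

#' Score raw feature rows with a fitted model
#'
#' @param object An `ffnn_model` from [fit_final()].
#' @param newdata Raw feature table containing the model's features.
#' @param ... Unused.
#' @return Matrix of class probabilities.
#' @export
predict.ffnn_model <- function(object, newdata, ...) {
  X <- as.data.frame(newdata, check.names = FALSE)[, object$feature_names,
                                                   drop = FALSE]
  ffnn_forward(object, apply_minmax(X, object$scaling))
}

# full-precision numeric <-> string helpers for lossless serialization
num_to_chr <- function(x) sprintf("%.17g", x)
chr_to_num <- function(x) as.numeric(x)

#' Save / load a model as structured text (JSON)
#'
#' Weights are serialized as full-precision strings so a save/load round
#' trip reproduces bit-identical predictions.
#'
#' @param model An `ffnn_model`.
#' @param path File path.
#' @return `load_model` returns the `ffnn_model`.
#' @export
save_model <- function(model, path) {
  enc_mat <- function(m) list(dim = dim(m), data = num_to_chr(as.numeric(m)))
  obj <- list(
    architecture = c(nrow(model$W1), ncol(model$W1), ncol(model$W2), 2L),
    W1 = enc_mat(model$W1), W2 = enc_mat(model$W2), W3 = enc_mat(model$W3),
    B1 = num_to_chr(model$B1), B2 = num_to_chr(model$B2),
    B3 = num_to_chr(model$B3),
    feature_names = model$feature_names,
    scaling = if (!is.null(model$scaling)) list(
      feature = model$scaling$feature,
      min = num_to_chr(model$scaling$min),
      max = num_to_chr(model$scaling$max),
      constant = model$scaling$constant),
    hyper = model$hyper,
    initial_loss = model$initial_loss, final_loss = model$final_loss)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec_mat <- function(m) matrix(chr_to_num(m$data), m$dim[1], m$dim[2])
  structure(
    list(W1 = dec_mat(obj$W1), B1 = chr_to_num(obj$B1),
         W2 = dec_mat(obj$W2), B2 = chr_to_num(obj$B2),
         W3 = dec_mat(obj$W3), B3 = chr_to_num(obj$B3),
         feature_names = obj$feature_names,
         scaling = if (!is.null(obj$scaling)) data.frame(
           feature = obj$scaling$feature,
           min = chr_to_num(obj$scaling$min),
           max = chr_to_num(obj$scaling$max),
           constant = obj$scaling$constant,
           stringsAsFactors = FALSE),
         hyper = obj$hyper,
         initial_loss = obj$initial_loss, final_loss = obj$final_loss),
    class = "ffnn_model")
}

#' The seven reference model features
#'
#' The glycopeptide panel of the reference migraine classifier:
#' IgG1 G0-NF, IgG1 G2NF, IgG2 G0N, IgG2 G1N, IgG2 G2N, IgG2 G2NF and
#' IgG3/4 G0.
#'
#' @return Character vector of 7 feature ids.
#' @export
reference_features <- function() {
  c("IgG1 G0-NF", "IgG1 G2NF", "IgG2 G0N", "IgG2 G1N", "IgG2 G2N",
    "IgG2 G2NF", "IgG3/4 G0")
}
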