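#' Train a cost-weighted linear SVM on normalized k-mer spectra
#'
#' Fits a soft-margin linear support vector machine on unit-normalized
#' k-mer spectrum features. Because the linear kernel on unit-sphere
#' features equals the cosine spectrum kernel on raw counts, this is the
#' primal form of a cosine spectrum-kernel machine, and the primal weight
#' vector assigns one interpretable weight per k-mer. Class misclassification
#' costs are `C * class_weight`; the defaults (C = 15, weights 10:1 in
#' favour of the positives) compensate for the 1:10 positive:negative
#' imbalance of the standard training design.
#'
#' @param pos,neg Numeric matrices of unit-normalized k-mer features
#'   (rows = sequences, 4^k columns named by [all_kmers()]); at least two
#'   rows each.
#' @param C Cost parameter (default 15).
#' @param class_weights Length-2 numeric: misclassification weight of the
#'   positive and the negative class (default `c(10, 1)`).
#' @param seed Integer seed (training is deterministic given the data order,
#'   but the seed is recorded and used for reproducibility of any
#'   library-internal randomness).
#' @param metadata Named list recorded on the model (species, tissue,
#'   sampling mode, ...).
#' @return An object of class `trained_linear_model` with fields `k`,
#'   `weights` (named per k-mer), `bias`, `C`, `class_weights`, `metadata`.
#' @export
train_classifier <- function(pos, neg, C = 15, class_weights = c(10, 1),
                             seed = 1L, metadata = list()) {
  if (is.null(dim(pos)) || is.null(dim(neg)) ||
      nrow(pos) < 2L || nrow(neg) < 2L) {
    stop("need at least 2 examples per class")
  }
  if (ncol(pos) != ncol(neg)) stop("pos and neg feature dimensions differ")
  k <- as.integer(round(log(ncol(pos), 4)))
  X <- rbind(pos, neg)
  y <- factor(rep(c("positive", "negative"), c(nrow(pos), nrow(neg))),
              levels = c("positive", "negative"))
  set.seed(seed)
  fit <- e1071::svm(X, y, type = "C-classification", kernel = "linear",
                    cost = C, scale = FALSE, tolerance = 1e-4,
                    cachesize = 256,
                    class.weights = c(positive = class_weights[1],
                                      negative = class_weights[2]))
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm orients the decision function towards its first internal label;
  # flip if needed so that larger scores mean more enhancer-like
  if (fit$labels[1L] != 1L) { w <- -w; b <- -b }
  names(w) <- colnames(X)
  structure(list(k = k, weights = w, bias = b, C = C,
                 class_weights = c(positive = class_weights[1],
                                   negative = class_weights[2]),
                 metadata = metadata, seed = as.integer(seed)),
            class = "trained_linear_model")
}

#' @export
print.trained_linear_model <- function(x, ...) {
  cat(sprintf(
    "trained_linear_model: k = %d (%d k-mer weights), C = %g, class weights %g:%g\n",
    x$k, length(x$weights), x$C, x$class_weights[1], x$class_weights[2]))
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Decision scores of a trained model
#'
#' `score_i = weights . x_i + bias`; higher scores are more enhancer-like.
#'
#' @param model A `trained_linear_model`.
#' @param X Numeric matrix of unit-normalized k-mer features with 4^k
#'   columns matching the model's k.
#' @return Numeric vector of decision values, one per row of `X`.
#' @export
decision_scores <- function(model, X) {
  stopifnot(inherits(model, "trained_linear_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != length(model$weights)) {
    stop("feature dimension ", ncol(X), " does not match model k = ",
         model$k, " (expected ", length(model$weights), " columns)")
  }
  drop(X %*% model$weights + model$bias)
}

#' Stratified k-fold cross-validation of the spectrum SVM
#'
#' Randomly partitions the data into `folds` disjoint sets that preserve
#' the positive:negative ratio (within one example), trains on every
#' leave-one-fold-out split, scores the held-out fold, and reports per-fold
#' auROC and auPR together with their means and standard errors.
#'
#' @inheritParams train_classifier
#' @param folds Number of folds (default 10); each class needs at least
#'   `folds` members.
#' @param neg_groups Optional vector (length `nrow(neg)`) of positive row
#'   indices assigning each negative to the positive it was matched to.
#'   When given, every matched cluster (one positive plus its negatives)
#'   stays in a single fold. Matched negatives share their seed's length
#'   and composition, so folds that split a cluster leak that signature
#'   between training and test and inflate the apparent AUC; grouped folds
#'   are the standard remedy for matched designs. With equal cluster sizes
#'   the class ratio per fold is preserved exactly.
#' @return An object of class `cv_result` with fields `auroc`, `aupr`
#'   (per-fold vectors), `mean_auroc`, `mean_aupr`, `se_auroc`, `se_aupr`,
#'   and `fold_assignment` (list with `pos` and `neg` fold ids).
#' @export
cross_validate <- function(pos, neg, folds = 10L, C = 15,
                           class_weights = c(10, 1), seed = 1L,
                           neg_groups = NULL) {
  folds <- as.integer(folds)
  if (nrow(pos) < folds || nrow(neg) < folds) {
    stop("each class needs at least ", folds, " examples for ", folds,
         "-fold cross-validation")
  }
  set.seed(seed)
  # seeded shuffle within each class, then round-robin fold labels
  fold_pos <- sample(rep_len(seq_len(folds), nrow(pos)))
  if (is.null(neg_groups)) {
    fold_neg <- sample(rep_len(seq_len(folds), nrow(neg)))
  } else {
    if (length(neg_groups) != nrow(neg)) {
      stop("neg_groups must assign every negative to a positive row")
    }
    fold_neg <- fold_pos[neg_groups]
  }
  auroc <- numeric(folds); aupr <- numeric(folds)
  for (f in seq_len(folds)) {
    model <- train_classifier(pos[fold_pos != f, , drop = FALSE],
                              neg[fold_neg != f, , drop = FALSE],
                              C = C, class_weights = class_weights,
                              seed = seed)
    te_pos <- pos[fold_pos == f, , drop = FALSE]
    te_neg <- neg[fold_neg == f, , drop = FALSE]
    scores <- decision_scores(model, rbind(te_pos, te_neg))
    labels <- rep(c(1L, 0L), c(nrow(te_pos), nrow(te_neg)))
    auroc[f] <- roc_auc(scores, labels)
    aupr[f] <- pr_auc(scores, labels)
  }
  structure(list(auroc = auroc, aupr = aupr,
                 mean_auroc = mean(auroc), mean_aupr = mean(aupr),
                 se_auroc = stats::sd(auroc) / sqrt(folds),
                 se_aupr = stats::sd(aupr) / sqrt(folds),
                 folds = folds,
                 fold_assignment = list(pos = fold_pos, neg = fold_neg)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result (%d folds): auROC %.3f +/- %.3f, auPR %.3f +/- %.3f\n",
              x$folds, x$mean_auroc, x$se_auroc, x$mean_aupr, x$se_aupr))
  invisible(x)
}

#' Serialize a trained model to JSON
#'
#' Writes k, the named k-mer weight vector, bias, cost, class weights and
#' metadata, so that external tools (or the motif-interpretation stage) can
#' consume the weights.
#'
#' @param model A `trained_linear_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "trained_linear_model"))
  jsonlite::write_json(
    list(k = model$k, kmers = names(model$weights),
         weights = unname(model$weights), bias = model$bias, C = model$C,
         class_weights = as.list(model$class_weights),
         metadata = model$metadata, seed = model$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trained model from JSON
#' @param path Path written by [write_model_json()].
#' @return A `trained_linear_model`.
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- setNames(as.numeric(x$weights), x$kmers)
  structure(list(k = as.integer(x$k), weights = w, bias = as.numeric(x$bias),
                 C = as.numeric(x$C),
                 class_weights = unlist(x$class_weights),
                 metadata = as.list(x$metadata),
                 seed = as.integer(x$seed)),
            class = "trained_linear_model")
}
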