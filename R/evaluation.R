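#' Area under the ROC curve
#'
#' Trapezoidal area with equal-score groups handled jointly (all examples
#' sharing a score move the curve in one diagonal step), which makes the
#' result exactly the concordance probability
#' `P(score+ > score-) + 0.5 * P(tie)`, i.e. `U / (m * n)` of the
#' Mann-Whitney U statistic.
#'
#' @param scores Numeric decision scores (higher = more positive).
#' @param labels Binary labels (1/TRUE = positive); both classes must be
#'   present.
#' @return auROC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  m <- sum(labels == 1L); n <- sum(labels == 0L)
  if (m == 0L || n == 0L) stop("roc_auc requires both classes present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))
  tp_g <- tapply(y, grp, sum)
  fp_g <- tapply(1 - y, grp, sum)
  tpr <- c(0, cumsum(tp_g)) / m
  fpr <- c(0, cumsum(fp_g)) / n
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-sum average precision: examples are ranked by descending score
#' (tied scores grouped), and the area is the sum over threshold steps of
#' precision times recall increment — no interpolation.
#'
#' @inheritParams roc_auc
#' @return auPR in (0, 1\].
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  m <- sum(labels == 1L)
  if (m == 0L) stop("pr_auc requires at least one positive")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))
  tp <- cumsum(tapply(y, grp, sum))
  np <- cumsum(tapply(rep(1L, length(y)), grp, sum))
  prec <- tp / np
  rec <- tp / m
  sum(prec * diff(c(0, rec)))
}

#' Relative AUC: the cross-species conservation statistic
#'
#' The auROC (or auPR) obtained by a classifier trained on species A and
#' tested on species B, divided by the mean cross-validated auROC (auPR) of
#' the classifier trained and tested on B. Values near 1 mean the model
#' generalizes nearly as well as a natively trained one; values above 1 are
#' allowed and not clipped.
#'
#' @param cross_value Cross-species AUC.
#' @param within_value Mean within-species cross-validation AUC of the test
#'   species (must be > 0).
#' @return The ratio `cross_value / within_value`.
#' @examples
#' relative_auc(0.78, 0.82)  # 0.951..., i.e. "95.1%"
#' @export
relative_auc <- function(cross_value, within_value) {
  if (any(within_value <= 0)) stop("within_value must be positive")
  cross_value / within_value
}

#' Cross-evaluation matrix over labelled datasets
#'
#' Builds the train-label x test-label grids of auROC/auPR and their
#' relative values. Off-diagonal cell (A, B) scores the model trained on A
#' against the full dataset of B; diagonal cells hold the mean
#' cross-validation values of the label's own classifier. Relative values
#' divide each column by its diagonal (the test label's within value); the
#' diagonal of a relative matrix is 1 by construction. The matrix need not
#' be symmetric.
#'
#' @param models Named list of `trained_linear_model`, one per label.
#' @param datasets Named list; each element a list with matrices `pos` and
#'   `neg` of unit-normalized features.
#' @param cv Named list of `cv_result`, one per label.
#' @return An object of class `cross_eval_matrix`: list of matrices
#'   `auroc`, `aupr`, `relative_auroc`, `relative_aupr` (rows = train
#'   label, columns = test label).
#' @export
cross_eval_matrix <- function(models, datasets, cv) {
  labels <- names(models)
  if (is.null(labels) || !setequal(labels, names(cv))) {
    stop("models and cv must be named lists over the same labels")
  }
  missing <- setdiff(labels, names(datasets))
  if (length(missing)) {
    stop("missing dataset(s): ", paste(missing, collapse = ", "))
  }
  ks <- vapply(models, `[[`, integer(1L), "k")
  if (length(unique(ks)) != 1L) stop("models have inconsistent k")
  n <- length(labels)
  auroc <- aupr <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  for (a in labels) {
    for (b in labels) {
      if (a == b) {
        auroc[a, b] <- cv[[b]]$mean_auroc
        aupr[a, b] <- cv[[b]]$mean_aupr
      } else {
        d <- datasets[[b]]
        scores <- decision_scores(models[[a]], rbind(d$pos, d$neg))
        lab <- rep(c(1L, 0L), c(nrow(d$pos), nrow(d$neg)))
        auroc[a, b] <- roc_auc(scores, lab)
        aupr[a, b] <- pr_auc(scores, lab)
      }
    }
  }
  rel_roc <- sweep(auroc, 2L, diag(auroc), "/")
  rel_pr <- sweep(aupr, 2L, diag(aupr), "/")
  structure(list(auroc = auroc, aupr = aupr,
                 relative_auroc = rel_roc, relative_aupr = rel_pr),
            class = "cross_eval_matrix")
}

#' @export
print.cross_eval_matrix <- function(x, ...) {
  cat("cross_eval_matrix (rows = train, cols = test)\nauROC:\n")
  print(round(x$auroc, 3))
  cat("relative auROC:\n")
  print(round(x$relative_auroc, 3))
  invisible(x)
}

#' Spearman rank correlation with large-sample p-value
#'
#' Pearson correlation of mid-ranks; the two-sided p-value uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees
#' of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 3); neither may be
#'   constant.
#' @return List with `rho` and `p_value`.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("rank correlation undefined for a constant vector")
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p)
}

#' Mann-Whitney U comparison of two groups
#'
#' `U` counts the pairs (a, b) with a > b, plus half a count per tie. For
#' small samples (m + n <= `exact_limit`, default 12) the p-value is exact,
#' by enumeration of all C(m+n, m) group assignments of the pooled values;
#' otherwise the normal approximation with tie-corrected variance and
#' continuity correction is used.
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @param alternative `"greater"` (a tends larger, default), `"less"`, or
#'   `"two.sided"`.
#' @param exact_limit Largest m + n for which the exact enumeration is used.
#' @return List with `U`, `p_value`, and `method` ("exact" or "normal").
#' @export
mannwhitney_compare <- function(group_a, group_b,
                                alternative = c("greater", "less",
                                                "two.sided"),
                                exact_limit = 12L) {
  alternative <- match.arg(alternative)
  m <- length(group_a); n <- length(group_b)
  if (m == 0L || n == 0L) stop("both groups must be non-empty")
  u_stat <- function(idx_a, pooled) {
    r <- rank(pooled)
    sum(r[idx_a]) - length(idx_a) * (length(idx_a) + 1) / 2
  }
  pooled <- c(group_a, group_b)
  U <- u_stat(seq_len(m), pooled)
  eps <- 1e-9
  if (m + n <= exact_limit) {
    combs <- utils::combn(m + n, m)
    u_null <- apply(combs, 2L, u_stat, pooled = pooled)
    p <- switch(alternative,
      greater = mean(u_null >= U - eps),
      less = mean(u_null <= U + eps),
      two.sided = mean(abs(u_null - m * n / 2) >= abs(U - m * n / 2) - eps))
    method <- "exact"
  } else {
    mu <- m * n / 2
    nt <- table(pooled)
    tie_term <- sum(nt^3 - nt) / ((m + n) * (m + n - 1))
    sigma <- sqrt(m * n / 12 * (m + n + 1 - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z_g <- (U - mu - 0.5) / sigma   # continuity-corrected
      z_l <- (U - mu + 0.5) / sigma
      p <- switch(alternative,
        greater = stats::pnorm(z_g, lower.tail = FALSE),
        less = stats::pnorm(z_l),
        two.sided = min(1, 2 * min(stats::pnorm(z_g, lower.tail = FALSE),
                                   stats::pnorm(z_l))))
    }
    method <- "normal"
  }
  list(U = U, p_value = p, method = method)
}

#' Export the cells of a cross-evaluation matrix as a tidy table
#'
#' @param mat A `cross_eval_matrix`.
#' @return Data frame with one row per (train, test) cell and columns
#'   `train`, `test`, `auroc`, `aupr`, `relative_auroc`, `relative_aupr`.
#' @export
cross_eval_table <- function(mat) {
  stopifnot(inherits(mat, "cross_eval_matrix"))
  labels <- rownames(mat$auroc)
  grid <- expand.grid(train = labels, test = labels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$auroc <- mat$auroc[cbind(grid$train, grid$test)]
  grid$aupr <- mat$aupr[cbind(grid$train, grid$test)]
  grid$relative_auroc <- mat$relative_auroc[cbind(grid$train, grid$test)]
  grid$relative_aupr <- mat$relative_aupr[cbind(grid$train, grid$test)]
  grid
}

#' Precision-recall curve points
#'
#' @inheritParams roc_auc
#' @return Data frame with columns `threshold`, `recall`, `precision` (one
#'   row per tie group).
#' @export
pr_points <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  m <- sum(labels == 1L)
  if (m == 0L) stop("pr_points requires at least one positive")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))
  tp <- cumsum(tapply(y, grp, sum))
  np <- cumsum(tapply(rep(1L, length(y)), grp, sum))
  data.frame(threshold = as.numeric(tapply(s, grp, `[`, 1L)),
             recall = as.numeric(tp) / m,
             precision = as.numeric(tp / np))
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return Data frame with columns `threshold`, `fpr`, `tpr` (one row per
#'   tie group, plus the origin).
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  m <- sum(labels == 1L); n <- sum(labels == 0L)
  if (m == 0L || n == 0L) stop("roc_points requires both classes present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))
  thr <- tapply(s, grp, `[`, 1L)
  tpr <- c(0, cumsum(tapply(y, grp, sum)) / m)
  fpr <- c(0, cumsum(tapply(1 - y, grp, sum)) / n)
  data.frame(threshold = c(Inf, as.numeric(thr)), fpr = fpr, tpr = tpr)
}
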