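test_that("roc_auc handles separation, hand example, and matches the rank-sum oracle", {
  expect_equal(roc_auc(c(5, 4, 3, 1, 0.5), c(1, 1, 0, 0, 0)), 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")

  # U/(m n) oracle, ties included
  set.seed(2)
  for (i in 1:40) {
    n <- sample(10:60, 1)
    scores <- sample(round(rnorm(n), sample(c(1, 3), 1)))  # force some ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    r <- rank(scores)
    m1 <- sum(labels == 1)
    U <- sum(r[labels == 1]) - m1 * (m1 + 1) / 2
    expect_equal(roc_auc(scores, labels), U / (m1 * sum(labels == 0)),
                 tolerance = 1e-12)
  }
})

test_that("roc_auc is invariant under monotone transforms and antisymmetric", {
  set.seed(4)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.3)
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(scores), labels), a, tolerance = 1e-12)
  expect_equal(roc_auc(rank(scores), labels), a, tolerance = 1e-12)
  expect_equal(roc_auc(-scores, labels), 1 - a, tolerance = 1e-12)
})

test_that("pr_auc is the step-sum average precision", {
  expect_equal(pr_auc(c(5, 4, 3, 1), c(1, 1, 0, 0)), 1)
  expect_equal(pr_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)),
               0.5 * 1 + 0.5 * (2 / 3))
  # single positive ranked last of n
  expect_equal(pr_auc(10:1, c(rep(0, 9), 1)), 1 / 10)
  expect_error(pr_auc(1:3, c(0, 0, 0)), "positive")

  # naive per-rank oracle on tie-free data
  set.seed(6)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    scores <- sample(seq_len(n)) + runif(n, 0, 0.1)
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) == 0) next
    o <- order(scores, decreasing = TRUE)
    y <- labels[o]
    prec <- cumsum(y) / seq_along(y)
    expect_equal(pr_auc(scores, labels), sum(prec[y == 1]) / sum(y),
                 tolerance = 1e-12)
  }
})

test_that("curve point exports are consistent with the scalar areas", {
  set.seed(7)
  scores <- rnorm(60); labels <- rbinom(60, 1, 0.3)
  rp <- roc_points(scores, labels)
  expect_equal(sum(diff(rp$fpr) * (head(rp$tpr, -1) + tail(rp$tpr, -1)) / 2),
               roc_auc(scores, labels), tolerance = 1e-12)
  pp <- pr_points(scores, labels)
  expect_equal(sum(pp$precision * diff(c(0, pp$recall))),
               pr_auc(scores, labels), tolerance = 1e-12)
  expect_equal(utils::tail(pp$recall, 1), 1)
})

test_that("relative AUC is a plain uncapped ratio", {
  expect_equal(relative_auc(0.78, 0.82), 0.78 / 0.82)
  expect_equal(round(100 * relative_auc(0.78, 0.82), 1), 95.1)
  expect_equal(relative_auc(0.82, 0.82), 1)
  expect_gt(relative_auc(0.9, 0.8), 1)  # no clipping
  expect_error(relative_auc(0.5, 0), "positive")
})

test_that("cross_eval_matrix wires diagonals, off-diagonals and relatives correctly", {
  set.seed(11)
  k <- 2L
  mk_model <- function(seed) {
    set.seed(seed)
    structure(list(k = k, weights = setNames(rnorm(16), all_kmers(k)),
                   bias = 0, C = 15,
                   class_weights = c(positive = 10, negative = 1),
                   metadata = list(), seed = seed),
              class = "trained_linear_model")
  }
  mk_cv <- function(auroc, aupr) {
    structure(list(auroc = rep(auroc, 10), aupr = rep(aupr, 10),
                   mean_auroc = auroc, mean_aupr = aupr,
                   se_auroc = 0, se_aupr = 0, folds = 10),
              class = "cv_result")
  }
  datasets <- lapply(1:3, function(i) {
    list(pos = random_features(12, k), neg = random_features(30, k))
  })
  names(datasets) <- c("a", "b", "c")
  models <- list(a = mk_model(1), b = mk_model(2), c = mk_model(3))
  cv <- list(a = mk_cv(0.9, 0.5), b = mk_cv(0.8, 0.4), c = mk_cv(0.85, 0.45))
  m <- cross_eval_matrix(models, datasets, cv)
  expect_equal(diag(m$auroc), c(a = 0.9, b = 0.8, c = 0.85))
  expect_equal(diag(m$relative_auroc), c(a = 1, b = 1, c = 1))
  # off-diagonal cell equals a direct scoring computation
  d <- datasets$b
  scores <- decision_scores(models$a, rbind(d$pos, d$neg))
  lab <- rep(c(1, 0), c(12, 30))
  expect_equal(m$auroc["a", "b"], roc_auc(scores, lab))
  expect_equal(m$relative_auroc["a", "b"], m$auroc["a", "b"] / 0.8)
  # matrix need not be symmetric
  expect_false(isTRUE(all.equal(m$auroc["a", "b"], m$auroc["b", "a"])))
  expect_error(cross_eval_matrix(models, datasets[1:2], cv), "missing dataset")

  tab <- cross_eval_table(m)
  expect_equal(nrow(tab), 9)
  expect_equal(tab$relative_auroc[tab$train == "a" & tab$test == "b"],
               m$relative_auroc["a", "b"])
})

test_that("rank correlation uses mid-ranks and the t approximation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(rank_correlation(x, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(rank_correlation(x, rev(x))$rho, -1)
  expect_error(rank_correlation(x, rep(1, 5)), "constant")
  expect_error(rank_correlation(1:2, 2:1), "at least 3")

  set.seed(13)
  for (i in 1:10) {
    a <- sample(1:5, 20, replace = TRUE)  # heavy ties
    b <- a + rnorm(20, sd = 2)
    got <- rank_correlation(a, b)
    # naive mid-rank oracle
    mid <- function(v) {
      sapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2)
    }
    expect_equal(got$rho, stats::cor(mid(a), mid(b)), tolerance = 1e-12)
    ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
    expect_equal(got$rho, unname(ct$estimate), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney U: exact enumeration, ties, and normal approximation", {
  res <- mannwhitney_compare(c(3, 4, 5), c(1, 2), alternative = "greater")
  expect_equal(res$U, 6)
  expect_equal(res$p_value, 0.1)   # 1 of C(5,2) = 10 assignments
  expect_equal(res$method, "exact")

  same <- mannwhitney_compare(c(1, 2, 3), c(1, 2, 3),
                              alternative = "two.sided")
  expect_gte(same$p_value, 0.99)

  # exact vs wilcox.test on tie-free data
  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(5); b <- rnorm(6)
    got <- mannwhitney_compare(a, b, alternative = "greater")
    ref <- stats::wilcox.test(a, b, alternative = "greater", exact = TRUE)
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }

  # normal approximation close to exact at m = n = 6
  set.seed(22)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(6, 0.5)
    pe <- mannwhitney_compare(a, b, alternative = "greater")$p_value
    pn <- mannwhitney_compare(a, b, alternative = "greater",
                              exact_limit = 0)$p_value
    expect_lt(abs(pe - pn), 0.015)
  }
})
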