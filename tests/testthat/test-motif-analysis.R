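# high-information test motif: 0.97 on each consensus base
sharp_motif <- function(consensus = "ACGTA", id = "M1", tf = "TF1") {
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  mat <- matrix(0.01, 4, nchar(consensus))
  mat[cbind(idx, seq_len(nchar(consensus)))] <- 0.97
  motif_model(id, tf, mat)
}

uniform_motif <- function(width = 5, id = "M0", tf = "TF0") {
  motif_model(id, tf, matrix(0.25, 4, width))
}

fake_model <- function(weights) {
  structure(list(k = as.integer(round(log(length(weights), 4))),
                 weights = weights, bias = 0, C = 15,
                 class_weights = c(positive = 10, negative = 1),
                 metadata = list(), seed = 1L),
            class = "trained_linear_model")
}

test_that("top-fraction selection counts, ordering, and tie handling", {
  set.seed(71)
  w <- setNames(rnorm(1024), all_kmers(5))
  m <- fake_model(w)
  sel <- select_top_kmers(m, 0.05, "positive")
  expect_length(sel$kmers, 52)  # ceiling(0.05 * 1024)
  expect_identical(sel$kmers, names(sort(w, decreasing = TRUE))[1:52])

  expect_length(select_top_kmers(m, 1.0)$kmers, 1024)

  bot <- select_top_kmers(m, 0.05, "negative")
  expect_identical(bot$kmers, names(sort(w))[1:52])

  # all-equal weights: lexicographically smallest k-mers win
  flat <- fake_model(setNames(rep(0.5, 1024), all_kmers(5)))
  expect_identical(select_top_kmers(flat, 0.05)$kmers, all_kmers(5)[1:52])
})

test_that("exact enumeration p-values behave as ranks over all k-mers", {
  m <- sharp_motif("ACGTA")
  hit <- match_kmer_to_motif("ACGTA", m)
  # the consensus and its reverse complement tie for the maximum, because
  # both strands of every k-mer are scored; the exact p is therefore 2/4^k
  expect_equal(hit$p_value, 2 / 1024)
  expect_equal(hit$best_strand, "+")
  expect_gt(hit$best_score, 0)

  # reverse complement scores identically on the minus strand
  rc <- match_kmer_to_motif("TACGT", m)
  expect_equal(rc$best_score, hit$best_score, tolerance = 1e-12)
  expect_equal(rc$best_strand, "-")

  u <- uniform_motif(5)
  miss <- match_kmer_to_motif("ACGTA", u)
  expect_equal(miss$best_score, 0)
  expect_equal(miss$p_value, 1)

  # p-values are rank(best score)/4^k: verify the empirical CDF steps
  lib1 <- build_motif_library(1, c(8, 8), 1.2, seed = 5)
  scores <- crossenhancer:::kmer_motif_scores(lib1[[1]], 5)
  for (km in sample(all_kmers(5), 25)) {
    expect_equal(match_kmer_to_motif(km, lib1[[1]])$p_value,
                 mean(scores >= scores[[km]] - 1e-12))
  }
})

test_that("k-mers longer than the motif slide the motif inside the k-mer", {
  m <- sharp_motif("ACGTA")
  long <- match_kmer_to_motif("GGACGTA", m)   # k = 7 > width 5
  # brute-force oracle over both strands and all offsets
  L <- log2(pmax(m$matrix, 0.01) / 0.25)
  brute <- -Inf
  for (km in c("GGACGTA", "TACGTCC")) {
    idx <- match(strsplit(km, "")[[1]], c("A", "C", "G", "T"))
    for (off in 0:2) {
      brute <- max(brute, sum(L[cbind(idx[off + 1:5], 1:5)]))
    }
  }
  expect_equal(long$best_score, brute, tolerance = 1e-12)
})

test_that("matched TF sets respect alpha and selection contents", {
  lib <- structure(list(M1 = sharp_motif("ACGTA", "M1", "TF1"),
                        M2 = sharp_motif("GGGCC", "M2", "TF2")),
                   class = "motif_library")
  expect_true("TF1" %in% matched_tf_set("ACGTA", lib))
  expect_identical(matched_tf_set(character(0), lib), character(0))
  expect_setequal(matched_tf_set("AAAAA", lib, alpha = 1),
                  c("TF1", "TF2"))
})

test_that("TF set intersections and UpSet counts partition the union", {
  sets <- list(s1 = c("A", "B", "C"), s2 = c("B", "C"),
               s3 = c("B", "C", "D"))
  res <- shared_tf_intersection(sets)
  expect_setequal(res$intersection, c("B", "C"))
  expect_equal(sum(res$upset_counts$count),
               length(unique(unlist(sets))))

  res0 <- shared_tf_intersection(list(s1 = c("A", "B"), s2 = character(0)))
  expect_length(res0$intersection, 0)
  expect_error(shared_tf_intersection(list(a = "x")), "at least 2")
})

test_that("permutation sharing p-values hit their extremes", {
  lib <- build_motif_library(12, c(8, 10), 1.6, seed = 8)
  mm <- kmer_match_matrix(lib, k = 5, alpha = 0.01)
  # selections built from consensus windows of the same 4 motifs: sharing
  # far above the random expectation
  strong <- lapply(1:3, function(i)
    unique(unlist(lapply(lib[1:4], consensus_windows))))
  names(strong) <- paste0("sp", 1:3)
  res <- permutation_shared_pvalue(strong, lib, fraction = 0.02,
                                   n_perm = 50, seed = 2, match_matrix = mm)
  expect_gte(res$observed, 4)
  expect_equal(res$p_value, 0)
  expect_equal(res$p_value_add1, 1 / 51)

  # empty-ish selections can never beat the null
  weak <- list(sp1 = "AAAAA", sp2 = "CCCCC", sp3 = "GGGGG")
  res2 <- permutation_shared_pvalue(weak, lib, fraction = 0.05,
                                    n_perm = 50, seed = 2, match_matrix = mm)
  expect_equal(res2$p_value, 1)
})

test_that("Fisher's exact test reproduces hand and enumeration results", {
  # the shared-TF liver expression table
  tab <- matrix(c(26, 7, 89, 70), 2, 2, byrow = TRUE)
  res <- expression_fisher(tab, alternative = "greater")
  expect_equal(round(res$p_value, 3), 0.011)
  expect_equal(res$odds_ratio, (26 * 70) / (7 * 89))

  expect_equal(expression_fisher(c(1, 0, 0, 1))$p_value, 0.5)
  expect_error(expression_fisher(c(0, 0, 3, 4)), "degenerate")

  # enumeration oracle over all tables with fixed margins, total <= 20
  set.seed(33)
  for (rep in 1:40) {
    tot <- sample(4:20, 1)
    a <- sample(0:tot, 1); b <- sample(0:(tot - a), 1)
    cc <- sample(0:(tot - a - b), 1); d <- tot - a - b - cc
    if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) next
    got <- expression_fisher(c(a, b, cc, d), alternative = "greater")$p_value
    # enumerate all tables with the same margins
    r1 <- a + b; c1 <- a + cc
    support <- max(0, c1 - (cc + d)):min(r1, c1)
    probs <- choose(r1, support) * choose(cc + d, c1 - support) /
      choose(tot, c1)
    expect_equal(got, sum(probs[support >= a]), tolerance = 1e-12)
    ref <- stats::fisher.test(matrix(c(a, cc, b, d), 2, 2),
                              alternative = "greater")$p.value
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("binomial match-rate tail probabilities", {
  expect_equal(match_rate_binomial(52, 0, 0.277), 1)
  expect_equal(match_rate_binomial(1, 1, 0.5), 0.5)

  # the enhancer-associated match-rate comparison: 46.1% of 52 is 24
  p <- match_rate_binomial(52, 24, 0.277)
  expect_equal(p, sum(stats::dbinom(24:52, 52, 0.277)), tolerance = 1e-12)
  expect_lt(abs(p - 0.0035), 3e-4)

  expect_equal(match_rate_binomial(10, 2, 0.5, alternative = "less"),
               stats::pbinom(2, 10, 0.5))
})
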