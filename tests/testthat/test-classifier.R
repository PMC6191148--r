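# toy fixture: positives carry 3 planted copies of ACGTA, negatives are
# random background
make_toy <- function(n_pos = 200, n_neg = 2000, len = 100, seed = 31) {
  set.seed(seed)
  pos_seqs <- vapply(seq_len(n_pos), function(i) {
    s <- strsplit(random_dna(len), "")[[1]]
    for (off in sample(seq_len(len - 5), 3)) {
      s[off:(off + 4)] <- c("A", "C", "G", "T", "A")
    }
    paste(s, collapse = "")
  }, character(1))
  neg_seqs <- vapply(seq_len(n_neg), function(i) random_dna(len),
                     character(1))
  list(pos = normalize_rows(kmer_spectrum_matrix(pos_seqs, 5)),
       neg = normalize_rows(kmer_spectrum_matrix(neg_seqs, 5)))
}

toy <- function() fixture("toy_classifier_data", make_toy)

test_that("the planted k-mer earns a top-5% weight and training is deterministic", {
  d <- toy()
  m <- train_classifier(d$pos, d$neg, seed = 1)
  rank_acgta <- rank(-m$weights)[["ACGTA"]]
  expect_lte(rank_acgta, ceiling(0.05 * 1024))

  m2 <- train_classifier(d$pos, d$neg, seed = 1)
  expect_equal(m$weights, m2$weights, tolerance = 1e-9)
  expect_equal(m$bias, m2$bias, tolerance = 1e-9)

  expect_error(train_classifier(d$pos[1, , drop = FALSE], d$neg),
               "at least 2")
})

test_that("held-out discrimination of the toy signal is near perfect", {
  d <- toy()
  set.seed(7)
  ho_pos <- sample(nrow(d$pos), 20)
  ho_neg <- sample(nrow(d$neg), 200)
  m <- train_classifier(d$pos[-ho_pos, ], d$neg[-ho_neg, ], seed = 1)
  scores <- decision_scores(m, rbind(d$pos[ho_pos, ], d$neg[ho_neg, ]))
  labels <- rep(c(1, 0), c(20, 200))
  expect_gte(roc_auc(scores, labels), 0.95)
  expect_gt(mean(scores[labels == 1]), mean(scores[labels == 0]))
})

test_that("decision scores equal the exported weight dot product", {
  d <- toy()
  m <- train_classifier(d$pos[1:50, ], d$neg[1:100, ], seed = 1)
  X <- rbind(d$pos[1:5, ], d$neg[1:5, ])
  expect_equal(decision_scores(m, X),
               drop(X %*% m$weights + m$bias), tolerance = 1e-9)
  expect_equal(decision_scores(m, X[c(1, 1), ])[1],
               decision_scores(m, X[c(1, 1), ])[2])
  expect_error(decision_scores(m, X[, 1:100]), "dimension")

  # JSON round trip preserves the scoring function
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  back <- read_model_json(path)
  expect_equal(decision_scores(back, X), decision_scores(m, X),
               tolerance = 1e-9)
  expect_equal(back$class_weights, m$class_weights)
})

test_that("stratified cross-validation preserves fold structure and class ratio", {
  set.seed(41)
  pos <- random_features(100, k = 3, shift_cols = 1:6, shift = 1.5)
  neg <- random_features(1000, k = 3)
  cv <- cross_validate(pos, neg, folds = 10, seed = 5)
  expect_equal(as.integer(table(cv$fold_assignment$pos)), rep(10L, 10))
  expect_equal(as.integer(table(cv$fold_assignment$neg)), rep(100L, 10))
  expect_equal(cv$mean_auroc, mean(cv$auroc))
  expect_equal(cv$mean_aupr, mean(cv$aupr))
  expect_true(all(cv$auroc >= 0 & cv$auroc <= 1))
  expect_gte(cv$mean_auroc, 0.9)  # clear planted signal
  expect_error(cross_validate(pos[1:5, ], neg, folds = 10), "at least 10")

  # grouped folds: every matched cluster stays together
  groups <- rep(seq_len(100), each = 10)
  cvg <- cross_validate(pos, neg, folds = 10, seed = 5, neg_groups = groups)
  expect_identical(cvg$fold_assignment$neg,
                   cvg$fold_assignment$pos[groups])
  expect_equal(as.integer(table(cvg$fold_assignment$neg)), rep(100L, 10))
  expect_error(cross_validate(pos, neg, neg_groups = groups[1:5]),
               "every negative")
})

test_that("raising the positive class weight does not reduce recall at threshold zero", {
  set.seed(51)
  pos <- random_features(40, k = 3, shift_cols = 1:4, shift = 0.6)
  neg <- random_features(400, k = 3)
  recall_at0 <- function(w) {
    m <- train_classifier(pos, neg, class_weights = c(w, 1), seed = 1)
    mean(decision_scores(m, pos) > 0)
  }
  expect_gte(recall_at0(10), recall_at0(1))
})

test_that("linear SVM on unit spectra ranks like a cosine spectrum-kernel machine", {
  skip_if_not_installed("kernlab")
  # partial signal keeps the problem non-separable, so decision values
  # spread out and score rankings are informative
  set.seed(61)
  n <- 30
  seqs_pos <- vapply(seq_len(n), function(i) {
    s <- strsplit(random_dna(60), "")[[1]]
    if (runif(1) < 0.6) {
      off <- sample(57, 1); s[off:(off + 3)] <- c("G", "A", "T", "C")
    }
    paste(s, collapse = "")
  }, character(1))
  seqs_neg <- vapply(seq_len(n), function(i) random_dna(60), character(1))
  counts <- kmer_spectrum_matrix(c(seqs_pos, seqs_neg), 4)
  y <- factor(rep(c("positive", "negative"), each = n),
              levels = c("positive", "negative"))
  K <- spectrum_kernel_matrix(counts)
  km <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "C-svc",
                      C = 1, kernel = "matrix")
  kscore <- drop(kernlab::predict(km, kernlab::as.kernelMatrix(
    K[, kernlab::SVindex(km), drop = FALSE]), type = "decision"))
  if (stats::cor(as.numeric(kscore), as.numeric(y == "positive")) < 0)
    kscore <- -kscore

  m <- train_classifier(normalize_rows(counts[1:n, ]),
                        normalize_rows(counts[(n + 1):(2 * n), ]),
                        C = 1, class_weights = c(1, 1), seed = 1)
  lscore <- decision_scores(m, normalize_rows(counts))
  expect_gte(stats::cor(lscore, kscore), 0.999)
  expect_gte(stats::cor(rank(lscore), rank(kscore)), 0.98)
})
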