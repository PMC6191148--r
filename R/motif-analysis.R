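#' Select the top (or bottom) weighted k-mers of a model
#'
#' Orders k-mers by primal weight — descending for the enhancer-associated
#' (`positive`) direction, ascending for the background-associated
#' (`negative`) direction — and keeps the first
#' `ceiling(fraction * 4^k)`. Ties at the selection boundary are broken
#' lexicographically. With the defaults (k = 5, fraction 0.05) this is the
#' 52 most enhancer-associated 5-mers.
#'
#' @param model A `trained_linear_model`.
#' @param fraction Fraction of all 4^k k-mers to keep, in (0, 1\].
#' @param direction `"positive"` (enhancer-associated, default) or
#'   `"negative"` (background-associated).
#' @return An object of class `kmer_selection`: list with `direction`,
#'   `fraction`, and `kmers` (ordered character vector).
#' @export
select_top_kmers <- function(model, fraction = 0.05,
                             direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  stopifnot(inherits(model, "trained_linear_model"),
            fraction > 0, fraction <= 1)
  w <- model$weights
  n_keep <- ceiling(fraction * length(w))
  o <- if (direction == "positive") order(-w, names(w)) else
    order(w, names(w))
  structure(list(direction = direction, fraction = fraction,
                 kmers = names(w)[o][seq_len(n_keep)]),
            class = "kmer_selection")
}

#' @export
print.kmer_selection <- function(x, ...) {
  cat(sprintf("kmer_selection: %d %s-direction k-mers (top %.1f%%)\n",
              length(x$kmers), x$direction, 100 * x$fraction))
  invisible(x)
}

# log-likelihood-ratio scores of every k-mer against a PPM, maximized over
# all full-containment offsets and both strands of the k-mer. Columns of
# the PPM are floored at `floor_prob` before the log-ratio against the
# uniform background 0.25.
kmer_motif_scores <- function(motif, k, floor_prob = 0.01) {
  stopifnot(inherits(motif, "motif_model"))
  L <- log2(pmax(motif$matrix, floor_prob) / 0.25)   # 4 x width
  W <- motif$width
  kmers <- all_kmers(k)
  code <- t(vapply(strsplit(kmers, ""), function(x)
    match(x, DNA_BASES), integer(k)))                # 4^k x k base indices
  code_rc <- (5L - code)[, k:1, drop = FALSE]        # reverse complement
  short <- min(k, W)
  score_at <- function(cd, kmer_off, motif_off) {
    # sum over the aligned overlap of length `short`
    s <- numeric(nrow(cd))
    for (j in seq_len(short)) {
      s <- s + L[cbind(cd[, kmer_off + j], motif_off + j)]
    }
    s
  }
  best <- rep(-Inf, length(kmers))
  if (W >= k) {
    for (off in 0:(W - k)) {
      best <- pmax(best, score_at(code, 0L, off), score_at(code_rc, 0L, off))
    }
  } else {
    for (off in 0:(k - W)) {
      best <- pmax(best, score_at(code, off, 0L), score_at(code_rc, off, 0L))
    }
  }
  names(best) <- kmers
  best
}

#' Match one k-mer against a motif with an exact enumeration p-value
#'
#' Scores the k-mer against the motif's position probability matrix with a
#' log2 likelihood ratio versus the uniform background (cells floored at
#' 0.01), maximizing over all full-containment alignment offsets and both
#' strands of the k-mer. The p-value is exact: the fraction of all 4^k
#' k-mers whose best score is at least this k-mer's best score, so it
#' always lies on the grid `j / 4^k`, j = 1..4^k.
#'
#' @param kmer Character scalar over ACGT.
#' @param motif A `motif_model`.
#' @return An object of class `motif_match`: list with `kmer`, `motif_id`,
#'   `tf_name`, `best_score` (bits), `best_offset`, `best_strand`,
#'   `p_value`.
#' @export
match_kmer_to_motif <- function(kmer, motif) {
  k <- nchar(kmer)
  scores <- kmer_motif_scores(motif, k)
  s <- scores[[kmer]]
  p <- mean(scores >= s - 1e-12)
  # recover the argmax offset/strand for reporting
  L <- log2(pmax(motif$matrix, 0.01) / 0.25)
  W <- motif$width
  best <- list(score = -Inf, offset = 0L, strand = "+")
  for (strand in c("+", "-")) {
    km <- if (strand == "+") kmer else revcomp_chr(kmer)
    idx <- match(strsplit(km, "")[[1]], DNA_BASES)
    offs <- if (W >= k) 0:(W - k) else 0:(k - W)
    for (off in offs) {
      sc <- if (W >= k) sum(L[cbind(idx, off + seq_len(k))]) else
        sum(L[cbind(idx[off + seq_len(W)], seq_len(W))])
      if (sc > best$score) best <- list(score = sc, offset = off,
                                        strand = strand)
    }
  }
  structure(list(kmer = kmer, motif_id = motif$motif_id,
                 tf_name = motif$tf_name, best_score = s,
                 best_offset = best$offset, best_strand = best$strand,
                 p_value = p),
            class = "motif_match")
}

#' Precompute the k-mer x motif match indicator matrix
#'
#' For every motif in the library, computes the exact enumeration p-value
#' of every k-mer and thresholds at `alpha`. The resulting logical matrix
#' makes TF-set construction and the permutation null cheap.
#'
#' @param library A `motif_library`.
#' @param k Word length (default 5).
#' @param alpha Per-(k-mer, motif) match threshold on the exact p-value
#'   (default 0.02, i.e. the ~20 best-scoring k-mers of each motif).
#' @return Logical matrix, 4^k rows (named by k-mer) x motifs (named by
#'   motif id), with attribute `tf_names`.
#' @export
kmer_match_matrix <- function(library, k = 5L, alpha = 0.02) {
  stopifnot(inherits(library, "motif_library"))
  M <- vapply(library, function(m) {
    s <- kmer_motif_scores(m, k)
    # exact p: fraction of k-mers scoring >= each k-mer's score
    r <- rank(-s, ties.method = "max") / length(s)
    r <= alpha
  }, logical(4^k))
  rownames(M) <- all_kmers(k)
  attr(M, "tf_names") <- library_tf_names(library)
  attr(M, "alpha") <- alpha
  M
}

#' TFs matched by a k-mer selection
#'
#' A TF is matched when at least one of its motifs is matched by at least
#' one selected k-mer at exact p <= alpha (default 0.02). Distinct k-mers
#' may match the same TF. The default threshold is deliberately stricter
#' than a nominal 0.05: with exact enumeration p-values, p <= 0.05 admits
#' ~51 k-mers per motif, so a random 52-k-mer selection would match nearly
#' every motif in a library and TF-sharing statistics would saturate.
#'
#' @param selection A `kmer_selection` or character vector of k-mers.
#' @param library A `motif_library` (ignored when `match_matrix` given).
#' @param alpha Match threshold.
#' @param match_matrix Optional precomputed [kmer_match_matrix()].
#' @return Character vector of matched TF names (unique, sorted).
#' @export
matched_tf_set <- function(selection, library = NULL, alpha = 0.02,
                           match_matrix = NULL) {
  kmers <- if (inherits(selection, "kmer_selection")) selection$kmers else
    selection
  if (is.null(match_matrix)) {
    if (is.null(library) || length(library) == 0L) {
      stop("matched_tf_set needs a non-empty motif library or match matrix")
    }
    k <- if (length(kmers)) nchar(kmers[1]) else 5L
    match_matrix <- kmer_match_matrix(library, k = k, alpha = alpha)
  }
  if (length(kmers) == 0L) return(character(0))
  hit <- colSums(match_matrix[kmers, , drop = FALSE]) > 0L
  sort(unique(attr(match_matrix, "tf_names")[hit]))
}

#' Intersection and UpSet counts of per-species TF sets
#'
#' @param tf_sets Named list (>= 2) of TF name vectors.
#' @return List with `intersection` (TFs present in every set) and
#'   `upset_counts`, a data frame of exclusive membership combinations
#'   (one indicator column per set plus `count`); the counts partition the
#'   union of all sets.
#' @export
shared_tf_intersection <- function(tf_sets) {
  if (length(tf_sets) < 2L) stop("need at least 2 TF sets")
  universe <- sort(unique(unlist(tf_sets)))
  memb <- vapply(tf_sets, function(s) universe %in% s,
                 logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L,
                                             dimnames = list(NULL,
                                                             names(tf_sets)))
  inter <- if (length(universe)) universe[rowSums(memb) == length(tf_sets)]
  else character(0)
  if (length(universe)) {
    key <- apply(memb * 1L, 1L, paste, collapse = "")
    tab <- table(key)
    combos <- do.call(rbind, lapply(names(tab), function(kk)
      as.logical(as.integer(strsplit(kk, "")[[1]]))))
    upset <- as.data.frame(combos)
    names(upset) <- names(tf_sets)
    upset$count <- as.integer(tab)
  } else {
    upset <- data.frame(matrix(logical(0), 0, length(tf_sets),
                               dimnames = list(NULL, names(tf_sets))),
                        count = integer(0))
  }
  list(intersection = inter, upset_counts = upset)
}

#' Permutation null for the number of TFs shared across species
#'
#' The observed statistic is the number of TFs matched (at `alpha`) by the
#' selected k-mers of every species. The null draws, independently for each
#' species, a uniform random set of `ceiling(fraction * 4^k)` k-mers,
#' maps each to its TF set, and intersects — `n_perm` times. The empirical
#' p-value is reported in the plain `r / n` convention (which can be 0) and
#' as the never-zero `(r + 1) / (n + 1)` estimate.
#'
#' @param models Named list of `trained_linear_model` (one per species), or
#'   a named list of character k-mer vectors to use directly as selections.
#' @param library A `motif_library`.
#' @param fraction Selection fraction (default 0.05).
#' @param direction Selection direction when `models` are models.
#' @param alpha Match threshold.
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed for the permutation draws.
#' @param match_matrix Optional precomputed [kmer_match_matrix()]; computed
#'   from `library` otherwise.
#' @return List with `observed` (shared TF count), `observed_tfs`,
#'   `null_counts` (length `n_perm`), `p_value` (r/n), and `p_value_add1`
#'   ((r+1)/(n+1)).
#' @export
permutation_shared_pvalue <- function(models, library, fraction = 0.05,
                                      direction = "positive", alpha = 0.02,
                                      n_perm = 100L, seed = 1L,
                                      match_matrix = NULL) {
  stopifnot(n_perm >= 1L, length(models) >= 2L)
  if (is.null(match_matrix)) {
    k <- if (inherits(models[[1]], "trained_linear_model")) models[[1]]$k
    else nchar(models[[1]][1])
    match_matrix <- kmer_match_matrix(library, k = k, alpha = alpha)
  }
  tf_names <- attr(match_matrix, "tf_names")
  n_kmers <- nrow(match_matrix)
  selections <- lapply(models, function(m) {
    if (inherits(m, "trained_linear_model")) {
      select_top_kmers(m, fraction = fraction, direction = direction)$kmers
    } else as.character(m)
  })
  n_sel <- ceiling(fraction * n_kmers)
  tf_fac <- factor(tf_names)
  shared_count <- function(sel_list) {
    # TF-level: a TF counts when, in every species, at least one of its
    # motifs is matched by that species' selection
    shared <- rep(TRUE, nlevels(tf_fac))
    for (sel in sel_list) {
      motif_hit <- colSums(match_matrix[sel, , drop = FALSE]) > 0L
      shared <- shared & as.logical(tapply(motif_hit, tf_fac, any))
    }
    sum(shared)
  }
  obs_tfs <- Reduce(intersect, lapply(selections, matched_tf_set,
                                      match_matrix = match_matrix))
  observed <- shared_count(selections)
  set.seed(seed)
  null_counts <- vapply(seq_len(n_perm), function(i) {
    rand <- lapply(seq_along(selections), function(j)
      rownames(match_matrix)[sample.int(n_kmers, n_sel)])
    shared_count(rand)
  }, numeric(1L))
  r <- sum(null_counts >= observed)
  list(observed = observed, observed_tfs = obs_tfs,
       null_counts = null_counts,
       p_value = r / n_perm, p_value_add1 = (r + 1) / (n_perm + 1))
}

#' One-sided Fisher's exact test on a 2x2 contingency table
#'
#' Exact hypergeometric tail probability `P(X >= a)` conditional on the
#' table margins, for the one-sided ("greater") alternative that the first
#' row is enriched for the first column; the `two.sided` and `less`
#' alternatives are also available. The odds ratio is the sample odds ratio
#' `(a * d) / (b * c)` (may be `Inf`).
#'
#' The canonical use is the shared-TF expression table: rows = TF shared /
#' not shared across species, columns = expressed / not expressed in the
#' tissue.
#'
#' @param table 2x2 matrix or the counts `c(a, b, c, d)` in row-major
#'   order (a = shared & expressed).
#' @param alternative `"greater"` (default), `"less"`, or `"two.sided"`.
#' @return List with `odds_ratio` and `p_value`.
#' @examples
#' expression_fisher(matrix(c(26, 89, 7, 70), 2, 2, byrow = TRUE))
#' @export
expression_fisher <- function(table,
                              alternative = c("greater", "less",
                                              "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == c(2L, 2L)))
    a <- table[1, 1]; b <- table[1, 2]; cc <- table[2, 1]; d <- table[2, 2]
  } else {
    stopifnot(length(table) == 4L)
    a <- table[1]; b <- table[2]; cc <- table[3]; d <- table[4]
  }
  if (any(c(a, b, cc, d) < 0)) stop("counts must be nonnegative")
  if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) {
    stop("degenerate margin: a zero row or column total leaves the test undefined")
  }
  m <- a + cc       # column-1 total ("expressed")
  n <- b + d        # column-2 total
  kk <- a + b       # row-1 total ("shared")
  p <- switch(alternative,
    greater = stats::phyper(a - 1, m, n, kk, lower.tail = FALSE),
    less = stats::phyper(a, m, n, kk),
    two.sided = {
      support <- max(0, kk - n):min(kk, m)
      dens <- stats::dhyper(support, m, n, kk)
      sum(dens[dens <= stats::dhyper(a, m, n, kk) * (1 + 1e-7)])
    })
  or <- (a * d) / (b * cc)
  list(odds_ratio = or, p_value = p)
}

#' Build the shared-TF x expression contingency table
#'
#' @param shared_tfs TFs shared across all species' selections.
#' @param expression Expression data frame (`tf_name`, `tissue`,
#'   `expressed`).
#' @param tissue Tissue to test.
#' @param universe All TFs under consideration (default: every TF in
#'   `expression`).
#' @return 2x2 integer matrix, rows shared/not-shared, columns
#'   expressed/not-expressed.
#' @export
expression_contingency <- function(shared_tfs, expression, tissue,
                                   universe = NULL) {
  ex <- expression[expression$tissue == tissue, ]
  if (is.null(universe)) universe <- unique(ex$tf_name)
  expressed <- universe %in% ex$tf_name[ex$expressed == 1]
  shared <- universe %in% shared_tfs
  matrix(c(sum(shared & expressed), sum(shared & !expressed),
           sum(!shared & expressed), sum(!shared & !expressed)),
         2L, 2L, byrow = TRUE,
         dimnames = list(c("shared", "not_shared"),
                         c("expressed", "not_expressed")))
}

#' Exact binomial test of the TF-motif match rate
#'
#' Tests whether `n_matched` of `n` selected k-mers matching at least one
#' TF motif exceeds the background match rate `p0` (the rate over all 4^k
#' k-mers): exact tail `P(X >= n_matched | n, p0)` for the one-sided
#' "greater" alternative.
#'
#' @param n Number of selected k-mers.
#' @param n_matched Number matching at least one motif.
#' @param p0 Background match probability, in (0, 1).
#' @param alternative `"greater"` (default), `"less"`, or `"two.sided"`
#'   (twice the smaller tail, capped at 1).
#' @return The p-value.
#' @export
match_rate_binomial <- function(n, n_matched, p0,
                                alternative = c("greater", "less",
                                                "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(n_matched >= 0, n_matched <= n, p0 > 0, p0 < 1)
  upper <- stats::pbinom(n_matched - 1, n, p0, lower.tail = FALSE)
  lower <- stats::pbinom(n_matched, n, p0)
  switch(alternative,
         greater = upper,
         less = lower,
         two.sided = min(1, 2 * min(upper, lower)))
}

#' Full k-mer-to-library match table
#'
#' @param kmers Character vector of k-mers.
#' @param library A `motif_library`.
#' @return Data frame with one row per (k-mer, motif) pair: `kmer`,
#'   `motif_id`, `tf_name`, `score`, `offset`, `strand`, `p_value`.
#' @export
match_table <- function(kmers, library) {
  do.call(rbind, lapply(kmers, function(km) {
    do.call(rbind, lapply(library, function(m) {
      x <- match_kmer_to_motif(km, m)
      data.frame(kmer = x$kmer, motif_id = x$motif_id, tf_name = x$tf_name,
                 score = x$best_score, offset = x$best_offset,
                 strand = x$best_strand, p_value = x$p_value)
    }))
  }))
}
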