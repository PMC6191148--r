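#' All k-mers in lexicographic order
#'
#' The fixed feature naming used throughout: all 4^k DNA words of length k,
#' ordered lexicographically with A < C < G < T.
#'
#' @param k Word length (>= 1).
#' @return Character vector of length 4^k.
#' @export
all_kmers <- function(k) {
  stopifnot(k >= 1)
  mkAllStrings(DNA_BASES, k)
}

#' k-mer spectrum of a sequence
#'
#' Counts every occurrence (overlaps included) of each of the 4^k k-mers on
#' the literal strand; reverse complements are counted separately, i.e. a
#' k-mer and its reverse complement are distinct features. Windows
#' containing `N` are skipped, so the total count equals
#' `sum over N-free runs of max(run_length - k + 1, 0)`.
#'
#' @param seq A `DNAString`, `DNAStringSet` of length 1, or character scalar.
#' @param k Word length (default 5).
#' @return An object of class `kmer_spectrum`: list with `k` and `counts`,
#'   an integer vector of length 4^k named by [all_kmers()].
#' @examples
#' kmer_spectrum("ACGTA", 2)$counts[c("AC", "CG", "GT", "TA")]
#' @export
kmer_spectrum <- function(seq, k = 5L) {
  if (is.character(seq)) seq <- DNAString(seq)
  if (is(seq, "DNAStringSet")) seq <- seq[[1L]]
  if (length(seq) < k) {
    stop("degenerate input: sequence length ", length(seq), " < k = ", k)
  }
  counts <- oligonucleotideFrequency(seq, width = k)
  structure(list(k = as.integer(k), counts = counts), class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("kmer_spectrum: k = %d, %d windows counted, %d distinct k-mers\n",
              x$k, sum(x$counts), sum(x$counts > 0)))
  invisible(x)
}

#' k-mer spectrum matrix for a set of sequences
#'
#' @param seqs A `DNAStringSet` or character vector.
#' @param k Word length (default 5).
#' @return Integer matrix, one row per sequence, 4^k columns named by
#'   [all_kmers()].
#' @export
kmer_spectrum_matrix <- function(seqs, k = 5L) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  if (any(width(seqs) < k)) {
    stop("degenerate input: ", sum(width(seqs) < k),
         " sequence(s) shorter than k = ", k)
  }
  m <- oligonucleotideFrequency(seqs, width = k, simplify.as = "matrix")
  rownames(m) <- names(seqs)
  m
}

#' Normalize a k-mer spectrum to the unit sphere
#'
#' Divides the count vector by its Euclidean norm, so that the linear kernel
#' between normalized spectra equals the cosine similarity of the raw
#' spectra. An all-zero spectrum (possible only for all-N input) maps to the
#' all-zero vector and is flagged degenerate.
#'
#' @param s A `kmer_spectrum`, or a numeric vector of counts.
#' @return An object of class `feature_vector`: list with `k`, `values`
#'   (norm 1, or all zero), and `degenerate` flag.
#' @export
normalize_spectrum <- function(s) {
  if (inherits(s, "kmer_spectrum")) {
    k <- s$k; counts <- s$counts
  } else {
    counts <- s
    k <- as.integer(round(log(length(counts), 4)))
  }
  nrm <- sqrt(sum(as.numeric(counts)^2))
  if (nrm == 0) {
    return(structure(list(k = k, values = as.numeric(counts) * 0,
                          degenerate = TRUE), class = "feature_vector"))
  }
  v <- as.numeric(counts) / nrm
  names(v) <- names(counts)
  structure(list(k = k, values = v, degenerate = FALSE),
            class = "feature_vector")
}

#' Row-normalize a spectrum matrix to the unit sphere
#'
#' @param m Matrix of k-mer counts (rows = sequences).
#' @return Numeric matrix with unit-norm rows (all-zero rows left at zero).
#' @export
normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

#' Cosine spectrum kernel between two feature vectors
#'
#' The spectrum kernel with unit-sphere normalization: the dot product of
#' the two unit-normalized spectra, i.e. the cosine similarity of the raw
#' k-mer count vectors.
#'
#' @param a,b `feature_vector` objects with equal `k`.
#' @return Similarity in \[0, 1\].
#' @export
spectrum_kernel <- function(a, b) {
  stopifnot(inherits(a, "feature_vector"), inherits(b, "feature_vector"))
  if (a$k != b$k) stop("mismatched k: ", a$k, " vs ", b$k)
  sum(a$values * b$values)
}

#' Cosine spectrum kernel matrix
#'
#' @param A,B Matrices of raw k-mer counts (rows = sequences); `B` defaults
#'   to `A`.
#' @return `nrow(A) x nrow(B)` matrix of cosine similarities.
#' @export
spectrum_kernel_matrix <- function(A, B = A) {
  tcrossprod(normalize_rows(A), normalize_rows(B))
}

#' Build unit-normalized k-mer features for intervals
#'
#' Convenience wrapper: extract interval sequences from a genome, count
#' k-mers, and normalize each row to the unit sphere.
#'
#' @param genome Named `DNAStringSet`.
#' @param intervals `GRanges`.
#' @param k Word length (default 5).
#' @return Numeric matrix of unit-norm rows, 4^k columns.
#' @export
featurize_intervals <- function(genome, intervals, k = 5L) {
  normalize_rows(kmer_spectrum_matrix(extract_sequences(genome, intervals), k))
}

#' Export a k-mer spectrum as TSV
#'
#' @param s A `kmer_spectrum`.
#' @param path Output path; columns `kmer`, `count`.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(s, path) {
  stopifnot(inherits(s, "kmer_spectrum"))
  write.table(data.frame(kmer = names(s$counts), count = as.integer(s$counts)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
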