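#' @importFrom stats runif rnorm rbinom uniroot setNames
#' @importFrom utils head read.table write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a transcription-factor motif model
#'
#' A motif model is a position probability matrix (PPM) over the DNA alphabet
#' together with identifiers and the consensus sequence. The matrix has four
#' rows (A, C, G, T) and one column per motif position; every column sums
#' to 1 and every cell is strictly inside (0, 1). The consensus is the
#' per-column argmax base, with ties resolved in alphabetical order
#' (A < C < G < T).
#'
#' @param motif_id Character scalar, unique motif identifier.
#' @param tf_name Character scalar, name of the transcription factor the
#'   motif belongs to.
#' @param matrix Numeric matrix, 4 x width, rows in A,C,G,T order; each
#'   column a probability distribution.
#' @return An object of class `motif_model` with fields `motif_id`,
#'   `tf_name`, `width`, `matrix` and `consensus`.
#' @export
motif_model <- function(motif_id, tf_name, matrix) {
  stopifnot(is.character(motif_id), length(motif_id) == 1L,
            is.character(tf_name), length(tf_name) == 1L,
            is.matrix(matrix), nrow(matrix) == 4L)
  if (ncol(matrix) < 5L) {
    stop("motif width must be >= 5, got ", ncol(matrix))
  }
  if (any(matrix <= 0) || any(matrix >= 1)) {
    stop("motif probabilities must lie strictly in (0, 1)")
  }
  csums <- colSums(matrix)
  if (any(abs(csums - 1) > 1e-9)) {
    stop("motif matrix columns must sum to 1 (max deviation ",
         format(max(abs(csums - 1))), ")")
  }
  rownames(matrix) <- DNA_BASES
  structure(
    list(motif_id = motif_id, tf_name = tf_name, width = ncol(matrix),
         matrix = matrix, consensus = ppm_consensus(matrix)),
    class = "motif_model"
  )
}

# argmax base per column; which.max takes the first maximum, and rows are in
# A,C,G,T order, so ties resolve alphabetically.
ppm_consensus <- function(mat) {
  paste(DNA_BASES[apply(mat, 2L, which.max)], collapse = "")
}

#' Per-column information content of a motif
#'
#' Information content of column j is `2 - H(p_j)` bits, where `H` is the
#' Shannon entropy (base 2) of the column's base distribution.
#'
#' @param motif A `motif_model`.
#' @return Numeric vector of length `motif$width`, bits per column.
#' @export
motif_information_content <- function(motif) {
  stopifnot(inherits(motif, "motif_model"))
  p <- motif$matrix
  2 + colSums(p * log2(p))
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model %s (%s): width %d, consensus %s, mean IC %.2f bits\n",
              x$motif_id, x$tf_name, x$width, x$consensus,
              mean(motif_information_content(x))))
  invisible(x)
}

# Solve for the dominant-base probability giving a column information
# content of `ic` bits, with the three other bases sharing the remainder.
dominant_prob_for_ic <- function(ic) {
  stopifnot(ic > 0, ic <= 2)
  col_ic <- function(p) {
    q <- (1 - p) / 3
    2 + p * log2(p) + 3 * q * log2(q)
  }
  upper <- 0.9995
  if (ic >= col_ic(upper)) return(upper)
  uniroot(function(p) col_ic(p) - ic, c(0.2501, upper), tol = 1e-10)$root
}

#' Build a synthetic motif library
#'
#' Generates `n_motifs` position probability matrices with widths drawn
#' uniformly from `width_range` and per-column information content
#' scattered around `info_content_target`. Each column has one dominant
#' base whose probability is solved so the column attains its target
#' information content; the remaining mass is split evenly. Every motif is
#' assigned to a distinct transcription factor.
#'
#' @param n_motifs Number of motifs (>= 1).
#' @param width_range Integer vector of length 2 within \[5, 30\]:
#'   inclusive range of motif widths.
#' @param info_content_target Target mean information content in bits per
#'   column, in (0, 2\].
#' @param seed Integer seed; the same call with the same seed returns an
#'   identical library.
#' @return An object of class `motif_library`: a list of `motif_model`
#'   objects named by `motif_id`.
#' @examples
#' lib <- build_motif_library(5, width_range = c(6, 10),
#'                            info_content_target = 1.5, seed = 1)
#' sapply(lib, function(m) m$width)
#' @export
build_motif_library <- function(n_motifs, width_range = c(8, 12),
                                info_content_target = 1.5, seed = 1) {
  if (!(is.numeric(n_motifs) && length(n_motifs) == 1L && n_motifs >= 1)) {
    stop("n_motifs must be a single integer >= 1")
  }
  if (length(width_range) != 2L || width_range[1] > width_range[2] ||
      width_range[1] < 5 || width_range[2] > 30) {
    stop("width_range must be an increasing pair within [5, 30]")
  }
  if (info_content_target <= 0 || info_content_target > 2) {
    stop("info_content_target must lie in (0, 2]")
  }
  set.seed(seed)
  n_motifs <- as.integer(n_motifs)
  ids <- sprintf("M%03d", seq_len(n_motifs))
  tfs <- sprintf("TF%03d", seq_len(n_motifs))
  motifs <- vector("list", n_motifs)
  widths_avail <- width_range[1]:width_range[2]
  for (i in seq_len(n_motifs)) {
    w <- widths_avail[sample.int(length(widths_avail), 1L)]
    # jitter per-column IC around the target, clamped away from 0 and 2
    ic <- pmin(1.995, pmax(0.05,
                           info_content_target + runif(w, -0.15, 0.15)))
    mat <- vapply(seq_len(w), function(j) {
      p <- dominant_prob_for_ic(ic[j])
      col <- rep((1 - p) / 3, 4L)
      col[sample.int(4L, 1L)] <- p
      col
    }, numeric(4L))
    motifs[[i]] <- motif_model(ids[i], tfs[i], mat)
  }
  names(motifs) <- ids
  structure(motifs, class = "motif_library")
}

#' @export
print.motif_library <- function(x, ...) {
  ic <- mean(unlist(lapply(x, motif_information_content)))
  cat(sprintf("motif_library: %d motifs, widths %d-%d, mean IC %.2f bits/column\n",
              length(x), min(vapply(x, `[[`, 1L, "width")),
              max(vapply(x, `[[`, 1L, "width")), ic))
  invisible(x)
}

#' @export
`[.motif_library` <- function(x, i) {
  structure(NextMethod(), class = "motif_library")
}

#' TF names of a motif library
#' @param library A `motif_library`.
#' @return Character vector of the library's TF names (one per motif).
#' @export
library_tf_names <- function(library) {
  unname(vapply(library, `[[`, character(1L), "tf_name"))
}

#' Write a motif library in MEME motif format (version 4)
#'
#' @param library A `motif_library`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(library, path) {
  stopifnot(inherits(library, "motif_library"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25000 C 0.25000 G 0.25000 T 0.25000", ""), con)
  for (m in library) {
    writeLines(sprintf("MOTIF %s %s", m$motif_id, m$tf_name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", m$width),
      con)
    writeLines(apply(m$matrix, 2L, function(col)
      paste(sprintf("%.6f", col), collapse = "  ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a motif library from MEME motif format
#'
#' Parses the minimal MEME v4 motif format subset written by [write_meme()]:
#' `MOTIF id name` headers followed by a `letter-probability matrix:` line
#' and one row of four probabilities per motif position. Columns are
#' renormalized to sum exactly to 1 (the text format rounds).
#'
#' @param path Path to a MEME motif file.
#' @return A `motif_library`.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  hits <- grep("^MOTIF\\s+", lines)
  if (length(hits) == 0L) stop("no MOTIF records found in ", path)
  motifs <- lapply(hits, function(i) {
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    motif_id <- hdr[2]
    tf_name <- if (length(hdr) >= 3L) hdr[3] else hdr[2]
    j <- i + 1L
    while (j <= length(lines) &&
           !grepl("^letter-probability matrix", lines[j])) j <- j + 1L
    if (j > length(lines)) stop("motif ", motif_id, " has no probability matrix")
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
    rows <- lines[(j + 1L):(j + w)]
    mat <- vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4L))
    mat <- sweep(mat, 2L, colSums(mat), "/")  # renormalize text rounding
    dimnames(mat) <- NULL
    motif_model(motif_id, tf_name, mat)
  })
  names(motifs) <- vapply(motifs, `[[`, character(1L), "motif_id")
  structure(motifs, class = "motif_library")
}
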