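#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet letterFrequency subseq reverseComplement
#'   oligonucleotideFrequency mkAllStrings
NULL

#' Build genomic intervals from 0-based half-open coordinates
#'
#' Interval sets throughout the package are `GRanges` objects. File formats
#' (BED) and this constructor use the BED convention — 0-based start,
#' exclusive end — while the `GRanges` representation is 1-based closed, as
#' usual in Bioconductor. Strand is ignored for regions (always `*`).
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive starts.
#' @param end Integer vector, exclusive ends; must satisfy `start < end`.
#' @param name Optional character vector of interval names.
#' @return A `GRanges` object.
#' @examples
#' genomic_intervals("chr1", 0, 100)   # first 100 bp of chr1
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL) {
  if (any(start < 0) || any(start >= end)) {
    stop("intervals require 0 <= start < end")
  }
  gr <- GRanges(chrom, IRanges(start = start + 1L, end = end))
  if (!is.null(name)) mcols(gr)$name <- name
  gr
}

#' Read intervals from a BED file
#'
#' BED3/BED6 reader (columns beyond the sixth are ignored); coordinates are
#' converted from the BED 0-based half-open convention.
#'
#' @param path Path to a BED file.
#' @return A `GRanges`, with a `name` metadata column when present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  strand(gr) <- "*"
  gr
}

#' Write intervals to a BED6 file
#'
#' Score is written as 0 and strand as "."; the `name` metadata column is
#' used when present.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(seqnames(gr)),
    start = start(gr) - 1L,
    end = end(gr),
    name = if (!is.null(mcols(gr)$name)) mcols(gr)$name
    else rep(".", length(gr)),
    score = rep(0L, length(gr)),
    strand = rep(".", length(gr))
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genome FASTA
#'
#' Line-wrapping-tolerant FASTA reader; sequences are uppercased on load and
#' names truncated at the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  x <- readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  DNAStringSet(toupper(x))
}

#' Write sequences to FASTA
#' @param seqs A named `DNAStringSet`.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Extract interval sequences from a genome
#'
#' @param genome A named `DNAStringSet` (one entry per chromosome).
#' @param intervals A `GRanges`; every seqname must be a genome entry and
#'   every interval must lie within its chromosome.
#' @return A `DNAStringSet`, one record per interval, in input order; record
#'   `i` has width equal to the width of interval `i`.
#' @export
extract_sequences <- function(genome, intervals) {
  chroms <- as.character(seqnames(intervals))
  bad <- !(chroms %in% names(genome))
  if (any(bad)) {
    i <- which(bad)[1]
    stop("unknown chromosome '", chroms[i], "' for interval ",
         chroms[i], ":", start(intervals)[i] - 1L, "-", end(intervals)[i])
  }
  lens <- width(genome)[match(chroms, names(genome))]
  oob <- end(intervals) > lens | start(intervals) < 1L
  if (any(oob)) {
    i <- which(oob)[1]
    stop("interval out of bounds: ", chroms[i], ":",
         start(intervals)[i] - 1L, "-", end(intervals)[i],
         " (chromosome length ", lens[i], ")")
  }
  out <- DNAStringSet(lapply(seq_along(intervals), function(i) {
    subseq(genome[[chroms[i]]], start(intervals)[i], end(intervals)[i])
  }))
  names(out) <- if (!is.null(mcols(intervals)$name)) mcols(intervals)$name
  else paste0(chroms, ":", start(intervals) - 1L, "-", end(intervals))
  out
}

#' GC content of sequences
#'
#' Fraction (G + C) / (A + C + G + T). `N` bases are excluded from both the
#' numerator and the denominator, so assembly gaps do not bias GC matching.
#' Sequences with no unambiguous base have undefined GC and yield `NA` with
#' a warning.
#'
#' @param seqs A `DNAStringSet`, `DNAString`, or character vector.
#' @return Numeric vector of GC fractions in \[0, 1\] (or `NA`).
#' @examples
#' gc_content(c("GGCC", "ATAT", "ACGT"))  # 1, 0, 0.5
#' @export
gc_content <- function(seqs) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  if (is(seqs, "DNAString")) seqs <- DNAStringSet(list(seqs))
  counts <- letterFrequency(seqs, DNA_BASES)
  denom <- rowSums(counts)
  if (any(denom == 0)) {
    warning("sequence(s) with no unambiguous bases: GC content undefined (NA)")
  }
  ifelse(denom == 0, NA_real_, (counts[, "G"] + counts[, "C"]) / denom)
}

#' Fraction of an interval covered by repeats
#'
#' Computes, for each query interval, the number of base pairs overlapped by
#' the union of the repeat intervals, divided by the query length. Union
#' semantics make the result invariant to how the repeat set is fragmented.
#'
#' @param x Query `GRanges`.
#' @param repeats Repeat `GRanges` (same assembly).
#' @return Numeric vector of overlap fractions in \[0, 1\], one per query.
#' @export
repeat_overlap_fraction <- function(x, repeats) {
  if (length(repeats) == 0L) return(rep(0, length(x)))
  rep_u <- reduce(repeats, ignore.strand = TRUE)
  # different chromosome universes are legitimate here (e.g. repeat-free
  # chromosomes); silence the no-common-seqlevels notice
  hits <- suppressWarnings(findOverlaps(x, rep_u, ignore.strand = TRUE))
  ov <- suppressWarnings(
    width(pintersect(x[queryHits(hits)], rep_u[subjectHits(hits)])))
  out <- rep(0, length(x))
  agg <- tapply(ov, queryHits(hits), sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out / width(x)
}

#' Subtract exclusion regions from an interval set
#'
#' Removes any interval that overlaps an exclusion region (assembly gaps,
#' blacklist) by at least 1 bp. Used to clean candidate regions before
#' sampling.
#'
#' @param x A `GRanges`.
#' @param exclusions A `GRanges` of regions to avoid (may be empty/NULL).
#' @return The subset of `x` overlapping no exclusion, order preserved.
#' @export
drop_excluded <- function(x, exclusions) {
  if (is.null(exclusions) || length(exclusions) == 0L) return(x)
  x[suppressWarnings(countOverlaps(x, exclusions, ignore.strand = TRUE)) == 0L]
}

#' Remove orthologous intervals from two species' sets
#'
#' Given an ortholog map of paired intervals, removes from `set_a` every
#' interval overlapping (>= 1 bp) the A-side of a mapped pair whose B-side
#' overlaps `set_b`, and symmetrically for `set_b`. This is the control that
#' rules out trivial cross-species generalization through enhancers shared
#' by descent: such regions are excluded from both the training and the
#' testing set.
#'
#' @param set_a,set_b `GRanges` for species A and B.
#' @param ortholog_map Data frame with columns `chrom_a`, `start_a`, `end_a`,
#'   `chrom_b`, `start_b`, `end_b` (0-based half-open), optionally
#'   `species_a`/`species_b`; see [ortholog_map_pairs()].
#' @param species_a,species_b Optional species names used to subset (and
#'   orient) the map when it covers several species pairs.
#' @return List with elements `a` and `b`: the filtered sets, input order
#'   preserved.
#' @export
filter_orthologous <- function(set_a, set_b, ortholog_map,
                               species_a = NULL, species_b = NULL) {
  if (!is.null(species_a) && !is.null(species_b)) {
    ortholog_map <- ortholog_map_pairs(ortholog_map, species_a, species_b)
  }
  if (is.null(ortholog_map) || nrow(ortholog_map) == 0L) {
    return(list(a = set_a, b = set_b))
  }
  map_a <- genomic_intervals(ortholog_map$chrom_a, ortholog_map$start_a,
                             ortholog_map$end_a)
  map_b <- genomic_intervals(ortholog_map$chrom_b, ortholog_map$start_b,
                             ortholog_map$end_b)
  # a pair is live when both of its sides touch the respective sets
  live <- suppressWarnings(
    countOverlaps(map_a, set_a, ignore.strand = TRUE) > 0L &
      countOverlaps(map_b, set_b, ignore.strand = TRUE) > 0L)
  suppressWarnings(list(
    a = set_a[countOverlaps(set_a, map_a[live], ignore.strand = TRUE) == 0L],
    b = set_b[countOverlaps(set_b, map_b[live], ignore.strand = TRUE) == 0L]
  ))
}

#' Orient an ortholog map for a species pair
#'
#' Subsets a multi-species ortholog map to the rows connecting two species,
#' flipping rows recorded in the opposite orientation so that the returned
#' map always has `species_a` on the A side. Lookup therefore works from
#' either side of a recorded pair.
#'
#' @param ortholog_map Data frame with columns `species_a`, `chrom_a`,
#'   `start_a`, `end_a`, `species_b`, `chrom_b`, `start_b`, `end_b`.
#' @param species_a,species_b Species names.
#' @return The oriented subset of the map (possibly 0 rows).
#' @export
ortholog_map_pairs <- function(ortholog_map, species_a, species_b) {
  fwd <- ortholog_map$species_a == species_a &
    ortholog_map$species_b == species_b
  rev <- ortholog_map$species_a == species_b &
    ortholog_map$species_b == species_a
  flipped <- ortholog_map[rev, ]
  if (nrow(flipped) > 0L) {
    flipped <- data.frame(
      species_a = flipped$species_b, chrom_a = flipped$chrom_b,
      start_a = flipped$start_b, end_a = flipped$end_b,
      species_b = flipped$species_a, chrom_b = flipped$chrom_a,
      start_b = flipped$start_a, end_b = flipped$end_a
    )
  }
  out <- rbind(ortholog_map[fwd, c("species_a", "chrom_a", "start_a", "end_a",
                                   "species_b", "chrom_b", "start_b", "end_b")],
               flipped)
  rownames(out) <- NULL
  out
}
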