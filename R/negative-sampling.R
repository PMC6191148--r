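#' Specification for matched negative-region sampling
#'
#' @param mode One of `"length_chrom"` (match length and chromosome),
#'   `"gc"` (additionally match GC content), `"gc_repeat"` (additionally
#'   match repeat-overlap proportion), or `"flanking"` (sample from the
#'   enhancer's flanking region).
#' @param ratio Negatives per positive (default 10, the imbalanced design
#'   reflecting that enhancers are a small portion of the genome).
#' @param gc_tolerance Maximum absolute GC difference from the seed
#'   enhancer, `gc` and `gc_repeat` modes (default 0.02).
#' @param repeat_tolerance Maximum absolute difference in repeat-overlap
#'   fraction, `gc_repeat` mode (default 0.05).
#' @param flank_multiplier Flank size in units of the enhancer length on
#'   either side (default 10).
#' @param max_attempts Candidate positions tried per required negative
#'   before the tolerance is relaxed (doubled once) and, failing that, an
#'   error is raised.
#' @param seed Integer seed for the sampler.
#' @return An object of class `sampling_spec`.
#' @export
sampling_spec <- function(mode = c("length_chrom", "gc", "gc_repeat",
                                   "flanking"),
                          ratio = 10L, gc_tolerance = 0.02,
                          repeat_tolerance = 0.05, flank_multiplier = 10L,
                          max_attempts = 500L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(ratio >= 1, flank_multiplier >= 1, max_attempts >= 1)
  if (gc_tolerance <= 0 || gc_tolerance >= 0.5 ||
      repeat_tolerance <= 0 || repeat_tolerance >= 0.5) {
    stop("tolerances must lie in (0, 0.5)")
  }
  structure(list(mode = mode, ratio = as.integer(ratio),
                 gc_tolerance = gc_tolerance,
                 repeat_tolerance = repeat_tolerance,
                 flank_multiplier = as.integer(flank_multiplier),
                 max_attempts = as.integer(max_attempts),
                 seed = as.integer(seed)),
            class = "sampling_spec")
}

# occupancy bookkeeping: per-chromosome start/end vectors (1-based closed)
occupancy_from_granges <- function(grs, chroms) {
  occ <- setNames(lapply(chroms, function(x)
    list(s = integer(0), e = integer(0))), chroms)
  for (gr in grs) {
    if (is.null(gr) || length(gr) == 0L) next
    ch <- as.character(seqnames(gr))
    for (ci in unique(ch)) {
      sel <- ch == ci
      occ[[ci]]$s <- c(occ[[ci]]$s, start(gr)[sel])
      occ[[ci]]$e <- c(occ[[ci]]$e, end(gr)[sel])
    }
  }
  occ
}

overlaps_occ <- function(occ_chrom, s, e) {
  # vectorized over candidates s, e
  if (length(occ_chrom$s) == 0L) return(rep(FALSE, length(s)))
  vapply(seq_along(s), function(i)
    any(s[i] <= occ_chrom$e & e[i] >= occ_chrom$s), logical(1L))
}

# cumulative GC / unambiguous-base counts for O(1) window GC lookups
gc_cumsums <- function(chrom_seq) {
  x <- strsplit(as.character(chrom_seq), "")[[1]]
  list(gc = cumsum(x == "G" | x == "C"),
       acgt = cumsum(x %in% DNA_BASES))
}

# GC of every length-L window of a chromosome, from gc_cumsums()
window_gc <- function(cs, L) {
  n <- length(cs$gc)
  num <- cs$gc[L:n] - c(0, cs$gc)[seq_len(n - L + 1L)]
  den <- cs$acgt[L:n] - c(0, cs$acgt)[seq_len(n - L + 1L)]
  ifelse(den == 0, NA_real_, num / den)
}

# repeat-overlap fraction of candidate windows (one chromosome)
candidate_repfrac <- function(rep_ranges, s, L) {
  if (is.null(rep_ranges) || length(rep_ranges) == 0L) {
    return(rep(0, length(s)))
  }
  q <- IRanges(start = s, width = L)
  hits <- findOverlaps(q, rep_ranges)
  ov <- width(pintersect(q[queryHits(hits)], rep_ranges[subjectHits(hits)]))
  out <- rep(0, length(s))
  agg <- tapply(ov, queryHits(hits), sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out / L
}

#' Sample matched genomic-background negatives
#'
#' For every enhancer, draws `ratio` random genomic regions of the same
#' length on the same chromosome that overlap no enhancer, no exclusion
#' region, and no other sampled negative. In `gc` mode, candidates must
#' additionally match the seed enhancer's GC content within
#' `gc_tolerance`; in `gc_repeat` mode the repeat-overlap fraction must
#' also match within `repeat_tolerance`. If a quota cannot be filled within
#' `max_attempts` candidates, the tolerance is doubled once with a warning;
#' if it still cannot, an error names the offending enhancer.
#'
#' @param enhancers `GRanges` of positive regions (a `name` column is used
#'   to record seeds, else names are generated).
#' @param genome Named `DNAStringSet` covering all chromosomes.
#' @param repeats `GRanges` of repeat elements (required for `gc_repeat`).
#' @param exclusions Optional `GRanges` of regions negatives must avoid
#'   (assembly gaps, blacklist).
#' @param spec A [sampling_spec()] with mode `length_chrom`, `gc`, or
#'   `gc_repeat`.
#' @return `GRanges` of `ratio * length(enhancers)` negatives with a
#'   `seed_enhancer` metadata column.
#' @export
sample_matched_negatives <- function(enhancers, genome, repeats = NULL,
                                     exclusions = NULL,
                                     spec = sampling_spec()) {
  stopifnot(inherits(spec, "sampling_spec"))
  if (!spec$mode %in% c("length_chrom", "gc", "gc_repeat")) {
    stop("spec$mode must be length_chrom, gc or gc_repeat (got ",
         spec$mode, "); use sample_flanking_negatives() for flanking mode")
  }
  set.seed(spec$seed)
  chroms <- names(genome)
  occ <- occupancy_from_granges(list(enhancers, exclusions), chroms)
  enh_names <- if (!is.null(mcols(enhancers)$name)) mcols(enhancers)$name
  else sprintf("enh%04d", seq_along(enhancers))

  need_gc <- spec$mode %in% c("gc", "gc_repeat")
  need_rep <- spec$mode == "gc_repeat"
  if (need_rep && is.null(repeats)) {
    stop("gc_repeat mode requires a repeats interval set")
  }
  rep_by_chrom <- NULL
  if (need_rep) {
    rep_red <- reduce(repeats, ignore.strand = TRUE)
    rep_by_chrom <- setNames(lapply(chroms, function(ci)
      ranges(rep_red[as.character(seqnames(rep_red)) == ci])), chroms)
    enh_repfrac <- repeat_overlap_fraction(enhancers, repeats)
  }
  if (need_gc) {
    enh_gc <- gc_content(extract_sequences(genome, enhancers))
    # cumulative counts make window GC an O(1) lookup, so GC matching
    # enumerates the genuinely matching starts instead of rejection-sampling
    cums <- lapply(genome, gc_cumsums)
  }

  res_chrom <- character(0); res_start <- integer(0); res_len <- integer(0)
  res_seed <- character(0)

  for (i in seq_along(enhancers)) {
    ci <- as.character(seqnames(enhancers))[i]
    L <- width(enhancers)[i]
    clen <- width(genome)[match(ci, chroms)]
    gc_tol <- spec$gc_tolerance
    rep_tol <- spec$repeat_tolerance
    got_s <- integer(0)
    relaxed <- FALSE
    # one pass over a candidate stream: chunked overlap/repeat filtering
    # plus greedy non-overlapping acceptance
    consume <- function(cand, got_s) {
      chunk <- 512L
      pos <- 1L
      while (length(got_s) < spec$ratio && pos <= length(cand)) {
        idx <- pos:min(pos + chunk - 1L, length(cand))
        pos <- pos + chunk
        s <- cand[idx]
        e <- s + L - 1L
        keep <- !overlaps_occ(occ[[ci]], s, e)
        if (need_rep && any(keep)) {
          rf <- candidate_repfrac(rep_by_chrom[[ci]], s[keep], L)
          keep[keep] <- abs(rf - enh_repfrac[i]) <= rep_tol
        }
        for (j in which(keep)) {
          if (length(got_s) >= spec$ratio) break
          if (any(s[j] <= (got_s + L - 1L) & e[j] >= got_s)) next
          got_s <- c(got_s, s[j])
        }
      }
      got_s
    }
    repeat {
      if (need_gc) {
        # enumerate genuinely matching starts rather than rejection-sample,
        # and take nearest-GC candidates first (caliper matching with
        # nearest neighbours, random among ties). Uniform selection inside
        # the band would leave a systematic offset towards the genome GC
        # and a wider GC spread than the positives, both of which a
        # classifier can read as residual signal.
        wgc <- window_gc(cums[[ci]], L)
        cand <- which(!is.na(wgc) & abs(wgc - enh_gc[i]) <= gc_tol)
        if (length(cand) > 1L) {
          cand <- cand[sample.int(length(cand))]
          cand <- cand[order(abs(wgc[cand] - enh_gc[i]))]  # stable: ties random
        }
      } else {
        cand <- sample.int(clen - L + 1L,
                           spec$max_attempts * spec$ratio, replace = TRUE)
      }
      got_s <- consume(cand, got_s)
      if (length(got_s) >= spec$ratio) break
      if (!relaxed) {
        relaxed <- TRUE
        gc_tol <- 2 * gc_tol
        rep_tol <- 2 * rep_tol
        warning("relaxing matching tolerance for enhancer ", enh_names[i],
                " (", spec$mode, " mode)", call. = FALSE)
      } else {
        stop("sampling failure: could not find ", spec$ratio,
             " matched negatives for enhancer ", enh_names[i],
             " (mode ", spec$mode, ")",
             if (need_gc) " even after relaxing tolerances" else "")
      }
    }
    # commit accepted negatives to the occupancy index
    occ[[ci]]$s <- c(occ[[ci]]$s, got_s)
    occ[[ci]]$e <- c(occ[[ci]]$e, got_s + L - 1L)
    res_chrom <- c(res_chrom, rep(ci, spec$ratio))
    res_start <- c(res_start, got_s)
    res_len <- c(res_len, rep(L, spec$ratio))
    res_seed <- c(res_seed, rep(enh_names[i], spec$ratio))
  }
  out <- GRanges(res_chrom, IRanges(start = res_start, width = res_len))
  mcols(out)$seed_enhancer <- res_seed
  mcols(out)$name <- sprintf("%s_neg%02d", res_seed,
                             sequence(rep(spec$ratio, length(enhancers))))
  out
}

#' Sample flanking negatives
#'
#' For each enhancer of length L, draws `ratio` regions of length L
#' uniformly from the window extending `flank_multiplier * L` on either
#' side of the enhancer (clipped to the chromosome), rejecting candidates
#' that overlap any enhancer in `all_enhancers`, any exclusion region, or
#' any previously accepted negative.
#'
#' @param enhancers `GRanges` of seed enhancers.
#' @param all_enhancers `GRanges` of all enhancers that negatives must not
#'   overlap (defaults to `enhancers`).
#' @param genome Named `DNAStringSet`.
#' @param exclusions Optional `GRanges` to avoid.
#' @param spec A [sampling_spec()] with `mode = "flanking"`.
#' @return `GRanges` of negatives with a `seed_enhancer` column.
#' @export
sample_flanking_negatives <- function(enhancers, all_enhancers = enhancers,
                                      genome, exclusions = NULL,
                                      spec = sampling_spec(mode = "flanking")) {
  stopifnot(inherits(spec, "sampling_spec"))
  if (spec$mode != "flanking") stop("spec$mode must be 'flanking'")
  set.seed(spec$seed)
  chroms <- names(genome)
  occ <- occupancy_from_granges(list(all_enhancers, exclusions), chroms)
  enh_names <- if (!is.null(mcols(enhancers)$name)) mcols(enhancers)$name
  else sprintf("enh%04d", seq_along(enhancers))

  res_chrom <- character(0); res_start <- integer(0); res_len <- integer(0)
  res_seed <- character(0)
  for (i in seq_along(enhancers)) {
    ci <- as.character(seqnames(enhancers))[i]
    L <- width(enhancers)[i]
    clen <- width(genome)[match(ci, chroms)]
    lo <- max(1L, start(enhancers)[i] - spec$flank_multiplier * L)
    hi <- min(clen, end(enhancers)[i] + spec$flank_multiplier * L)
    if (hi - lo + 1L < L) {
      stop("sampling failure: flanking window of enhancer ", enh_names[i],
           " shorter than the enhancer")
    }
    got_s <- integer(0); attempts <- 0L
    while (length(got_s) < spec$ratio) {
      if (attempts >= 2L * spec$max_attempts) {
        stop("sampling failure: could not find ", spec$ratio,
             " flanking negatives for enhancer ", enh_names[i])
      }
      n_cand <- 64L
      attempts <- attempts + n_cand
      s <- lo + sample.int(hi - L + 1L - lo + 1L, n_cand, replace = TRUE) - 1L
      e <- s + L - 1L
      keep <- !overlaps_occ(occ[[ci]], s, e)
      for (j in which(keep)) {
        if (length(got_s) >= spec$ratio) break
        if (any(s[j] <= (got_s + L - 1L) & e[j] >= got_s)) next
        got_s <- c(got_s, s[j])
      }
    }
    occ[[ci]]$s <- c(occ[[ci]]$s, got_s)
    occ[[ci]]$e <- c(occ[[ci]]$e, got_s + L - 1L)
    res_chrom <- c(res_chrom, rep(ci, spec$ratio))
    res_start <- c(res_start, got_s)
    res_len <- c(res_len, rep(L, spec$ratio))
    res_seed <- c(res_seed, rep(enh_names[i], spec$ratio))
  }
  out <- GRanges(res_chrom, IRanges(start = res_start, width = res_len))
  mcols(out)$seed_enhancer <- res_seed
  mcols(out)$name <- sprintf("%s_flank%02d", res_seed,
                             sequence(rep(spec$ratio, length(enhancers))))
  out
}
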