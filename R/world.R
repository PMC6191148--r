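#' Species specification for the synthetic world
#'
#' @param name Species name.
#' @param gc_background Genome-wide GC fraction of the order-0 background
#'   model, in (0, 1). Bases are drawn i.i.d. with
#'   `P(C) = P(G) = gc/2`, `P(A) = P(T) = (1 - gc)/2`.
#' @param divergence_from_ref Neutral divergence from the reference species
#'   in substitutions per site, in \[0, 1\]; must be 0 for the reference
#'   (first) species. Orthologous enhancers of this species are produced by
#'   applying this many substitutions per site to the ancestral sequence.
#' @param motif_usage Optional named nonnegative weights over a tissue's
#'   motif set, normalized to sum to 1; `NULL` means uniform usage. A single
#'   vector applies to all tissues.
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(name, gc_background, divergence_from_ref = 0,
                         motif_usage = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            gc_background > 0, gc_background < 1,
            divergence_from_ref >= 0, divergence_from_ref <= 1)
  if (!is.null(motif_usage)) {
    if (any(motif_usage < 0) || sum(motif_usage) <= 0) {
      stop("motif_usage weights must be nonnegative with positive sum")
    }
    motif_usage <- motif_usage / sum(motif_usage)
  }
  structure(list(name = name, gc_background = gc_background,
                 divergence_from_ref = divergence_from_ref,
                 motif_usage = motif_usage),
            class = "species_spec")
}

#' Configuration of a synthetic multi-species world
#'
#' The defaults define the package's reference simulation: three species
#' diverging star-like from the first, one liver-like tissue using 8 motifs
#' out of a 205-motif library, two chromosomes of 3 Mb per species, 100
#' enhancers of 150-350 bp with 4 planted motif instances each, a mild +0.04
#' enhancer GC shift, 8% repeat coverage, 20% orthologous enhancers, and a
#' TF-expression model in which tissue-motif TFs are expressed with
#' probability 0.9 against a 0.5 baseline.
#'
#' @param species List of [species_spec()] objects; the first is the
#'   reference and must have divergence 0.
#' @param tissues Named list: tissue name -> character vector of motif ids
#'   (non-empty, all present in `motif_library`).
#' @param motif_library A [build_motif_library()] result.
#' @param n_chromosomes,chrom_length Genome shape per species.
#' @param n_enhancers_per_tissue Number of enhancers per species x tissue.
#' @param enhancer_length_range Inclusive (min, max) enhancer length in bp.
#' @param motifs_per_enhancer Number of motif instances planted per enhancer.
#' @param enhancer_gc_delta Signed GC shift of enhancer background relative
#'   to the species background.
#' @param repeat_fraction Approximate fraction of each genome covered by
#'   tandem repeats.
#' @param enhancer_repeat_fraction Fraction of (non-orthologous) enhancers
#'   forced to overlap a planted repeat, so repeat-matched and repeat-free
#'   analyses are both non-degenerate.
#' @param ortholog_fraction Fraction of each tissue's enhancers descended
#'   from a common ancestral sequence shared by all species.
#' @param expression_signal Probability that a tissue-motif TF is expressed
#'   in that tissue.
#' @param expression_baseline Probability that any other TF is expressed in
#'   a tissue.
#' @param seed Integer seed; the whole world is a deterministic function of
#'   the configuration including this seed.
#' @return An object of class `world_config`.
#' @export
world_config <- function(species = NULL, tissues = NULL, motif_library = NULL,
                         n_chromosomes = 2L, chrom_length = 3000000L,
                         n_enhancers_per_tissue = 100L,
                         enhancer_length_range = c(150L, 350L),
                         motifs_per_enhancer = 4L,
                         enhancer_gc_delta = 0.04,
                         repeat_fraction = 0.08,
                         enhancer_repeat_fraction = 0.2,
                         ortholog_fraction = 0.2,
                         expression_signal = 0.9,
                         expression_baseline = 0.5,
                         seed = 1L) {
  if (is.null(motif_library)) {
    motif_library <- build_motif_library(205L, width_range = c(8, 12),
                                         info_content_target = 1.5,
                                         seed = seed + 101L)
  }
  if (is.null(species)) {
    species <- list(
      species_spec("speciesA", 0.41, 0),
      species_spec("speciesB", 0.43, 0.15),
      species_spec("speciesC", 0.40, 0.30)
    )
  }
  if (is.null(tissues)) {
    tissues <- list(liver = names(motif_library)[seq_len(8L)])
  }
  stopifnot(length(species) >= 1L, length(tissues) >= 1L,
            !is.null(names(tissues)))
  if (species[[1]]$divergence_from_ref != 0) {
    stop("the first (reference) species must have divergence_from_ref = 0")
  }
  for (tn in names(tissues)) {
    if (length(tissues[[tn]]) == 0L) stop("tissue '", tn, "' has no motifs")
    missing <- setdiff(tissues[[tn]], names(motif_library))
    if (length(missing)) {
      stop("tissue '", tn, "' references unknown motifs: ",
           paste(missing, collapse = ", "))
    }
  }
  lr <- as.integer(enhancer_length_range)
  if (!(lr[1] > 0 && lr[1] <= lr[2] && lr[2] <= chrom_length)) {
    stop("need 0 < min length <= max length <= chrom_length")
  }
  fracs <- c(repeat_fraction, enhancer_repeat_fraction, ortholog_fraction,
             expression_signal, expression_baseline)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  structure(list(
    species = species, tissues = tissues, motif_library = motif_library,
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_enhancers_per_tissue = as.integer(n_enhancers_per_tissue),
    enhancer_length_range = lr,
    motifs_per_enhancer = as.integer(motifs_per_enhancer),
    enhancer_gc_delta = enhancer_gc_delta,
    repeat_fraction = repeat_fraction,
    enhancer_repeat_fraction = enhancer_repeat_fraction,
    ortholog_fraction = ortholog_fraction,
    expression_signal = expression_signal,
    expression_baseline = expression_baseline,
    seed = as.integer(seed)
  ), class = "world_config")
}

#' Preset world configurations for the package's standard simulations
#'
#' Three study designs used throughout the documentation and tests:
#' \describe{
#'   \item{default}{The [world_config()] defaults: three species, one
#'     tissue with 8 shared motifs, shared (uniform) motif usage. The
#'     setting for cross-species generalization and motif-recovery
#'     analyses.}
#'   \item{two_tissue}{Two species, two tissues with disjoint 6-motif sets
#'     and shared usage, 60 enhancers per tissue. The setting for
#'     comparing cross-species same-tissue against cross-tissue
#'     same-species generalization.}
#'   \item{gc_only}{Three species, one tissue, no planted motifs
#'     (`motifs_per_enhancer = 0`) and no repeats, enhancer GC shifted by
#'     +0.06, 150 enhancers of 150-300 bp. The only enhancer signal is
#'     GC, the setting for the GC-matching control.}
#' }
#'
#' @param type Preset name.
#' @param seed Integer seed stored in the configuration.
#' @return A `world_config`.
#' @export
example_world_config <- function(type = c("default", "two_tissue", "gc_only"),
                                 seed = 1L) {
  type <- match.arg(type)
  switch(type,
    default = world_config(seed = seed),
    two_tissue = {
      lib <- build_motif_library(205L, width_range = c(8, 12),
                                 info_content_target = 1.5,
                                 seed = seed + 101L)
      world_config(
        species = list(species_spec("speciesA", 0.41, 0),
                       species_spec("speciesB", 0.43, 0.15)),
        tissues = list(liver = names(lib)[1:6], limb = names(lib)[7:12]),
        motif_library = lib,
        n_enhancers_per_tissue = 60L,
        chrom_length = 1000000L,
        seed = seed)
    },
    gc_only = world_config(
      motifs_per_enhancer = 0L,
      enhancer_gc_delta = 0.06,
      n_enhancers_per_tissue = 150L,
      enhancer_length_range = c(150L, 300L),
      ortholog_fraction = 0,
      repeat_fraction = 0,
      enhancer_repeat_fraction = 0,
      seed = seed)
  )
}

# i.i.d. bases at a given GC fraction, as a character vector
random_bases <- function(n, gc) {
  gc <- min(max(gc, 0.02), 0.98)
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# exact-composition variant: the G+C count is fixed at round(gc * n) and
# the arrangement randomized. Used for enhancer backgrounds so that every
# enhancer's GC sits at the configured shift instead of spreading
# binomially into tails where no matched background window exists.
random_bases_exact <- function(n, gc) {
  gc <- min(max(gc, 0.02), 0.98)
  n_gc <- round(gc * n)
  sample(c(sample(c("C", "G"), n_gc, replace = TRUE),
           sample(c("A", "T"), n - n_gc, replace = TRUE)))
}

#' Apply neutral substitutions to a sequence
#'
#' Each site is independently replaced with probability `d` by a base drawn
#' uniformly from A, C, G, T (so the expected observed mismatch fraction is
#' `3/4 * d`: a quarter of replacements restore the original base).
#'
#' @param seq Character scalar or `DNAString`.
#' @param d Substitutions per site, in \[0, 1\].
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Character scalar of the same length as the input.
#' @export
evolve_sequence <- function(seq, d, seed = NULL) {
  stopifnot(d >= 0, d <= 1)
  if (!is.null(seed)) set.seed(seed)
  x <- strsplit(as.character(seq), "")[[1]]
  hit <- runif(length(x)) < d
  if (any(hit)) x[hit] <- sample(DNA_BASES, sum(hit), replace = TRUE)
  paste(x, collapse = "")
}

# sample an instance sequence from a PPM, one base per column
sample_motif_instance <- function(motif) {
  idx <- apply(motif$matrix, 2L, function(p) sample.int(4L, 1L, prob = p))
  paste(DNA_BASES[idx], collapse = "")
}

revcomp_chr <- function(s) {
  as.character(reverseComplement(DNAString(s)))
}

# Plant n motif instances at random non-overlapping offsets on random
# strands inside a sequence (character vector of bases). Returns the
# modified vector plus a record of what was planted.
plant_motifs <- function(bases, motif_ids, library) {
  L <- length(bases)
  placed_start <- integer(0); placed_end <- integer(0)
  rec <- list()
  for (mid in motif_ids) {
    m <- library[[mid]]
    w <- m$width
    if (w > L) stop("capacity error: motif wider than enhancer")
    ok <- FALSE
    for (try in seq_len(200L)) {
      off <- sample.int(L - w + 1L, 1L) - 1L   # 0-based offset
      s <- off + 1L; e <- off + w
      if (!any(s <= placed_end & e >= placed_start)) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("capacity error: cannot place ", length(motif_ids),
           " non-overlapping motif instances in a ", L, " bp enhancer")
    }
    strand <- sample(c("+", "-"), 1L)
    inst <- sample_motif_instance(m)
    if (strand == "-") inst <- revcomp_chr(inst)
    bases[s:e] <- strsplit(inst, "")[[1]]
    placed_start <- c(placed_start, s); placed_end <- c(placed_end, e)
    rec[[length(rec) + 1L]] <- list(motif_id = mid, offset = off,
                                    strand = strand, width = w)
  }
  list(bases = bases, planted = rec)
}

# overwrite a random internal segment with tandem copies of a repeat
# consensus; returns modified bases and the 0-based segment bounds
force_repeat_segment <- function(bases, consensus) {
  L <- length(bases)
  seg_len <- min(L - 10L, sample(60:120, 1L))
  s <- sample.int(L - seg_len + 1L, 1L)
  unit <- strsplit(consensus, "")[[1]]
  fill <- rep(unit, length.out = seg_len)
  bases[s:(s + seg_len - 1L)] <- fill
  list(bases = bases, start = s - 1L, end = s - 1L + seg_len)
}

# sample non-overlapping (chrom, start) placements for given lengths
place_intervals <- function(lengths, n_chrom, chrom_len, max_tries = NULL) {
  n <- length(lengths)
  if (is.null(max_tries)) max_tries <- 200L * n + 1000L
  chrom <- integer(n); start <- integer(n)
  occ <- lapply(seq_len(n_chrom), function(i) list(s = integer(0), e = integer(0)))
  tries <- 0L
  for (i in seq_len(n)) {
    L <- lengths[i]
    repeat {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("capacity error: unable to place ", n,
             " non-overlapping intervals of total length ", sum(lengths),
             " in ", n_chrom, " x ", chrom_len, " bp")
      }
      ci <- sample.int(n_chrom, 1L)
      s <- sample.int(chrom_len - L + 1L, 1L)
      e <- s + L - 1L
      o <- occ[[ci]]
      if (!any(s <= o$e & e >= o$s)) {
        occ[[ci]]$s <- c(o$s, s); occ[[ci]]$e <- c(o$e, e)
        chrom[i] <- ci; start[i] <- s
        break
      }
    }
  }
  list(chrom = chrom, start = start)
}

#' Sample a TF-expression table
#'
#' Bernoulli expression calls per TF x tissue: TFs whose motif belongs to a
#' tissue's motif set are expressed there with probability `signal`, all
#' other TF/tissue combinations with probability `baseline`.
#'
#' @param library A `motif_library`.
#' @param tissues Named list of motif-id vectors.
#' @param signal,baseline Expression probabilities.
#' @return Data frame with columns `tf_name`, `tissue`, `expressed` (0/1).
#' @export
sample_expression_table <- function(library, tissues, signal = 0.9,
                                    baseline = 0.5) {
  tf <- library_tf_names(library)
  mid <- names(library)
  out <- do.call(rbind, lapply(names(tissues), function(tn) {
    is_tissue <- mid %in% tissues[[tn]]
    p <- ifelse(is_tissue, signal, baseline)
    data.frame(tf_name = tf, tissue = tn,
               expressed = as.integer(runif(length(tf)) < p))
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a synthetic multi-species world
#'
#' Generates, deterministically from the configuration, per-species genomes
#' with species-specific GC background and tandem repeats, per-tissue
#' enhancer sets with planted motif instances (sampled from the tissue's
#' motif set with species-specific usage weights), orthologous enhancers
#' evolved from shared ancestral sequences, an ortholog map, a TF-expression
#' table, and a ground-truth record of every planted motif instance.
#'
#' A fraction `ortholog_fraction` of each tissue's enhancers derives from a
#' common ancestor: the ancestral sequence (background at the reference GC
#' plus `enhancer_gc_delta`, with motifs planted once) is independently
#' mutated into each species at that species' divergence, and every species
#' pair is recorded in the ortholog map. The remaining enhancers are
#' simulated independently per species.
#'
#' @param config A [world_config()].
#' @return An object of class `synthetic_world` with fields `config`,
#'   `genomes` (per species `DNAStringSet`), `enhancers` (per species
#'   `GRanges` with `name` and `tissue` columns), `repeats`, `gaps` (empty),
#'   `ortholog_map` (data frame, 0-based half-open coordinates),
#'   `expression`, and `truth` (one row per planted motif instance).
#' @export
simulate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  lib <- config$motif_library
  sp_names <- unname(vapply(config$species, `[[`, character(1L), "name"))
  names(config$species) <- sp_names
  n_sp <- length(sp_names)
  lr <- config$enhancer_length_range
  n_enh <- config$n_enhancers_per_tissue
  n_orth <- round(config$ortholog_fraction * n_enh)

  usage_weights <- function(sp, tissue_motifs) {
    u <- config$species[[sp]]$motif_usage
    if (is.null(u)) return(setNames(rep(1 / length(tissue_motifs),
                                        length(tissue_motifs)), tissue_motifs))
    w <- u[tissue_motifs]
    if (any(is.na(w))) stop("motif_usage for ", sp,
                            " missing weights for tissue motifs")
    w / sum(w)
  }

  # per-species repeat consensus (20-50 bp) at the species GC
  consensi <- lapply(sp_names, function(sp) {
    paste(random_bases(sample(20:50, 1L),
                       config$species[[sp]]$gc_background), collapse = "")
  })
  names(consensi) <- sp_names

  # ---- enhancer sequences -------------------------------------------------
  # seqs[[sp]]: list of char vectors; meta rows align with seqs
  seqs <- setNames(lapply(sp_names, function(x) list()), sp_names)
  meta <- setNames(lapply(sp_names, function(x)
    data.frame(tissue = character(0), name = character(0),
               orth_slot = integer(0))), sp_names)
  truth <- list()
  forced_rep <- setNames(lapply(sp_names, function(x) list()), sp_names)

  add_truth <- function(sp, tissue, enh_name, planted) {
    for (p in planted) {
      truth[[length(truth) + 1L]] <<- data.frame(
        species = sp, tissue = tissue, enhancer = enh_name,
        motif_id = p$motif_id, offset = p$offset, strand = p$strand,
        width = p$width)
    }
  }

  for (tissue in names(config$tissues)) {
    tmotifs <- config$tissues[[tissue]]
    ref_w <- usage_weights(sp_names[1], tmotifs)
    # orthologous slots: one ancestor, evolved into every species
    for (slot in seq_len(n_orth)) {
      L <- (lr[1]:lr[2])[sample.int(lr[2] - lr[1] + 1L, 1L)]
      anc <- random_bases_exact(L, config$species[[1]]$gc_background +
                                  config$enhancer_gc_delta)
      mids <- sample(tmotifs, config$motifs_per_enhancer, replace = TRUE,
                     prob = ref_w)
      pl <- plant_motifs(anc, mids, lib)
      for (sp in sp_names) {
        d <- config$species[[sp]]$divergence_from_ref
        s <- evolve_sequence(paste(pl$bases, collapse = ""), d)
        i <- length(seqs[[sp]]) + 1L
        nm <- sprintf("%s_%s_orth%03d", sp, tissue, slot)
        seqs[[sp]][[i]] <- strsplit(s, "")[[1]]
        meta[[sp]] <- rbind(meta[[sp]], data.frame(
          tissue = tissue, name = nm, orth_slot = slot))
        add_truth(sp, tissue, nm, pl$planted)
      }
    }
    # independent slots per species
    n_ind <- n_enh - n_orth
    n_forced <- ceiling(config$enhancer_repeat_fraction * n_ind)
    for (sp in sp_names) {
      w <- usage_weights(sp, tmotifs)
      gc_e <- config$species[[sp]]$gc_background + config$enhancer_gc_delta
      for (slot in seq_len(n_ind)) {
        L <- (lr[1]:lr[2])[sample.int(lr[2] - lr[1] + 1L, 1L)]
        bases <- random_bases_exact(L, gc_e)
        rep_seg <- NULL
        if (slot <= n_forced) {
          fr <- force_repeat_segment(bases, consensi[[sp]])
          bases <- fr$bases
          rep_seg <- c(fr$start, fr$end)
        }
        nm <- sprintf("%s_%s_enh%03d", sp, tissue, slot)
        if (config$motifs_per_enhancer > 0L) {
          mids <- sample(tmotifs, config$motifs_per_enhancer, replace = TRUE,
                         prob = w)
          pl <- plant_motifs(bases, mids, lib)
          bases <- pl$bases
          add_truth(sp, tissue, nm, pl$planted)
        }
        i <- length(seqs[[sp]]) + 1L
        seqs[[sp]][[i]] <- bases
        meta[[sp]] <- rbind(meta[[sp]], data.frame(
          tissue = tissue, name = nm, orth_slot = NA_integer_))
        if (!is.null(rep_seg)) {
          forced_rep[[sp]][[length(forced_rep[[sp]]) + 1L]] <-
            c(enh = i, s = rep_seg[1], e = rep_seg[2])
        }
      }
    }
  }

  # ---- placement and genome assembly -------------------------------------
  genomes <- list(); enhancers <- list(); repeats <- list(); gaps <- list()
  ortho_rows <- list()
  chrom_names <- sprintf("chr%d", seq_len(config$n_chromosomes))

  for (sp in sp_names) {
    lens <- vapply(seqs[[sp]], length, integer(1L))
    pl <- place_intervals(lens, config$n_chromosomes, config$chrom_length)
    gr <- GRanges(chrom_names[pl$chrom],
                  IRanges(start = pl$start, width = lens))
    mcols(gr)$name <- meta[[sp]]$name
    mcols(gr)$tissue <- meta[[sp]]$tissue

    # background genome
    chrs <- lapply(seq_len(config$n_chromosomes), function(i)
      random_bases(config$chrom_length, config$species[[sp]]$gc_background))

    # tandem repeat blocks outside enhancers
    rep_s <- integer(0); rep_e <- integer(0); rep_c <- integer(0)
    target <- config$repeat_fraction * config$n_chromosomes *
      config$chrom_length
    covered <- 0; attempts <- 0L
    unit <- strsplit(consensi[[sp]], "")[[1]]
    while (covered < target && attempts < 5000L) {
      attempts <- attempts + 1L
      blk <- length(unit) * sample(5:15, 1L)
      ci <- sample.int(config$n_chromosomes, 1L)
      s <- sample.int(config$chrom_length - blk + 1L, 1L)
      e <- s + blk - 1L
      enh_here <- which(pl$chrom == ci)
      clash <- any(s <= (pl$start[enh_here] + lens[enh_here] - 1L) &
                     e >= pl$start[enh_here]) ||
        any(s <= rep_e[rep_c == ci] & e >= rep_s[rep_c == ci])
      if (clash) next
      chrs[[ci]][s:e] <- rep(unit, length.out = blk)
      rep_s <- c(rep_s, s); rep_e <- c(rep_e, e); rep_c <- c(rep_c, ci)
      covered <- covered + blk
    }
    if (covered < 0.8 * target) {
      stop("capacity error: placed only ", covered, " of ", target,
           " repeat bp for ", sp)
    }

    # write enhancer sequences into the genome
    for (i in seq_along(seqs[[sp]])) {
      ci <- pl$chrom[i]; s <- pl$start[i]
      chrs[[ci]][s:(s + lens[i] - 1L)] <- seqs[[sp]][[i]]
    }
    # forced enhancer-internal repeat segments, in genome coordinates
    for (fr in forced_rep[[sp]]) {
      i <- fr[["enh"]]
      rep_s <- c(rep_s, pl$start[i] + fr[["s"]])
      rep_e <- c(rep_e, pl$start[i] + fr[["e"]] - 1L)
      rep_c <- c(rep_c, pl$chrom[i])
    }

    genome <- DNAStringSet(vapply(chrs, paste, character(1L), collapse = ""))
    names(genome) <- chrom_names
    genomes[[sp]] <- genome
    enhancers[[sp]] <- gr
    repeats[[sp]] <- sort(GRanges(chrom_names[rep_c],
                                  IRanges(start = rep_s, end = rep_e)))
    gaps[[sp]] <- GRanges()
  }

  # ---- ortholog map -------------------------------------------------------
  for (tissue in names(config$tissues)) {
    for (slot in seq_len(n_orth)) {
      for (i in seq_len(n_sp - 1L)) {
        for (j in (i + 1L):n_sp) {
          a <- sp_names[i]; b <- sp_names[j]
          ia <- enhancers[[a]][mcols(enhancers[[a]])$name ==
                                 sprintf("%s_%s_orth%03d", a, tissue, slot)]
          ib <- enhancers[[b]][mcols(enhancers[[b]])$name ==
                                 sprintf("%s_%s_orth%03d", b, tissue, slot)]
          ortho_rows[[length(ortho_rows) + 1L]] <- data.frame(
            species_a = a, chrom_a = as.character(seqnames(ia)),
            start_a = start(ia) - 1L, end_a = end(ia),
            species_b = b, chrom_b = as.character(seqnames(ib)),
            start_b = start(ib) - 1L, end_b = end(ib),
            tissue = tissue)
        }
      }
    }
  }
  ortholog_map <- if (length(ortho_rows)) {
    out <- do.call(rbind, ortho_rows)
    rownames(out) <- NULL
    out
  } else
    data.frame(species_a = character(0), chrom_a = character(0),
               start_a = integer(0), end_a = integer(0),
               species_b = character(0), chrom_b = character(0),
               start_b = integer(0), end_b = integer(0),
               tissue = character(0))

  expression <- sample_expression_table(lib, config$tissues,
                                        config$expression_signal,
                                        config$expression_baseline)
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(species = character(0), tissue = character(0),
               enhancer = character(0), motif_id = character(0),
               offset = integer(0), strand = character(0), width = integer(0))
  rownames(truth_df) <- NULL

  structure(list(config = config, genomes = genomes, enhancers = enhancers,
                 repeats = repeats, gaps = gaps,
                 ortholog_map = ortholog_map, expression = expression,
                 truth = truth_df),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "synthetic_world: %d species, %d tissue(s), %d x %d bp chromosomes, %d enhancers/tissue\n",
    length(x$genomes), length(x$config$tissues), x$config$n_chromosomes,
    x$config$chrom_length, x$config$n_enhancers_per_tissue))
  invisible(x)
}

#' Enhancers of one species (optionally one tissue)
#' @param world A `synthetic_world`.
#' @param species Species name.
#' @param tissue Optional tissue name.
#' @return A `GRanges`.
#' @export
world_enhancers <- function(world, species, tissue = NULL) {
  gr <- world$enhancers[[species]]
  if (is.null(gr)) stop("unknown species: ", species)
  if (!is.null(tissue)) gr <- gr[mcols(gr)$tissue == tissue]
  gr
}

#' Pairwise neutral divergence table of a world
#'
#' Star topology: the divergence between two species is the sum of their
#' branch lengths to the reference ancestor.
#'
#' @param world A `synthetic_world`.
#' @return Data frame with columns `species_a`, `species_b`, `divergence`.
#' @export
world_divergence_table <- function(world) {
  sp <- world$config$species
  nm <- vapply(sp, `[[`, character(1L), "name")
  d <- vapply(sp, `[[`, numeric(1L), "divergence_from_ref")
  out <- expand.grid(species_a = nm, species_b = nm,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$divergence <- d[match(out$species_a, nm)] + d[match(out$species_b, nm)]
  out$divergence[out$species_a == out$species_b] <- 0
  out
}

#' Write a synthetic world to disk
#'
#' Writes per-species genome FASTA, enhancer/repeat BED6, the motif library
#' in MEME v4 format, the TF-expression and pairwise-divergence TSVs, and a
#' JSON file holding the truth record and ortholog map. All interval
#' coordinates are 0-based half-open.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(world$genomes)) {
    write_fasta(world$genomes[[sp]], file.path(dir, paste0(sp, ".fa")))
    write_bed(world$enhancers[[sp]],
              file.path(dir, paste0(sp, ".enhancers.bed")))
    write_bed(world$repeats[[sp]], file.path(dir, paste0(sp, ".repeats.bed")))
    write_bed(world$gaps[[sp]], file.path(dir, paste0(sp, ".gaps.bed")))
  }
  write_meme(world$config$motif_library, file.path(dir, "motifs.meme"))
  write.table(world$expression, file.path(dir, "expression.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(world_divergence_table(world), file.path(dir, "divergence.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(truth = world$truth, ortholog_map = world$ortholog_map),
    file.path(dir, "truth.json"), dataframe = "rows", digits = NA)
  invisible(dir)
}
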