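# Shared fixtures, built once per test run and cached. Heavy simulations
# (worlds, trained models) are reused across test files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a small, fast world for structural unit tests
tiny_world <- function(seed = 7) {
  fixture(paste0("tiny_world_", seed), function() {
    lib <- build_motif_library(10, width_range = c(6, 9),
                               info_content_target = 1.3, seed = 2)
    cfg <- world_config(
      species = list(species_spec("spA", 0.42, 0),
                     species_spec("spB", 0.45, 0.2)),
      tissues = list(liver = names(lib)[1:4]),
      motif_library = lib,
      n_chromosomes = 2L, chrom_length = 150000L,
      n_enhancers_per_tissue = 30L,
      enhancer_length_range = c(120L, 250L),
      motifs_per_enhancer = 3L,
      seed = seed)
    simulate_world(cfg)
  })
}

default_world <- function(seed = 1) {
  fixture(paste0("default_world_", seed), function() {
    simulate_world(example_world_config("default", seed = seed))
  })
}

# full cross-species liver analysis (length/chrom negatives) on the
# default world
liver_analysis <- function(seed = 1) {
  fixture(paste0("liver_analysis_", seed), function() {
    cross_eval_analysis(default_world(seed), tissue = "liver",
                        sampling_mode = "length_chrom", seed = seed)
  })
}

# GC-controlled classifiers (no CV) per species on the default world,
# used by the motif-interpretation tests
gc_models <- function(seed = 1) {
  fixture(paste0("gc_models_", seed), function() {
    w <- default_world(seed)
    models <- list()
    for (sp in names(w$genomes)) {
      d <- build_dataset(w, sp, "liver", sampling_mode = "gc",
                         seed = seed + 50)
      models[[sp]] <- train_classifier(d$pos, d$neg, seed = seed,
                                       metadata = list(species = sp,
                                                       tissue = "liver",
                                                       sampling_mode = "gc"))
    }
    models
  })
}

default_match_matrix <- function(seed = 1) {
  fixture(paste0("match_matrix_", seed), function() {
    kmer_match_matrix(default_world(seed)$config$motif_library, k = 5L)
  })
}

# naive sliding-window k-mer tally, the independent oracle for spectra
naive_kmer_tally <- function(seq, k) {
  counts <- setNames(integer(4^k), all_kmers(k))
  s <- strsplit(seq, "")[[1]]
  if (length(s) >= k) {
    for (i in 1:(length(s) - k + 1)) {
      w <- paste(s[i:(i + k - 1)], collapse = "")
      if (w %in% names(counts)) counts[w] <- counts[w] + 1L
    }
  }
  counts
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# random unit-norm feature rows mimicking normalized k-mer spectra
random_features <- function(n, k = 3, shift_cols = NULL, shift = 0,
                            len = 80) {
  m <- t(vapply(seq_len(n), function(i) {
    sp <- kmer_spectrum(random_dna(len), k)$counts
    as.numeric(sp)
  }, numeric(4^k)))
  colnames(m) <- all_kmers(k)
  if (!is.null(shift_cols)) m[, shift_cols] <- m[, shift_cols] + shift
  normalize_rows(m)
}

# consensus width-k windows of a motif, both strands (features are
# strand-literal and instances plant on either strand)
consensus_windows <- function(motif, k = 5, both_strands = FALSE) {
  cons <- motif$consensus
  wins <- vapply(seq_len(nchar(cons) - k + 1),
                 function(i) substr(cons, i, i + k - 1), character(1))
  if (both_strands) {
    wins <- unique(c(wins, as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(wins)))))
  }
  wins
}
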