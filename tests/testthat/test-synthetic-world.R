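library(GenomicRanges)
library(Biostrings)

test_that("sequence evolution preserves length and hits the expected mismatch rate", {
  s <- random_dna(500)
  expect_identical(evolve_sequence(s, 0, seed = 1), s)
  out <- evolve_sequence(s, 0.7, seed = 2)
  expect_equal(nchar(out), nchar(s))

  # substitution accepts the original base with prob 1/4, so the observed
  # mismatch fraction is d * 3/4
  n <- 10000
  s <- random_dna(n)
  out <- evolve_sequence(s, 0.4, seed = 3)
  mismatch <- mean(strsplit(s, "")[[1]] != strsplit(out, "")[[1]])
  p <- 0.4 * 3 / 4
  expect_lt(abs(mismatch - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("simulated worlds have the configured structure and are deterministic", {
  w <- tiny_world()
  cfg <- w$config
  for (sp in c("spA", "spB")) {
    enh <- world_enhancers(w, sp, "liver")
    expect_length(enh, cfg$n_enhancers_per_tissue)
    expect_true(all(width(enh) >= 120 & width(enh) <= 250))
    expect_true(all(start(enh) >= 1 & end(enh) <= cfg$chrom_length))
    # non-overlapping within the species set
    expect_equal(sum(countOverlaps(enh, enh) != 1L), 0L)
  }

  # every truth instance lies inside its parent enhancer
  enh_all <- do.call(c, unname(lapply(names(w$genomes),
                                      function(sp) w$enhancers[[sp]])))
  widths <- setNames(width(enh_all), mcols(enh_all)$name)
  expect_true(all(w$truth$offset >= 0))
  expect_true(all(w$truth$offset + w$truth$width <=
                    widths[w$truth$enhancer]))

  # byte-identical regeneration
  w2 <- simulate_world(w$config)
  expect_identical(lapply(w$genomes, as.character),
                   lapply(w2$genomes, as.character))
  expect_identical(w$truth, w2$truth)
  expect_identical(w$ortholog_map, w2$ortholog_map)
  expect_identical(w$expression, w2$expression)
})

test_that("planted motif instances match the genome sequence at truth coordinates", {
  w <- tiny_world()
  lib <- w$config$motif_library
  tr <- w$truth[w$truth$species == "spA", ]
  enh <- world_enhancers(w, "spA", "liver")
  seqs <- extract_sequences(w$genomes$spA, enh)
  names(seqs) <- mcols(enh)$name
  # instance sequences have positive PWM likelihood well above background
  ok <- 0
  for (i in seq_len(nrow(tr))) {
    inst <- substr(as.character(seqs[[tr$enhancer[i]]]),
                   tr$offset[i] + 1, tr$offset[i] + tr$width[i])
    if (tr$strand[i] == "-") {
      inst <- as.character(reverseComplement(DNAString(inst)))
    }
    m <- lib[[tr$motif_id[i]]]
    idx <- match(strsplit(inst, "")[[1]], c("A", "C", "G", "T"))
    ll <- sum(log2(m$matrix[cbind(idx, seq_len(m$width))] / 0.25))
    if (ll > 0) ok <- ok + 1
  }
  expect_gte(ok / nrow(tr), 0.95)
})

test_that("enhancer GC shift is recovered empirically", {
  # motif-free world isolates the configured +0.10 GC delta
  lib <- build_motif_library(5, c(6, 8), 1.3, seed = 4)
  cfg <- world_config(
    species = list(species_spec("spA", 0.40, 0)),
    tissues = list(liver = names(lib)[1:2]),
    motif_library = lib,
    n_chromosomes = 1L, chrom_length = 400000L,
    n_enhancers_per_tissue = 60L, enhancer_length_range = c(150L, 300L),
    motifs_per_enhancer = 0L, enhancer_gc_delta = 0.10,
    repeat_fraction = 0, enhancer_repeat_fraction = 0,
    ortholog_fraction = 0, seed = 5)
  w <- simulate_world(cfg)
  enh <- world_enhancers(w, "spA", "liver")
  enh_gc <- mean(gc_content(extract_sequences(w$genomes$spA, enh)))
  set.seed(6)
  starts <- sample(0:(400000 - 300), 1000)
  lens <- sample(width(enh), 1000, replace = TRUE)
  bg <- genomic_intervals("chr1", starts, pmin(starts + lens, 399999))
  bg <- bg[countOverlaps(bg, enh) == 0]
  bg_gc <- mean(gc_content(extract_sequences(w$genomes$spA, bg)))
  expect_lt(abs((enh_gc - bg_gc) - 0.10), 0.02)
})

test_that("planted consensus 5-mers are enriched in enhancers over background", {
  w <- default_world(1)
  sp <- "speciesA"
  enh <- world_enhancers(w, sp, "liver")
  enh_counts <- colSums(kmer_spectrum_matrix(
    extract_sequences(w$genomes[[sp]], enh), 5))
  enh_bp <- sum(width(enh))
  set.seed(17)
  starts <- sample(0:(w$config$chrom_length - 400), 1500)
  lens <- sample(width(enh), 1500, replace = TRUE)
  bg <- genomic_intervals("chr1", starts, starts + lens)
  bg <- bg[countOverlaps(bg, w$enhancers[[sp]]) == 0]
  bg_counts <- colSums(kmer_spectrum_matrix(
    extract_sequences(w$genomes[[sp]], bg), 5))
  bg_bp <- sum(width(bg))
  for (mid in w$config$tissues$liver) {
    wins <- consensus_windows(w$config$motif_library[[mid]], 5)
    enh_rate <- sum(enh_counts[wins]) / enh_bp
    bg_rate <- sum(bg_counts[wins]) / bg_bp
    expect_gt(enh_rate, bg_rate)
  }
})

test_that("the ortholog map is symmetric and repeats cover the configured fraction", {
  w <- tiny_world()
  map_ab <- ortholog_map_pairs(w$ortholog_map, "spA", "spB")
  map_ba <- ortholog_map_pairs(w$ortholog_map, "spB", "spA")
  expect_equal(nrow(map_ab), nrow(map_ba))
  expect_gt(nrow(map_ab), 0)
  # the same pairs, seen from either side
  key_ab <- paste(map_ab$chrom_a, map_ab$start_a, map_ab$chrom_b,
                  map_ab$start_b)
  key_ba <- paste(map_ba$chrom_b, map_ba$start_b, map_ba$chrom_a,
                  map_ba$start_a)
  expect_setequal(key_ab, key_ba)
  # mapped intervals reference real enhancers
  a_iv <- genomic_intervals(map_ab$chrom_a, map_ab$start_a, map_ab$end_a)
  expect_true(all(countOverlaps(a_iv, world_enhancers(w, "spA", "liver")) > 0))

  for (sp in names(w$genomes)) {
    cov <- sum(width(reduce(w$repeats[[sp]]))) /
      (w$config$n_chromosomes * w$config$chrom_length)
    expect_gt(cov, 0.5 * w$config$repeat_fraction)
    expect_lt(cov, 2.5 * w$config$repeat_fraction)
  }
})

test_that("infeasible configurations raise capacity errors", {
  lib <- build_motif_library(5, c(6, 8), 1.3, seed = 4)
  cfg <- world_config(
    species = list(species_spec("spA", 0.40, 0)),
    tissues = list(liver = names(lib)[1:2]),
    motif_library = lib,
    n_chromosomes = 1L, chrom_length = 5000L,
    n_enhancers_per_tissue = 40L, enhancer_length_range = c(200L, 400L),
    ortholog_fraction = 0, repeat_fraction = 0, seed = 5)
  expect_error(simulate_world(cfg), "capacity")
  expect_error(world_config(enhancer_length_range = c(500, 100)), "length")
  expect_error(
    world_config(species = list(species_spec("x", 0.4, 0.1))), "reference")
})

test_that("world serialization writes the standard formats coherently", {
  w <- tiny_world()
  dir <- withr::local_tempdir()
  write_world(w, dir)
  expect_true(file.exists(file.path(dir, "spA.fa")))
  g <- read_fasta(file.path(dir, "spA.fa"))
  expect_identical(as.character(g), as.character(w$genomes$spA))
  bed <- read_bed(file.path(dir, "spA.enhancers.bed"))
  expect_equal(start(bed), start(w$enhancers$spA))
  lib <- read_meme(file.path(dir, "motifs.meme"))
  expect_identical(names(lib), names(w$config$motif_library))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth$truth), nrow(w$truth))
  div <- utils::read.table(file.path(dir, "divergence.tsv"), header = TRUE,
                           sep = "\t")
  expect_equal(div$divergence[div$species_a == "spA" & div$species_b == "spB"],
               0.2)
})
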