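#' Specification of one prediction experiment
#'
#' One experiment trains a classifier on one species x tissue enhancer set
#' (against sampled matched negatives) and evaluates it on another —
#' possibly the same — species x tissue set, mirroring the
#' numbered-experiment bookkeeping used for large cross-prediction grids.
#'
#' @param experiment_id Integer id, unique within a registry.
#' @param train_species,train_tissue Training set label.
#' @param test_species,test_tissue Test set label (defaults: same as
#'   training).
#' @param sampling_mode Negative sampling mode (see [sampling_spec()]).
#' @param k Word length.
#' @param C,class_weights SVM cost and class weights.
#' @param folds Cross-validation folds for the within-species reference.
#' @param seed Per-experiment seed (sampling and fold assignment).
#' @param remove_orthologs Remove ortholog-mapped enhancers from both the
#'   training and the testing set before featurization.
#' @param repeat_free Restrict positives to enhancers with zero repeat
#'   overlap.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(experiment_id, train_species, train_tissue,
                            test_species = train_species,
                            test_tissue = train_tissue,
                            sampling_mode = "length_chrom",
                            k = 5L, C = 15, class_weights = c(10, 1),
                            folds = 10L, seed = 1L,
                            remove_orthologs = FALSE, repeat_free = FALSE) {
  structure(list(experiment_id = as.integer(experiment_id),
                 train_species = train_species, train_tissue = train_tissue,
                 test_species = test_species, test_tissue = test_tissue,
                 sampling_mode = sampling_mode, k = as.integer(k), C = C,
                 class_weights = class_weights, folds = as.integer(folds),
                 seed = as.integer(seed),
                 remove_orthologs = isTRUE(remove_orthologs),
                 repeat_free = isTRUE(repeat_free)),
            class = "experiment_spec")
}

#' Build a featurized positive/negative dataset from a world
#'
#' Extracts one species x tissue enhancer set, samples matched negatives in
#' the requested mode (negatives avoid every enhancer of the species, all
#' tissues), and returns unit-normalized k-mer feature matrices.
#'
#' @param world A `synthetic_world`.
#' @param species,tissue Dataset label.
#' @param sampling_mode One of the [sampling_spec()] modes.
#' @param k Word length.
#' @param ratio Negatives per positive.
#' @param seed Sampling seed.
#' @param repeat_free Keep only enhancers with zero repeat overlap.
#' @param enhancers Optional replacement enhancer set (e.g. after ortholog
#'   filtering); defaults to the world's.
#' @return List with `pos`, `neg` (feature matrices), `enhancers`,
#'   `negatives` (`GRanges`), and `neg_groups` (seed positive index per
#'   negative, for grouped cross-validation).
#' @export
build_dataset <- function(world, species, tissue,
                          sampling_mode = "length_chrom", k = 5L,
                          ratio = 10L, seed = 1L, repeat_free = FALSE,
                          enhancers = NULL) {
  if (is.null(enhancers)) enhancers <- world_enhancers(world, species, tissue)
  if (repeat_free) {
    enhancers <- enhancers[
      repeat_overlap_fraction(enhancers, world$repeats[[species]]) == 0]
  }
  genome <- world$genomes[[species]]
  other <- world$enhancers[[species]]
  other <- other[!(mcols(other)$name %in% mcols(enhancers)$name)]
  exclusions <- c(granges(other), granges(world$gaps[[species]]))
  spec <- sampling_spec(mode = sampling_mode, ratio = ratio, seed = seed)
  negatives <- if (sampling_mode == "flanking") {
    sample_flanking_negatives(enhancers,
                              all_enhancers = world$enhancers[[species]],
                              genome = genome,
                              exclusions = granges(world$gaps[[species]]),
                              spec = spec)
  } else {
    sample_matched_negatives(enhancers, genome,
                             repeats = world$repeats[[species]],
                             exclusions = exclusions, spec = spec)
  }
  list(pos = featurize_intervals(genome, enhancers, k),
       neg = featurize_intervals(genome, negatives, k),
       enhancers = enhancers, negatives = negatives,
       neg_groups = match(mcols(negatives)$seed_enhancer,
                          mcols(enhancers)$name))
}

#' Cross-evaluation of classifiers over species x tissue combinations
#'
#' For every requested species x tissue combination: builds the dataset,
#' runs stratified cross-validation (the within reference), trains a model
#' on the full set, and finally assembles the [cross_eval_matrix()] of all
#' pairwise applications.
#'
#' @param world A `synthetic_world`.
#' @param combos Data frame with columns `species` and `tissue`; default
#'   all species of the world crossed with the given `tissue`.
#' @param tissue Tissue used when `combos` is NULL.
#' @param sampling_mode,k,ratio,C,class_weights,folds,seed See
#'   [build_dataset()] and [train_classifier()].
#' @return List with `datasets`, `models`, `cv`, and `matrix` (a
#'   `cross_eval_matrix`), all named by `species.tissue` labels (plain
#'   species names when a single tissue is involved).
#' @export
cross_eval_analysis <- function(world, combos = NULL, tissue = NULL,
                                sampling_mode = "length_chrom", k = 5L,
                                ratio = 10L, C = 15, class_weights = c(10, 1),
                                folds = 10L, seed = 1L) {
  if (is.null(combos)) {
    if (is.null(tissue)) tissue <- names(world$config$tissues)[1]
    combos <- data.frame(species = names(world$genomes), tissue = tissue)
  }
  labels <- if (length(unique(combos$tissue)) == 1L) combos$species else
    paste(combos$species, combos$tissue, sep = ".")
  datasets <- list(); models <- list(); cv <- list()
  for (i in seq_len(nrow(combos))) {
    d <- build_dataset(world, combos$species[i], combos$tissue[i],
                       sampling_mode = sampling_mode, k = k, ratio = ratio,
                       seed = seed + i)
    cvr <- cross_validate(d$pos, d$neg, folds = folds, C = C,
                          class_weights = class_weights, seed = seed + i,
                          neg_groups = d$neg_groups)
    mdl <- train_classifier(d$pos, d$neg, C = C,
                            class_weights = class_weights, seed = seed + i,
                            metadata = list(species = combos$species[i],
                                            tissue = combos$tissue[i],
                                            sampling_mode = sampling_mode))
    datasets[[labels[i]]] <- d
    cv[[labels[i]]] <- cvr
    models[[labels[i]]] <- mdl
  }
  mat <- cross_eval_matrix(models,
                           lapply(datasets, function(d) d[c("pos", "neg")]),
                           cv)
  list(datasets = datasets, models = models, cv = cv, matrix = mat,
       combos = cbind(combos, label = labels))
}

#' Run one experiment and append it to a registry
#'
#' Executes the full sample -> featurize -> train/CV -> evaluate chain for
#' an [experiment_spec()] and appends one row (settings, AUCs, relative
#' AUCs) to a registry TSV. Reruns append; prior rows are never modified.
#'
#' @param spec An `experiment_spec`.
#' @param world A `synthetic_world`.
#' @param registry_path Optional path of a TSV registry to append to.
#' @return The registry row as a one-row data frame (invisibly returns it
#'   after writing when `registry_path` is given).
#' @export
run_experiment <- function(spec, world, registry_path = NULL) {
  stopifnot(inherits(spec, "experiment_spec"),
            inherits(world, "synthetic_world"))
  tr_enh <- world_enhancers(world, spec$train_species, spec$train_tissue)
  te_enh <- world_enhancers(world, spec$test_species, spec$test_tissue)
  if (spec$remove_orthologs &&
      spec$train_species != spec$test_species) {
    filt <- filter_orthologous(tr_enh, te_enh, world$ortholog_map,
                               spec$train_species, spec$test_species)
    tr_enh <- filt$a; te_enh <- filt$b
  }
  train <- build_dataset(world, spec$train_species, spec$train_tissue,
                         sampling_mode = spec$sampling_mode, k = spec$k,
                         seed = spec$seed, repeat_free = spec$repeat_free,
                         enhancers = tr_enh)
  same <- spec$train_species == spec$test_species &&
    spec$train_tissue == spec$test_tissue
  test <- if (same) train else
    build_dataset(world, spec$test_species, spec$test_tissue,
                  sampling_mode = spec$sampling_mode, k = spec$k,
                  seed = spec$seed + 1L, repeat_free = spec$repeat_free,
                  enhancers = te_enh)
  cv <- cross_validate(test$pos, test$neg, folds = spec$folds, C = spec$C,
                       class_weights = spec$class_weights, seed = spec$seed,
                       neg_groups = test$neg_groups)
  if (same) {
    auroc <- cv$mean_auroc; aupr <- cv$mean_aupr
  } else {
    model <- train_classifier(train$pos, train$neg, C = spec$C,
                              class_weights = spec$class_weights,
                              seed = spec$seed)
    scores <- decision_scores(model, rbind(test$pos, test$neg))
    lab <- rep(c(1L, 0L), c(nrow(test$pos), nrow(test$neg)))
    auroc <- roc_auc(scores, lab)
    aupr <- pr_auc(scores, lab)
  }
  row <- data.frame(
    experiment_id = spec$experiment_id,
    train_species = spec$train_species, train_tissue = spec$train_tissue,
    test_species = spec$test_species, test_tissue = spec$test_tissue,
    sampling_mode = spec$sampling_mode, k = spec$k, C = spec$C,
    class_weight_pos = spec$class_weights[1],
    class_weight_neg = spec$class_weights[2],
    folds = spec$folds, seed = spec$seed,
    remove_orthologs = spec$remove_orthologs,
    repeat_free = spec$repeat_free,
    n_train_pos = nrow(train$pos), n_test_pos = nrow(test$pos),
    auroc = auroc, aupr = aupr,
    within_auroc = cv$mean_auroc, within_aupr = cv$mean_aupr,
    relative_auroc = relative_auc(auroc, cv$mean_auroc),
    relative_aupr = relative_auc(aupr, cv$mean_aupr),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  if (!is.null(registry_path)) {
    write.table(row, registry_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = !file.exists(registry_path),
                append = file.exists(registry_path))
  }
  invisible(row)
}
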