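---
title: "Cross-species enhancer sequence classification: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species enhancer sequence classification: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Enhancers — distal regulatory regions operationally defined by histone-mark
profiles such as H3K27ac without H3K4me3 — turn over rapidly between
mammalian genomes, yet the *short sequence vocabulary* that makes a region
enhancer-like (transcription-factor binding motifs and related k-mer
composition) may be conserved. `crossenhancer` implements the quantitative
machinery for asking that question: train a sequence-only classifier to
separate one species' tissue enhancers from matched genomic background,
apply it to another species (or another tissue), and express the
transferred performance relative to what a natively trained classifier
achieves. If short sequence properties are conserved, the relative
performance stays near 100%.

# Model and procedure

## Features: the k-mer spectrum on the unit sphere

Each region is represented by its k-mer spectrum — the vector of counts of
all $4^k$ DNA words of length $k$ (default $k = 5$, configurable 4–7),
counted with overlaps on the literal strand. Reverse complements are *not*
collapsed: a k-mer and its reverse complement are separate features, and
strand symmetry is left for the classifier to learn. Windows containing `N`
are skipped rather than imputed. Count vectors are normalized to the
Euclidean unit sphere, so the linear kernel between feature vectors equals
the cosine similarity of the raw spectra — the cosine-normalized spectrum
kernel. This identity (asserted to $10^{-9}$ in the test suite) is what
lets the package train a *primal* linear SVM and still read the result as a
spectrum-kernel machine: the fitted weight vector assigns one
interpretable weight per k-mer.

## Classifier: cost-weighted soft-margin linear SVM

Training uses a soft-margin linear SVM (libsvm via `e1071`) with cost
$C = 15$ and class weights 10 (positives) : 1 (negatives). The training
design is deliberately imbalanced — ten sampled background regions per
enhancer — reflecting that enhancers are a small fraction of the genome;
the class weighting compensates by penalizing misclassified positives
tenfold. The solver tolerance is fixed at $10^{-4}$; training is
deterministic given the data order. A bias term is included (with
unit-sphere features its effect is minor, but the decision values exported
alongside the per-k-mer weights are then self-contained:
$s = w \cdot x + b$).

Within-species performance is measured by stratified 10-fold
cross-validation: folds preserve the positive:negative ratio to within one
example, each fold is scored exactly once by a model trained on the other
nine, and auROC/auPR are averaged over folds. When the negatives are
matched (the pipeline's normal case), fold assignment is *grouped*: each
enhancer and its matched negatives stay in one fold. Matched negatives
share their seed's length and GC signature, and folds that split a
cluster let the model recognize held-out members of clusters it trained
on — on a null dataset with exactly GC-matched negatives this artifact
alone inflates a randomly-split CV auROC to ≈ 0.58, while grouped folds
(like fully held-out clusters) return it to chance. With equal cluster
sizes (1 positive : `ratio` negatives) grouped assignment preserves the
per-fold class ratio exactly. auROC is computed by the
trapezoidal rule with tied scores grouped, which makes it exactly the
concordance probability $U/(mn)$; auPR is step-sum average precision with
no interpolation. Both identities are enforced against independent oracles
in the tests.

## The conservation statistic: relative auROC/auPR

For a classifier trained on dataset A and applied to dataset B,

$$\text{relative AUC}(A \to B) =
  \frac{\text{AUC}(A \to B)}{\overline{\text{AUC}}_{CV}(B \to B)}$$

where the denominator is the *mean cross-validated* AUC of B's own
classifier — never a single fold. Values may exceed 1 and are not clipped.
`cross_eval_analysis()` assembles the full train × test grid with
cross-validation means on the diagonal.

## Matched negatives: four background designs

`sample_matched_negatives()` and `sample_flanking_negatives()` construct
the four negative designs, always at a configurable ratio (default 10
negatives per enhancer), with no negative overlapping any enhancer, any
exclusion region (assembly gaps, blacklists), or any other negative:

* **length_chrom** — random regions matched on length and chromosome;
* **gc** — additionally matched on GC content within an absolute tolerance
  (default 0.02);
* **gc_repeat** — additionally matched on the proportion of the region
  overlapped by repeat elements (tolerance 0.05, union semantics over the
  repeat set);
* **flanking** — drawn from the window extending 10 enhancer-lengths on
  either side of the enhancer, clipped to the chromosome.

GC tolerances are not stated properties of the source datasets, so they
are explicit, configurable parameters here. GC matching does not reject
uniform proposals (which would practically never hit the GC tail where
many enhancers live); instead window GC is computed for *every* candidate
start via cumulative-count arrays and the sampler draws directly from the
genuinely matching positions. If an enhancer's quota cannot be filled, the
tolerance is doubled once with a warning; a second failure is a hard error
naming the enhancer, not a silent shortfall. `N` bases are excluded from
both numerator and denominator of GC so assembly gaps cannot bias the
matching.

The GC-matched design is a *negative control* for sequence composition:
on a synthetic genome whose only enhancer signal is a GC shift, the
GC-matched classifier should fall to chance while the length-matched one
stays well above it. The repeat-free analysis is expressed as a filter
(`repeat_overlap_fraction(x, repeats) == 0`) composed with these samplers
rather than a separate code path.

## Ortholog removal

Cross-species performance could be trivially inflated by enhancers shared
by descent. `filter_orthologous()` removes, from both the training and the
testing set, every interval overlapping (≥ 1 bp) a mapped ortholog pair
connecting the two sets. The overlap threshold for "the same enhancer" is
not specified by the upstream datasets; ≥ 1 bp of the mapped interval is
used and documented as a choice.

## Motif interpretation

The top 5% of positively weighted k-mers (⌈0.05 · 4^k⌉ = 52 for k = 5;
boundary ties broken lexicographically) are matched against a library of
transcription-factor position probability matrices. The matcher is
deliberately simple and exactly testable: score = summed
$\log_2(p/0.25)$ over the aligned overlap (PPM cells floored at 0.01),
maximized over all full-containment offsets and both strands of the k-mer;
the p-value is the *exact enumeration* value — the fraction of all $4^k$
k-mers achieving at least that best score — so p always lies on the grid
$j/4^k$. Note one structural consequence: because both strands are
scored, a non-palindromic consensus k-mer ties with its reverse
complement, so the smallest attainable p is $2/4^k$. This replaces an
external motif-comparison tool with different (unpublishable) null
internals; absolute match counts are therefore not comparable to
TOMTOM/JASPAR-based counts, and only statistics computed from printed
contingency tables are compared against published values.

A TF is *matched* when any of its motifs is matched by any selected k-mer
at p ≤ α, and *shared* when matched in every species. The default match
threshold is α = 0.02, deliberately below a nominal 0.05: exact
enumeration p-values admit ⌊α·4^k⌋ k-mers per motif *by construction*, so
at α = 0.05 a random 52-k-mer selection already matches ~93% of any PWM
library and the shared-TF statistic saturates — the permutation test then
has no power regardless of how strong the planted signal is, while at
α = 0.02 the null stays wide enough for the empirical p-value to remain
calibrated. (The external tool this matcher replaces filters on a
q-value and is far more stringent than p ≤ 0.05 in practice: its
published overall match rate corresponds to roughly the two best k-mers
per motif.) Because planted instances land on either strand and features
are strand-literal, a motif's constituent k-mer vocabulary — used in
recovery checks — includes the reverse complements of its consensus
windows; the planted signal splits between the two. Significance of
sharing uses a permutation null: each permutation draws an independent
uniform random k-mer set of the same size per species and intersects the
induced TF sets (default 100 permutations). The empirical p-value is
reported both as r/n (which can be 0, the convention used for headline
results) and as (r+1)/(n+1) (never 0). Expression enrichment of shared TFs
uses the one-tailed Fisher exact test (hypergeometric tail, sample odds
ratio a·d/b·c), and the overall match-rate comparison uses the exact
binomial tail against the all-k-mer background rate.

## Cross-tissue versus cross-species comparison

Group comparisons of relative AUCs (e.g. cross-species same-tissue versus
cross-tissue same-species) use the Mann-Whitney U test: U counts pairs
with half-credit for ties; p is exact by enumeration of all
$\binom{m+n}{m}$ assignments for $m + n \le 12$ and otherwise uses the
normal approximation with tie-corrected variance and continuity
correction (the continuity correction keeps the large-sample branch
within 0.01 of the exact branch at the crossover sizes, which the tests
assert). One-sided (cross-species better) is the default, configurable.

# The synthetic world

Real multi-species ChIP-seq enhancer compendia cannot ship inside a
package, so `simulate_world()` generates worlds with exactly the
statistical structure the analysis assumes, plus a truth record for
parameter-recovery tests:

* **Genomes** — per-species order-0 background parameterized by GC
  (A=T=(1−GC)/2, C=G=GC/2). This is the simplest model under which the
  GC-matching control is meaningful; it deliberately omits
  higher-order composition, CpG islands and isochores.
* **Repeats** — tandem copies of one 20–50 bp per-species consensus,
  placed in blocks to ≈ the configured genome fraction; a configurable
  fraction of enhancers is forced to overlap a repeat segment so
  repeat-matched and repeat-free analyses are both non-degenerate.
* **Enhancers** — non-overlapping intervals with lengths uniform in a
  configured range, background GC shifted by `enhancer_gc_delta`, and a
  fixed number of motif instances sampled column-wise from the tissue's
  PWMs (species-specific usage weights), planted at non-overlapping
  offsets on random strands.
* **Orthologs** — a star phylogeny: a configurable fraction of each
  tissue's enhancers descends from a common ancestral sequence that is
  independently mutated into each species at that species' neutral
  divergence (each site substituted with probability d by a uniform base,
  so the expected mismatch fraction is 3d/4). Every species pair is
  recorded in the ortholog map.
* **Motif library** — synthetic PPMs with one dominant base per column,
  solved to hit a target per-column information content (default 1.5
  bits). The default library holds 205 motifs, one TF each — the size of
  the standard vertebrate motif collection — of which one 8-motif subset
  defines the default tissue. The large library also keeps the
  shared-TF count distribution under the permutation null wide, which is
  what makes the r/n empirical p-value well calibrated (with a small
  library the null counts are so discrete that ties inflate the mean
  null p above 1/2).
* **Expression** — Bernoulli per TF × tissue: tissue-motif TFs expressed
  with probability 0.9, all others 0.5. At ≈ 30 shared TFs these defaults
  give the Fisher test high power, which the test suite verifies as a
  power property rather than assuming.

Worlds are byte-identical functions of their configuration (including the
seed) and serialize to standard formats: FASTA genomes, BED6 intervals
(0-based half-open, strand "."), MEME v4 motifs, TSV expression and
divergence tables, JSON truth/ortholog records.

## Problem sizes and parameter choices

The reference ("default") world is 3 species × 2 chromosomes × 3 Mb,
100 enhancers of 150–350 bp per tissue with 4 planted instances each,
enhancer GC shift +0.04, 8% repeat coverage, 20% orthologs, and species
backgrounds in a mammal-like 0.40–0.43 GC range. These sizes are chosen
so that (i) a desk-scale machine trains the full 3-species grid in
minutes, and (ii) GC-matched negatives exist at the stated tolerance for
*every* enhancer. The second condition drives two generator choices worth
spelling out. Enhancer backgrounds are drawn with *exact* composition
(the G+C count is fixed at the shifted fraction, the arrangement random)
rather than i.i.d.: under i.i.d. draws, the binomial spread of enhancer
GC puts a tail of enhancers several standard deviations above the genome
GC, where the number of matching windows per genome — roughly
$\Phi(-(\Delta GC - tol)/\sigma_L)$ per start — collapses to zero and
matched sampling must fail. Orthologous enhancers sharpen the problem
because they carry the *ancestral* composition (shifted further toward
0.5 by uniform substitution) into every descendant genome, which is why
the species GC spread is kept narrow. Second, within the tolerance band
the candidate-window density is always skewed toward the genome GC, so
uniform selection inside the band leaves matched negatives systematically
~0.01 below their seeds *and* with a wider GC spread than the positives —
both residually learnable. The sampler therefore does nearest-neighbour
caliper matching: candidates are taken in order of |ΔGC| (random among
ties), which in practice matches the seed's GC count exactly. For the
GC-control study the shift must carry the whole signal, so that world
uses +0.06 with no planted motifs and 80 enhancers of 150–300 bp; +0.06
keeps the length-matched classifier well above chance while leaving the
matched sampler feasible. The two-tissue study uses two species and two
disjoint 6-motif tissues at 60 enhancers per set. The uniform enhancer
length distribution is a modelling choice — the source datasets do not
publish their length distributions.

# What passing tests do and do not show

The synthetic worlds make the pipeline's *inferential machinery* fully
checkable: planted motifs are recovered among the top-weighted k-mers,
shared-usage worlds produce relative auROCs near 1 while disjoint-tissue
worlds do not, GC-matched controls erase pure GC signals, the permutation
p-value is calibrated under its own null. They do not certify behaviour
on real genomes: order-0 backgrounds lack repeat families,
higher-order composition, and correlated motif grammar; planted instances
are independent draws from the PWM rather than co-evolving sites; and
histone-mark enhancer calls carry label noise the simulation does not
model. Published headline AUCs from genome-scale datasets are likewise
not reproducible at package scale; the package reproduces the published
*self-contained* statistics (contingency-table and count-based values)
exactly, and demonstrates the genome-scale claims qualitatively on the
synthetic worlds.

# Numerical and degenerate-input conventions

* Coordinates: BED 0-based half-open at every file boundary; `GRanges`
  (1-based closed) internally.
* GC of an all-N sequence is undefined: `NA` plus a warning, never 0.
* An all-zero spectrum normalizes to the all-zero vector and is flagged
  degenerate rather than erroring, so callers can filter.
* `roc_auc`/`pr_auc` refuse single-class inputs; `relative_auc` refuses a
  zero denominator.
* Rank correlation is undefined for constant vectors and errors
  explicitly; its p-value uses the large-sample t approximation.
* Top-fraction k-mer counts use ceiling (5% of 1024 → 52); boundary ties
  are broken lexicographically so selections are deterministic.
* Sampling failures are loud: one tolerance relaxation with a warning,
  then an error naming the enhancer.

# Interfaces

All stages are plain R functions over Bioconductor containers
(`DNAStringSet`, `GRanges`) and base data frames; `experiment_spec()` /
`run_experiment()` provide the one-call experiment bookkeeping with an
append-only TSV registry, and `cross_eval_analysis()` the grid
orchestration. The package intentionally ships no shell entry point: the
natural interface for this analysis is an R session or script, and the
registry TSV plus the serialized model JSONs are the machine-readable
surface for downstream tools.
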