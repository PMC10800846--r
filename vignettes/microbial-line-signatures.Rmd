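---
title: "Microbial line signatures: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microbial line signatures: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

linesig implements a three-part analysis of small-intestinal microbiome
data from two chicken lines divergently selected for antibody response
(HAS, high; LAS, low): (1) community characterization — filtering,
presence/absence partitioning, observed-OTU alpha diversity, weighted
UniFrac beta diversity with PCoA and PERMANOVA, and per-OTU differential
abundance; (2) discovery of a minimal microbial signature predicting line
via a classifier ensemble with iterative feature reduction; and
(3) linkage of each signature microbe's discretized abundance to host
gene-expression patterns. Label-permutation negative controls accompany
both machine-learning stages. This vignette documents the models, the
tunable parameters and the design decisions; the README shows a worked
example.

## The synthetic study generator

Real sequencing data are not required anywhere: `simulate_study()`
generates a coupled OTU table, phylogeny and expression matrix with known
planted structure, so every downstream stage is testable by recovery.

The design mirrors the study layout: 2 lines × 3 tissues (duodenum,
jejunum, ileum) × 6 biological replicates = 36 samples. Counts are
negative binomial with mean `mu = baseline × tissue × line × depth`:

* **Baseline abundances.** Per-OTU weights are log-normal (sdlog 1.5),
  normalized to relative abundances and scaled by the expected depth.
  Real 16S communities are strongly uneven; a heavy-tailed baseline is the
  standard emulation.
* **Planted OTUs.** `n_discriminative` OTUs (default 20) have their mean
  multiplied by `fold_change` (default 4) in one line (alternating which
  line is boosted); `n_exclusive_per_line` OTUs (default 5) have
  structural-zero mean in the other line, so the exclusivity filter is
  triggerable deterministically. Planted OTUs are drawn from the abundant
  tail of the baseline distribution (log-normal meanlog 3, sdlog 0.7,
  i.e. typical means of a few hundred counts): the real signature taxa are
  dominant lactobacilli, and a planted "signature" microbe at two reads
  per sample would not emulate them.
* **Dispersion.** `nb_dispersion` is the NB phi with
  `var = mu + phi mu^2`; the default 0.25 is moderate overdispersion,
  typical of dominant taxa in replicated 16S designs.
* **Depth.** Per-sample library factors are log-normal with sdlog 0.3
  around `library_size_mean` (default 50,000 — a free parameter; the study
  does not report per-sample depth).
* **Tissue effect.** A per-OTU × tissue log-normal multiplier (sdlog
  0.25) provides a tissue main effect; tissue-specific community
  *structure* beyond that is out of scope.
* **Phylogeny.** `simulate_tree()` draws a random coalescent topology
  (`ape::rcoal`) — any rooted tree with positive branch lengths satisfies
  weighted UniFrac's requirements.
* **Expression.** Gene baselines are uniform on log2 [3, 9] with Gaussian
  log2 noise (`expr_noise_sd`, default 0.25). Each discriminative OTU owns
  a disjoint block of `n_linked_genes_per_otu` genes (default 50) whose
  log2 expression shifts by `expr_effect_size` (default 2) per ordinal
  step of that OTU's discretized abundance class — the link is driven by
  the class, not the raw counts, mirroring stage two's design where the
  class is the classification target. Samples are scaled to a sum of
  10^6 (TPM).

Identical configurations (including the seed) reproduce byte-identical
data. What the generator does **not** emulate: compositional coupling
between OTUs (each OTU is drawn independently given its mean),
zero-inflation beyond what the NB produces, chimeras and sequencing
error, phylogenetic signal in the planted effects (the tree is
independent of which OTUs are planted), and realistic gene–gene
correlation structure. Recovery results on this generator therefore
demonstrate that the pipeline's logic is correct, not that its
sensitivity transfers to arbitrary real communities.

## Community statistics

* **Low-count filter**: OTUs with total count below `min_total`
  (default 10) across all samples are removed; the operation is
  idempotent and keeps totals exactly at the threshold.
* **Presence partition**: an OTU is present in a line if any sample of
  that line has a positive count — no minimum-count threshold, matching
  the purely qualitative Venn semantics.
* **Alpha diversity** is observed-OTU richness (union of positive-count
  OTUs per group); rarefaction and phylogenetic alpha diversity are out
  of scope.
* **Weighted UniFrac**: for samples A and B,
  `d = sum_b len_b |A_b - B_b|` over branches, where `A_b` is the
  fraction of A's counts descending from branch `b`. The normalized
  variant (default) divides by `sum_b len_b (A_b + B_b)`, the pair's
  maximum attainable value, giving distances in [0, 1] comparable across
  pairs; the raw variant is available by flag. The implementation
  accumulates branch masses in postorder; tests compare it against a
  brute-force branch-enumeration oracle at 1e-10.
* **PCoA** is classical metric scaling (`stats::cmdscale`); negative
  eigenvalues are reported and their axes dropped, and explained
  fractions are computed over the positive eigenvalues only.
* **PERMANOVA** uses Anderson's distance-based sums of squares with
  free permutation of sample labels (no strata — the study reports no
  blocking structure). When the number of distinct label assignments is
  at most `n_permutations` the null is enumerated exhaustively and the
  p-value is exact; otherwise `p = (1 + #[F* >= F]) / (1 + n)`. An
  all-zero distance matrix is flagged degenerate with p = 1.
* **Differential abundance** fits a per-OTU negative-binomial GLM (log
  link) of counts on line, with a library-size offset from TMM
  normalization, and a 1-df likelihood-ratio test with the dispersion
  estimated under the full model and held fixed for the null refit. The
  original analysis names only "a generalized linear model"; an NB GLM
  with TMM offsets and LRT is the standard choice for overdispersed
  counts and is what we adopt. Both Benjamini–Hochberg and Bonferroni
  adjusted p-values are reported; the pipeline's default significance
  gate is FDR p <= 0.05. Because the upstream tool's exact GLM family and
  normalization are undisclosed, the published headline counts (e.g. 206
  differentially abundant OTUs) are not reproduction targets.

## Stage one: the microbial signature

Candidate features are ranked by the mean of two ranks: descending
information gain and ascending differential-abundance p-value
(average-rank ties, deterministic id tie-break). Information gain is
`H(labels) - H(labels | binned feature)` in bits after Fayyad–Irani
MDL discretization — the criterion used by WEKA's entropy-based ranker;
a feature whose MDL criterion accepts no split carries gain 0.

The ensemble evaluates three classifiers — a linear-kernel SVM
(`e1071::svm`), a single-hidden-layer perceptron (`nnet::nnet`) and a
CART tree (`rpart`, `minsplit = 2`, `cp = 0`, since the WEKA-style tree
must be able to split a dozen samples) — under two validations: one
stratified 66/34 percent split (test size floored per class: 12 jejunum
samples split 8/4 as 4+4 vs 2+2) and stratified K-fold hold-out with
K = 6, the number of biological replicates, each fold held out once and
the cell reported as the mean of the six runs. `average_accuracy` is the
arithmetic mean of the six cells. Features are standardized inside each
training fold; raw counts are the default attribute scale (relative
abundances can be passed instead by transforming the table first).

Two numerical choices deserve note. First, the perceptron's
conventional `(p + k)/2` hidden-unit sizing is capped so the total
weight count stays near 600 (`max_weights`): `nnet`'s quasi-Newton
optimizer scales quadratically in the weight count, and with a dozen
training samples additional units add cost, not fit; 100 epochs with
weight decay 0.1 is ample for convergence at this scale. Second, fold
assignment is random within strata; if a draw would leave a training
partition with a single class it is redrawn (up to ten times, logged).

`reduce_features()` drops the worst-ranked 20% (at least one feature)
per iteration down to a floor of 5, re-evaluating with the same seed so
fold assignments are comparable across iterations. Its `best_set` is the
accuracy-maximizing set, smallest on ties. With strongly planted signal
the average accuracy saturates at 1.0 well above the floor, so the
smallest tied set is the floor itself — a 5-OTU set maximizes a saturated
criterion vacuously. The pipeline therefore carries forward a *candidate
set* of about `signature_size` features (default 20; the iteration with
the smallest count at or above the target), matching the workflow of
taking the top twenty OTUs into individual evaluation, and then applies
the two filters: per-OTU ensemble accuracy >= 0.75 (each OTU as the sole
attribute, same seed) and presence in at least one sample of each line.
OTUs exclusive to one line are removed however predictive they are,
because their "prediction" is simply line membership re-encoded.

## Abundance classes

For each signature OTU, per-sample counts are discretized relative to
the mean:

* some samples at zero (`with_absent`): `m` = mean of the nonzero
  counts; 0 → Absent, count > m → High, otherwise Low (a count exactly
  at the mean is Low — strict inequality);
* all samples positive (`all_present`): `m` = mean of all counts;
  count > 1.5 m → High, count < 0.5 m → Low, the closed interval
  between → Medium.

"Mean ± 50%" is read multiplicatively (1.5 m and 0.5 m), the only
depth-scale-free reading; the classes are therefore invariant to
rescaling all counts. The `with_absent` mean is computed over the
present samples only, and over whatever sample universe is passed in
(the pipeline passes the stage-one tissue slice). A vector that yields a
single class is flagged degenerate and excluded from stage two rather
than raising an error. Ordinal encoding for the expression link runs
along the scheme's realized ladder (Absent/Low/High or Low/Medium/High
→ 0/1/2).

## Stage two: expression patterns predicting abundance class

Genes are ranked by information gain alone against the OTU's class
labels (no p-value exists for this contrast), on the log2(TPM + 1)
scale — TPM is the input unit and the log stabilizes classifier
behaviour. For each candidate list size the same ensemble runs with the
top genes as attributes and the class as target; the best size maximizes
average accuracy, smallest on ties. The default size grid
{35, 50, 83, 100, 228, 312, 339, 349, 500} spans the reported range of
optimal list sizes (35–500) without claiming the original search
procedure, which is unstated; a powers-of-two grid is substituted when
fewer genes are available. With a dozen samples and up to four classes,
strictly stratified folds are often impossible: classes with fewer than
two samples are merged into their nearest ordinal neighbour *for fold
construction only* (Absent → Low; Medium → the larger of Low/High), the
merge is recorded, and a sample whose true class is missing from a
training partition simply scores as an error.

## Negative controls

`run_control()` re-runs the full ensemble on datasets whose labels are
reassigned by a uniformly random non-identity permutation (features
untouched), ten times by default, and reports the per-run averages, the
grand mean, the chance level and the gap. Chance is the empirical
majority-class frequency — 0.5 for balanced two-class labels, ~1/3 for
balanced three-class labels — rather than 1/#classes, because real
discretizations are not guaranteed balanced. Control seeds are derived
from the main seed by hashing and never coincide with it. No permutation
p-value is claimed; the gap and its Monte-Carlo standard error are
reported.

## Pipeline, reproducibility and problem sizes

`run_pipeline()` executes data acquisition → filtering and diversity →
differential abundance → stage one (jejunum slice by default) →
discretization → stage two → controls, writing every stage's artifacts
as TSV/JSON plus a manifest; `render_report()` rebuilds the report from
the serialized artifacts alone, so any stage can be re-run or audited
independently. All stage seeds are derived from the master seed by a
deterministic hash of the stage name, making stages reproducible
independently of execution order; identical configurations reproduce
identical result files.

The test suite exercises recovery at the full design (450 OTUs, 36
samples, 2000 genes) over 20 simulation seeds for both stages, type-I calibration on pooled per-OTU tests from five 450-OTU
null tables and 1000 simulated null PERMANOVA datasets, and oracle
equivalence on 25 random UniFrac instances — sizes chosen to keep
Monte-Carlo error small relative to the tolerances they support.

## Known limitations

* The signature search is greedy (rank-and-drop), not exhaustive; it
  inherits the ranking's blind spots (an OTU informative only jointly
  with another can be dropped early).
* Accuracy saturation at n = 12 makes the "best" feature set weakly
  identified; the target-size candidate set is a pragmatic, documented
  choice, not an optimum.
* Per-OTU NB GLMs with 36 samples rely on the chi-square approximation
  of the LRT; calibration is verified empirically at the null but exact
  small-sample control is not claimed.
* Pathway enrichment on the exported gene lists is out of scope (the
  upstream tool is proprietary); the package exports ranked lists.
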