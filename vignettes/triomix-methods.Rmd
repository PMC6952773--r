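---
title: "Methods: pathway-level multi-omics integration with triomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway-level multi-omics integration with triomix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`triomix` integrates transcript, protein and metabolite tables measured
on the same samples into pathway-level evidence, extracts persistent
feature clusters, and searches for small multivariate biomarker panels.
This vignette documents the statistical model behind each stage, the
tunable parameters, the synthetic study the generator emulates, and the
design choices made where more than one reasonable formulation exists.

## The model, stage by stage

### Normalization and filtering

TIC normalization rescales each sample column so that all column totals
equal the mean of the original totals — the standard equal-total-signal
assumption for label-based LC-MS quantification. It preserves
within-sample proportions and feature ranks. One caveat matters for
interpretation: TIC is compositional. If a sizeable set of features
moves in one direction in one condition, the rescaling pushes every
other feature slightly the opposite way. The downstream pathway test is
*competitive* (members versus random member sets from the same layer),
so this global shift cancels; per-feature differential calls, however,
inherit it, exactly as they would in a real TMT experiment.

Proteins identified by a single unique peptide ("singlets") are removed
before analysis (`filter_singletons()`, threshold `min_peptides = 2`):
one peptide gives no internal replication of the identification and
such entries are unreliable at the quantification stage.

Differential calls use Welch's two-sample t-test on log2 intensities.
A feature is called significant only when both thresholds are met: a
linear change above `min_change`
(default 0.15, i.e. >15% up or down, `|ratio − 1| > 0.15`) and
`p < alpha` (default 0.05). Welch rather than the pooled-variance t is
the conservative default because condition variances need not be equal.
Zero intensities are replaced by half the smallest positive value in
the layer before taking logs; this is configurable only by
pre-transforming the table, and is deliberately simple — imputation is
out of scope.

### Persistence statistics

For pathway scoring, each feature receives a *persistence z-score*: the
Welch-t condition contrast is computed within each sample group
separately, converted to a signed normal quantile, and the per-group
z-scores are combined by Stouffer's method (sum divided by √k). A
feature whose hypoxia response keeps one sign in fetal, adult-male and
adult-female samples accumulates |z| ≈ √3 × per-group z; a response
confined to one group is diluted. This operationalizes the search for
effects that persist across development rather than group-specific
ones, and it uses every sample without pooling variances across groups.

### Competitive pathway test

For one pathway in one layer, the observed statistic is the mean |z| of
its mapped members (at least `min_members = 3` scored members required;
below that the layer is omitted for that pathway rather than imputed).
The p-value is the permutation tail probability that a uniformly drawn
member set of equal size has mean |z| at least as large, with the +1
continuity correction:

p = (1 + #{permutations ≥ observed}) / (n_perm + 1).

The correction floors p at 1/(n_perm+1), which keeps ln p finite for
Fisher's method. `exact = TRUE` enumerates all member sets instead —
feasible for small instances and used as the oracle route in tests.
The default `n_perm` is 10,000 for standalone use; the pipeline default
is 2,000, which resolves the floor at 5 × 10⁻⁴ per layer — ample,
because the ranking is driven by the combined statistic and the number
of contributing layers once signals saturate.

### Fisher combination

Per-layer p-values are combined with X² = −2 Σ ln pᵢ referred to a
chi-square distribution with 2k degrees of freedom, k the number of
layers that were testable for the pathway. Letting k shrink (instead of
imputing p = 1 for untestable layers) means a pathway measurable in all
three layers can reach lower combined p than one measurable in two —
intended behavior: more independent observations, more evidence.

### Assignment capping

Overlapping pathways reuse the same measurements; ranking them
independently overstates the evidence. `dp_rank()` selects a set of
pathways to retain and an explicit entity-to-pathway assignment, where
an *entity* is a layer-tagged data point (the same gene measured as
transcript and as protein is two entities). Constraints: each entity
supports at most `cap` pathways (default 2) and each retained pathway
keeps at least `min_members` entities (default 3). Objective:
Σ −log10(combined p) over retained pathways.

Two regimes, both reported in the result:

* **exact** (≤ `exact_max` = 10 pathways): pathway subsets are
  enumerated in decreasing objective; the first subset for which a
  bipartite flow (entity capacity `cap`, pathway demand `min_members`)
  saturates all demands is optimal. Feasibility is monotone — adding a
  pathway never helps the others — so this search is sound.
* **greedy** (larger instances): pathways are processed in decreasing
  score (ties: more members, then id); each claims its members with
  spare capacity and is dropped if fewer than `min_members` remain.
  The first pathway is always retained, so the greedy objective is
  bounded below by the best single pathway.

After the retain decision, remaining entity capacity is distributed so
retained pathways keep every member they can — this does not change the
objective but makes the reported `n_entities_retained` meaningful.

`rank_report()` orders pathways by combined p ascending, breaking ties
by `n_entities_retained` descending and finally by id. The secondary
key is deliberate: with strong signals both a planted module and a
50%-overlapping decoy can floor their permutation p-values in every
testable layer, and the pathway explaining more retained measurements
is then the better "solution for the overall data trend". BH FDR is
computed across all testable pathways.

### Embedding and consensus clusters

Feature profiles (per-gene log2 intensities, row-standardized within
each layer, transcript and protein sample vectors concatenated) are
embedded in 2-D by Barnes–Hut t-SNE with perplexity 20, a PCA reduction
to the first 50 components (capped at the available dimensionality) and
early-exaggeration factor 4. "Exaggeration" is read as the early
exaggeration multiplier of the attractive forces — the common meaning
in t-SNE implementations; this is an interpretation, flagged as such.
The embedding is repeated 15 times with seeds `base_seed + 1 … + 15`.

Each run is density-clustered: points closer than a radius — the 90th
percentile of 5-nearest-neighbor distances — are connected, connected
components of at least `min_cluster = 5` points are clusters, the rest
is noise. Runs are aligned to the first run by greedy maximal overlap
of the label contingency table and a per-feature majority vote yields
the consensus. Stability is the mean pairwise adjusted Rand index of
per-run labels; below `stability_min = 0.8` the extraction attaches a
warning status rather than failing. The largest consensus cluster is
the "main data stream"; every other cluster is an outlier cluster and
is directed by the sign of its members' mean fetal-minus-adult profile
(positive → group 1, up in fetal; negative → group 2). The density rule
is a reproducible stand-in for what is, in practice, often a visual
call on the embedding plane; reports carry the parameters used.

### Enrichment

Outlier-cluster genes are tested against annotation terms with the
one-sided hypergeometric test; the universe defaults to genes
quantified in at least two layers, mirroring the integration scope.
Terms smaller than `min_term_size = 3` after intersection with the
universe are skipped; BH FDR is computed across tested terms. Counts
are reported as `k/K` (hits over term size), the familiar
"count in gene set" format.

### Biomarker panels

`manova_test()` computes Wilks' Λ = det(W)/det(T) from the within- and
total-SSCP matrices with Rao's F approximation (exact for two
conditions; for a single feature it reduces to the one-way ANOVA F).
Near-singular panels (reciprocal condition number below 1e-10) are
rejected naming the offending features, so duplicated or collinear
features fail loudly instead of producing unstable determinants.

`search_panels()` tests **all** combinations of size 1 to `max_panel`
(default 6) — but from a candidate pool of the `pool_size` (default 20)
features with the smallest univariate Welch p. Exhausting all
combinations of thousands of proteins is combinatorially impossible;
restricting to a top-K pool preserves the "all possible combinations"
semantics inside a feasible candidate set, and the restriction is
recorded in the result object. Panels whose p beats their best member
singleton are flagged synergistic. Raw p-values are reported (panels
are hypotheses to rank, not calls); a BH column is added for
transparency. Panel sizes infeasible for the sample count
(n ≤ size + groups − 1) are skipped with a message.

### Custom proteome database

Transcripts are translated in all six frames; ORFs are maximal
stop-free stretches (stop-to-stop, no initiator methionine required —
the goal is all possible encoded peptides, not gene prediction) of at
least `min_orf_len = 20` aa, below which fragments are under the scale
of useful peptide evidence. Codons containing N translate to X. A
reference protein is retained iff it shares an exact ungapped amino
acid substring of at least `min_match_len = 30` aa with some ORF. The
evidence criterion had to be decided (cross-referencing can be
implemented many ways): exact shared substring is deterministic,
aligner-free, and brute-force verifiable; both lengths are exposed as
parameters because reasonable analyses may want stricter or looser
evidence.

## What the generator emulates — and what it does not

`simulate_multiomics()` produces the study design the pipeline assumes:
three groups (fetal, adult male, adult female) × two conditions
(normoxia, hypoxia) × `n_replicates = 5`, with a transcript, a protein
and a metabolite layer over a shared universe (defaults: 500 genes, 120
metabolites). Intensities follow a multiplicative log-normal noise
model — log2 intensity = feature baseline (uniform on [6, 12]) +
planted effects + N(0, `noise_sd` = 0.25) — and transcripts are rounded
to counts. One noise engine serves all three layers because the
pipeline consumes normalized intensities, not raw counts; negative
binomial count noise is deliberately not modeled.

The planted module (40 genes, 10 metabolites) carries a log2 condition
effect of 1.0 with the *same sign in every group and layer* — the
persistent-change signature the integration is designed to find. Half
the module is additionally elevated in fetal samples and half
suppressed (log2 ± 1), so the embedding stage sees two directed outlier
clusters. One decoy pathway always overlaps the planted module by 50%
(plus random fillers) to exercise the assignment cap, and one
annotation term covers exactly the module. Null features carry zero
effect everywhere. Singlet unique-peptide counts (20% of background
proteins) are planted off the module so the planted signal is not
arbitrarily thinned by the filter — the filter's accounting is tested
separately with uniformly placed singlets.

The replicate-level variance structure of the real study is not public;
`noise_sd = 0.25` (≈ 19% CV) is a typical within-group spread for
TMT-style data and is a package parameter, not a claim about any
particular experiment. The generator does not simulate batch effects,
missing values, raw spectra or reporter-ion channels, broad
fetal-versus-adult remodeling of the background features, or annotation
bias; passing tests therefore demonstrate correctness of the machinery
and recoverability of a coherent planted signal under realistic noise —
not robustness to every artifact of real data. The RNG is R's default
Mersenne-Twister; one seed fixes the entire dataset byte-for-byte.

## Numerical choices and degenerate inputs

* Permutation p floored at 1/(n_perm+1); exact mode divides by the full
  subset count, and the observed set counts itself, so p > 0 always.
* `fisher_combine()` rejects p outside (0, 1] rather than clamping.
* Zero-total sample columns fail TIC normalization naming the sample.
* Constant matrices are rejected by PCA as degenerate.
* K-means uses 25 restarts with a fixed per-k seed; the silhouette tie
  goes to the smallest k. Fewer distinct points than the largest k is
  an error.
* t-SNE requires n_features > 3 × perplexity + 1; each run is seeded
  `base_seed + run`, making every coordinate reproducible.
* Cluster-label majority votes break ties toward the smaller label, so
  drawn votes fall back to background.
* MANOVA guards determinants with a reciprocal-condition threshold and
  reports the feature names on failure.
* All pipeline outputs carry `version / seed / parameter-hash` header
  comments; the manifest stores md5 checksums so a rerun with the same
  configuration can be verified byte-for-byte.

## Problem sizes in the shipped tests

The test suite exercises the pipeline at sizes chosen to make
brute-force verification exhaustive and end-to-end runs quick: the
default synthetic study (500 genes, 30 samples, 15 pathways) for
end-to-end recovery over 20 seeds; ≤ 8 pathways × ≤ 10 entities for
exact-versus-enumeration assignment checks; 10-feature universes for
exhaustive permutation enumeration; 300-nt sequences for codon-loop
translation oracles. These sizes are the package's own verification
design: every scale-sensitive algorithm (greedy assignment, k-mer
matching, batched translation) is compared against an independent
brute-force implementation in the regime where brute force is exact.

## Known limitations

* The competitive pathway test conditions on the observed z-field; it
  does not model inter-feature correlation within pathways, which can
  make p-values liberal when members share technical covariance.
* The assignment cap formulation (entities capped at M pathways,
  retained pathways keeping ≥ min_members) is one reading of
  "limit the number of assignments of each data point"; capping at 1
  and ranking pathways rather than entities are alternative readings.
  The chosen formulation is exact, testable, and reported alongside the
  regime that produced it.
* Density-based cluster extraction replaces a human call on the t-SNE
  plane; its radius/size parameters are exposed and reported, but no
  claim is made that they match any particular manual gating.
* Enrichment uses local GMT files only; orthologue mapping and live
  database retrieval are out of scope.
* Biomarker panels are ranked by raw MANOVA p within a top-K pool;
  cross-validated classification performance is a different question
  and out of scope.
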