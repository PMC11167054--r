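---
title: "Methods: thermodynamic modeling of transcribed enhancers"
author: "eRNAthermo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermodynamic modeling of transcribed enhancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eRNAthermo)
```

## The problem

Upon estrogen stimulation, thousands of genomic regions in ER+ breast
cancer cells carry both an ERα ChIP peak and the active-enhancer mark
H3K27Ac, yet only a minority are transcribed into short bidirectional
enhancer RNA (eRNA). Because eRNA transcription marks functionally active
enhancers and is detectable genome-wide in nascent-transcription assays, it
provides a binary activity readout for a sequence-to-expression modeling
exercise: which sequence features, and which underlying TF-level
mechanisms, distinguish the transcribed from the silent subset? All
regions in the comparison already share ERα binding and H3K27Ac, so
whatever separates the classes must go beyond those two signals.

`eRNAthermo` implements that exercise end to end: class labeling from
replicate peak tracks, motif-feature construction, Random Forest feature
triage, ensembles of thermodynamic sequence-to-expression models with a
classification objective, in silico perturbations, and mechanism-aware
variant scoring.

## Class labeling

Candidate enhancers are the intersection intervals of two merged, scored
peak tracks (ERα and H3K27Ac ChIP). Peaks below score 5 are dropped and
retained peaks within 100 bp of each other are merged before intersection;
both settings are exposed (`thresholdAndMerge`). A candidate is labeled
**positive** when it overlaps (≥ 1 bp) at least one nascent-transcription
peak in *each* of the two post-treatment replicates and overlaps neither
pre-treatment replicate track; **negative** when it overlaps no
post-treatment peak at all; anything else — single-replicate support, or
two-replicate support with pre-treatment signal — is **excluded** as
ambiguous. The exclusion rule deliberately discards potential false
negatives (regions with signal in only one replicate) rather than risking
label noise in the negative class. Pre-treatment overlap excludes only
otherwise-positive regions: the quoted labeling rules define negatives
purely by the absence of post-treatment signal, and we do not extend the
pre-treatment filter to them.

Partitioning is per class: `floor(n_class / 5)` of each class is held out
for testing by default, and a further explicit-count train/validation
sub-split (`splitTrainValidation`) supports the two-stage design in which
the thermodynamic stage consumes its own training and validation subsets.

## Motif features

Scanning uses log-likelihood ratios in natural log units; only ratios and
thresholds matter, so the base is an internal convention. PWMs receive a
pseudocount (default `1e-3`, added to probabilities and renormalized) so no
column is degenerate. The background is order-0 with configurable
frequencies (uniform by default) — the simplest model consistent with LLR
scoring; the synthetic generator uses the same background, so feature
nulls are exact.

Two design points deserve emphasis because the underlying conventions are
genuinely open:

* **Putative-site floor for the affinity sum.** The summed-affinity
  feature adds `LR = e^llr` over "putative sites". Summing over *all*
  windows would bury signal under thousands of near-zero terms, so the
  default floor is `llr > 0` (`LR > 1`, i.e. windows that look more like
  site than background), with the floor exposed as a parameter (`-Inf`
  reproduces the unconditional sum). The strict p = 1e-4 threshold is
  reserved for calling the discrete sites used by the adjacency features,
  which is where a hard site list is actually required.
* **Adjacency distance.** "Within 50 bp of each other" is measured
  start-to-start by default (edge-to-edge is available). Homotypic pairs
  count unordered distinct pairs within one site list.

Site thresholds are calibrated per motif as the smallest achievable window
score whose exact null tail probability (computed by dynamic programming
over the per-column score distribution, scores discretized on a 1e-3-nat
grid) is at most the target p-value. The returned threshold is lowered by
the worst-case accumulated rounding (half a grid step per column) so
discretization can never silently exclude a true site; the bias is
bounded by `L/2` grid steps, i.e. a few thousandths of a nat.

With `M` motifs the feature matrix has `M` affinity columns followed by
`M(M+1)/2` adjacency columns (upper triangle with diagonal); z-scoring
uses the sample standard deviation and maps constant columns to zero.

## Random Forest triage

The classifier is a 1000-tree Random Forest with per-tree down-sampling of
the majority class to minority size (the classes are ~1:3.7 imbalanced in
the motivating data). `mtry` is chosen by repeated stratified 6-fold
cross-validation on mean held-out AUROC; repeats default to 3 and folds
are stratified because per-fold class composition is otherwise unstable at
these class sizes. Importance is the raw (unnormalized) mean increase in
out-of-bag error upon permuting a feature, and the top-k features (k = 16
by default) are mapped to the TF set and interaction pairs of the
thermodynamic stage: affinity features contribute TFs, adjacency features
contribute allowed pairs (plus any literature-motivated extras passed
explicitly).

AUROC is computed by the trapezoid rule with tied scores grouped; AUPRC by
step-wise precision interpolation. Under these conventions a constant
scorer has AUPRC exactly equal to prevalence — the 0.21 baseline for an
89-positive / 333-negative test set — which the test suite pins down.

## The thermodynamic model

Each enhancer is reduced to its called sites, each carrying a relative
affinity `r = LR_site / LR_optimal ∈ (0, 1]` against the motif's best
possible window. The model defines a Boltzmann ensemble over all
configurations of bound and unbound sites, subject to steric exclusion (no
two bound sites may overlap — the standard configuration constraint in
this model family). The OFF-ensemble weight of a configuration multiplies
`K_t · r` per bound site; the ON ensemble (basal machinery bound)
additionally multiplies `tau_t` per bound site; consecutively bound sites
of an allowed pair within `coopDistance` multiply `omega`. Predicted
activity is the BTM occupancy `q_BTM Z_on / (Z_off + q_BTM Z_on)`.

Numerical and structural choices:

* **Nearest-bound-neighbor cooperativity** within 50 bp (matching the
  adjacency feature window; the interaction range is not dictated by the
  model family and is configurable). This admits an exact dynamic program
  (`A_i = w_i (1 + Σ_j A_j ω_{ji})` over compatible predecessors `j`),
  verified against brute-force `2^n` enumeration to machine precision in
  the tests.
* **TF concentrations are absorbed into `K`** — the data are a single
  cellular condition, so binding strength and abundance are not separately
  identifiable.
* **`q_BTM` is fixed at 1.** The logistic mapping (`alpha`, `beta`)
  already absorbs any monotone rescaling of `yhat`, so `q_BTM` is
  redundant as a free parameter; fixing it also keeps the free-parameter
  count at `2·nTF + nPairs + 2`. For the motivating 17-TF / 9-pair
  configuration that is 45; published descriptions of the equivalent
  configuration quote 44, a one-parameter discrepancy that cannot be
  resolved from the text (most plausibly one additional fixed parameter),
  and which does not affect any behavior tested here.
* **Objective.** `Σ ln(1 + exp(-y·α·(ŷ−β)))` with `y ∈ {−1, +1}`; at
  `ŷ = β` each example contributes exactly `ln 2`. Because the objective
  only uses the *ordering*-plus-logistic transform of `ŷ`, raw predicted
  activities are not interpretable as absolute expression; all downstream
  effect sizes are therefore computed on the percentile scale (below).
* **Optimizer.** Bounded Nelder–Mead simplex in log-parameter space
  (linear for `beta`), with boxes mapped through a scaled logistic
  transform so the search is unconstrained; default budget 2000 objective
  evaluations. Default boxes: `K, tau ∈ [1e-3, 1e3]`, `omega ∈ [1e-2,
  1e2]`, `alpha ∈ [0.1, 100]`, `beta ∈ [0, 1]`. The fit never returns a
  model worse than its initialization, and a zero-iteration call returns
  the initialization unchanged.
* **Ensembles.** Initializations are sampled uniformly in log-space within
  the boxes; the ensemble is filtered on validation data as the union of
  the top-k models by AUROC and by AUPRC (so between `k` and `2k`
  survive). Multi-start ensembles are the package's answer to
  identifiability: individual parameter values are only interpreted when
  they are consistent across the selected ensemble.

The site-calling threshold inside the thermodynamic stage defaults to the
same p = 1e-4 value as the feature stage; the two share a configuration
key rather than guessing different conventions.

## Perturbations, regulons, networks

A TF knock-down sets `K_t = 0` (its sites can never be bound); an
interaction nullification sets `omega = 1`. Effects are reported per
enhancer as `percentile(perturbed) − percentile(WT)`, where percentiles
are always taken against the scoring model's wild-type prediction
distribution over all enhancers — this bounds deltas to [−100, 100] and
makes models with different `alpha/beta` comparable. Knocking down an
activator gives negative deltas; this sign convention is pinned by
closed-form single-site tests.

"Affected" means `|delta| ≥ 5` percentile points; fractions affected and
means over affected enhancers are computed per model and then averaged
across the ensemble (both directions are reported; absolute deltas define
"affected" since a perturbation's direction is a per-enhancer property).
Regulon membership, by contrast, uses the *ensemble-mean* delta against
the ±5 threshold, so a regulon is a single consensus set rather than a
per-model family. Positive-vs-negative class contrasts use Wilcoxon
rank-sum tests with Benjamini–Hochberg adjustment across perturbations.
Enrichment of a predicted regulon against an experimentally derived target
set uses the exact hypergeometric upper tail.

The tripartite network connects TFs to regulon enhancers and enhancers to
genes either by TSS proximity (±10 kb) or by user-supplied chromatin
interaction pairs, which may bridge arbitrary genomic distance.

## Variant scoring

A single-nucleotide variant is applied to its host enhancer (reference
mismatches are an error, not a warning — they indicate stale coordinates),
the mutant is re-annotated from scratch (sites may appear, disappear, or
change strength), and the per-model effect is the mutant-minus-WT
percentile difference against the WT-only reference distribution. Ranking
uses `|delta|` by default (signed ranking is a flag); ties break on
variant id for determinism. The mechanism annotation reports, per TF, the
change in the best window LLR overlapping the variant, normalized by the
TF's maximum called-site LLR across the analyzed collection (the PWM's
theoretical maximum is a configurable alternative; the collection maximum
keeps the scale grounded in sites that actually occur). Indels and
multi-nucleotide variants are rejected explicitly.

Prioritization is evaluated as precision against a true set, with two
baselines: location-based (sampling the same number of variants uniformly
from the in-enhancer pool) and random (sampling from the full collection),
each resampled; a t-test compares the model-based and location-based
precision distributions.

## The synthetic benchmark

The generator emulates the statistical structure the analysis relies on:
two enhancer classes whose sequences differ in planted activator /
repressor site content and planted cooperative adjacencies; four replicate
peak tracks consistent with the labeling rule (with a per-replicate
dropout probability, so noisy replicates produce "excluded" regions
exactly as real data do); and SNVs that destroy planted sites (most
informative column set to the worst base), create sites from planted
near-consensus decoys, or fall outside all planted elements.

Defaults are fixed once: 200 positive and 600 negative enhancers (the
thermodynamic-stage training composition of the motivating analysis),
500 bp enhancers (typical merged-peak scale), uniform background, 8-bp
motifs with dominant-base probabilities in [0.80, 0.95] (information
content comparable to curated vertebrate PWMs), 50-bp cooperation
distance, and uniform non-overlapping site placement. Planted sites are
sampled from the PWM by default, which disperses site strengths the way
genomic sites are dispersed; `siteMode = "consensus"` plants exact
consensus sequences and is used in benchmarks whose point is site-level
recovery (parameter-sign recovery, regulon precision, variant detection),
where the planted architecture *is* the known generating model.
Non-overlapping placement keeps the steric-exclusion rule exercised by
dedicated overlapping-site fixtures in the tests rather than by default
data. Variants are SNVs only, and no chromatin, nucleosome or read-level
noise is simulated.

What passing tests do and do not show: the benchmark demonstrates that
each algorithm recovers what was planted under its own assumptions (the
background model is the generator's, sites are independent, labels are
noiseless at zero replicate noise). It does not demonstrate performance
on real enhancers, where motif content is correlated with chromatin
state, the background is inhomogeneous, and labels carry assay noise —
the motivating analysis' published performance numbers (test AUROC ≈ 0.7
at desk scale cannot be reproduced without the original external data)
remain the reference point for that regime.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale: tens to
hundreds of enhancers, 2–5 motifs for model-fitting benchmarks, ensembles
of 3–6 initializations with a few hundred simplex evaluations, 100
random instances for the partition-function property test, and 10 seeds
for sign recovery. These sizes were chosen so the full pipeline exercises
every code path in a few minutes while leaving the statistical assertions
comfortably powered; all sampling flows from explicit integer seeds, and
every generator output is byte-identical under a fixed seed.

## Known limitations

* Condition-specific TF concentrations are not modeled (absorbed into
  `K`); comparing conditions requires refitting.
* The thermodynamic stage models only the TFs and pairs selected upstream;
  de novo motif discovery is out of scope.
* Short-range repression/quenching variants of the configuration model are
  not implemented.
* Percentile effects are relative to the analyzed enhancer collection; they
  are not absolute expression changes.
* Variant scoring treats each SNV independently; linkage between variants
  and multi-variant haplotypes are not represented.
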