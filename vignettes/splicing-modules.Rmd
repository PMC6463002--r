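---
title: "Splicing-module discovery: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splicing-module discovery: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicemod)
```

`splicemod` identifies groups of alternative-splicing events that are
perturbed together in tumors, scores how strongly each group deviates
from normal tissue in every sample, and asks whether that deviation
predicts survival. This vignette explains the statistical model behind
each stage, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where the procedure was genuinely open.

## The data and its preprocessing

The unit of measurement is the percent-spliced-in (PSI) value: the
fraction, in [0, 1], of a gene's transcripts that realize one splicing
outcome (an exon included, an intron retained, ...) in one sample.
Events belong to six classes: exon skipping (ES), retained intron
(RI), alternative donor (AD), alternative acceptor (AA), mutually
exclusive exons (ME), and alternative terminator (AT). Alternative
promoters are deliberately out of scope — their regulation is mostly
transcriptional, not spliceosomal.

PSI quantification fails where coverage is thin, so the pipeline first
filters: an event is kept only if its missing fraction is at most 10%
among normal samples *and* at most 1% among tumor samples; afterwards
any tumor sample still missing more than 0.1% of the retained events
is dropped. All three thresholds are inclusive ("≤ max" retained)
because the removal rules are stated as strict exceedances. Normal
samples are never removed by the sample rule — they are the reference
population and are typically scarce. The order (events first, then
samples, with sample missingness evaluated on the event-filtered
matrix) is fixed and documented so results are reproducible; the two
filters are idempotent as a pair.

Remaining gaps are filled by k-nearest-neighbor imputation over events
(default k = 10): for a missing cell the k events closest in Euclidean
distance over mutually observed samples, among events observed at that
sample, are averaged; imputed values are clipped to [0, 1] and ties in
distance break by event order, making imputation fully deterministic.
An event with no observed value at all is an error naming the event.

One interaction deserves a warning: with missingness spread uniformly
and large tumor cohorts, the 1% event rule lets through events with
one or two missing tumor cells, and the 0.1% sample rule then removes
many samples. Real PSI missingness is concentrated in specific
low-coverage events rather than uniform, which is why the published
thresholds behave sensibly on real data. Synthetic experiments that
want to keep every sample should use a low `missing_rate` (the default
0.002 with the default 40-tumor cohort behaves like real data: events
with any missing tumor cell fail the 1% rule outright, so surviving
events are complete in tumors).

## Differential splicing

Each event is tested for a tumor-versus-normal location shift with a
Wilcoxon test. TCGA-style tumor and normal cohorts are mostly
unpaired, so the default is the rank-sum (Mann–Whitney) form on the
full groups; a paired signed-rank mode exists for matched designs.
The exact null distribution is used when the combined sample size is
at most 25 and no ties are present; otherwise the normal approximation
with tie-corrected variance (no continuity correction). Degenerate
input — every value identical — reports P = 1 with a flag rather than
failing.

Effect size is ΔPSI = mean(tumor) − mean(normal); a median variant is
available. P-values are adjusted by Benjamini–Hochberg, and an event
is called differential when q < 0.1 and |ΔPSI| > 0.1, both strict, the
conventional thresholds for this kind of analysis. Both cutoffs are
exposed as parameters.

## Network reconstruction

Pearson correlations between differential events, computed over tumor
samples only, become edge weights of an undirected graph. Tumor-only
is a deliberate choice: the network should describe covariation of
the *cancer* state, while normals serve as the scoring reference; an
all-samples option exists, and Kendall's tau-b is available as a
robustness check (partitions from the two weightings agree closely on
synthetic cohorts, which the test-suite verifies with the adjusted
Rand index).

Random walks need nonnegative weights, so correlations are
transformed. The default is the absolute value: anticorrelated
co-membership is real in splicing (a switch between two outcomes of
the same regulatory program produces strong negative correlations) and
should keep such events in one module. A `positive_only` transform is
available for sensitivity analysis. No hard correlation threshold is
applied — the graph stays dense and only exact zeros are excluded —
because any cutoff would be an extra, unstated parameter.

## Walktrap module identification

Community detection follows the Pons–Latapy random-walk scheme. With
edge weights w and strengths d(i) = Σ_j w_ij, the walk's transition
matrix is P_ij = w_ij / d(i); the t-step profile of vertex i is row i
of P^t (default t = 4, sensible range 3–5). Vertices (and communities,
via the mean of their members' profile rows) are compared by the
strength-weighted distance

r²(C₁, C₂) = Σ_k (P^t_{C₁k} − P^t_{C₂k})² / d(k).

Starting from singletons, the two *adjacent* communities with the
smallest Ward-style criterion

Δσ = (1/n) · |C₁||C₂| / (|C₁|+|C₂|) · r²(C₁, C₂)

are merged until one community per connected component remains. The
merge tree is then cut at the level maximizing weighted modularity
Q = Σ_c (e_c/m − (d_c/2m)²), with ties resolved toward fewer
communities. Numerical choices:

* **Tie-breaking in merges** is lexicographic on the community-id
  pair (singletons are numbered by vertex order, merged communities by
  creation order). The criterion has exact ties on symmetric toy
  graphs, and determinism is required for testing; on real correlation
  graphs ties are measure-zero.
* **Disconnected graphs**: each component is agglomerated separately
  (walk profiles are undefined across components) and the modularity
  cut is computed over the concatenated merge sequence.
* **No self-loops** are added. On tiny bipartite-like toys the walk is
  periodic (a single edge at t = 4 returns home), which is documented
  as a caveat; dense correlation graphs do not exhibit it.
* Profiles are stored pre-scaled by 1/√d(k), so community distances
  are plain Euclidean distances and each merge updates a single
  weighted mean — the whole candidate matrix is recomputed
  vectorized per step, which is exact (not an approximation) and fast
  at the few-hundred-vertex scale differential-event graphs have.

Modules are named M1, M2, ... by decreasing event count (ties by gene
count, then smallest member event id), and each gets a splice-class
census and gene count. There is no minimum module size by default
(real analyses report modules with as few as 11 events), but
`min_module_size` exists.

## Module scoring

For sample s and module M, score(s) = aggregate over events e ∈ M of
(PSI_{e,s} − ref_e), where ref_e summarizes the normal samples. The
deviations are *signed* — directional "+"/"−" calls in the pan-cancer
summary need the sign — and the aggregate is the mean by default with
a median variant; the reference defaults pair mean-of-normals with the
average score and median-of-normals with the median score. Average and
median scores correlate above 0.9 on synthetic cohorts, so the choice
is not load-bearing. Scores of normal samples are computable (used in
cross-type comparisons) but excluded from survival testing.

## Survival association

Tumor samples are split at the median module score — at-median samples
go to the low group, a convention that matters with tied scores — and
the two groups are compared per endpoint (overall survival; progression-
free interval) with the Kaplan–Meier estimator and the log-rank test.
Hazard ratios with Wald 95% intervals come from a Cox model on the
binary high/low indicator so that the HR matches the KM comparison;
a continuous-covariate mode exists for calibration work. Ties use
Breslow's method by default (Efron optional). Complete separation is
reported as a capped monotone fit with a warning rather than an error.

Retention mirrors the standard accounting: a module is kept when its
log-rank P ≤ 0.05 for either endpoint ("OS", "PFI", or "both" reason
codes), plus an optional near-significant window 0.05 < OS P < 0.1
("near_OS"). Applied to the bundled TCGA reference table this yields
10 OS-significant, 8 PFI-significant, 5 in both, 13 in either, and 15
retained modules. No multiple-testing correction is applied across
modules at this stage, matching standard practice for a handful of
candidate modules per cancer type.

## Enrichment and pan-cancer summaries

Gene-set enrichment is a one-sided hypergeometric upper-tail test
(equivalently Fisher's exact over-representation test) of module
*genes* against the background of all quantified spliced genes — a
gene with several module events counts once, since annotations attach
to genes. BH adjustment runs across terms. The background choice is
essential: nearly every transcribed gene splices, so enrichment
against a whole-genome background would be anticonservative.

Across cancer types, a module from type X is applied to type Y over
the event intersection, using Y's own normals as reference; cells with
no shared events are marked not evaluable rather than erroring. The
per-cell sign call is "+" ("−") when at least 80% of samples score
above (below) zero — "higher than normal" is score > 0 because scores
are already normal-subtracted — and a module is flagged *common* when
one nonzero sign recurs in at least 15 of 16 evaluated types,
rescaled as ceiling(15/16 · T) when T ≠ 16 types are evaluable.
Cancer types are clustered by average linkage on Euclidean distances
between their module mean-score profiles (missing cells mean-imputed
per module); linkage and distance are configuration, not dogma, since
nothing pins them down uniquely.

## The synthetic generator

`generate_cohort()` draws PSI as

clamp01( inv_logit( b_e + λ_e·z_{m(e),s} + δ_m·1[s tumor] ) + ε ),

with baseline logits b_e ~ N(0,1), factor loadings λ_e of magnitude
`loading_strength` (positive unless `negative_loading_prob` plants
anticorrelated switches), one latent factor z per module per sample,
Gaussian noise ε (sd `noise_sd`), and uniform missingness. The
logistic link keeps PSI bounded while letting effects act additively
on the logit scale; clamping after noise keeps the final marginal in
[0, 1]. Note that δ is a *logit-scale* shift: its PSI-scale effect is
δ·p(1−p) to first order, about 0.2–0.3 for mid-range events at the
default δ = 2. Survival times are exponential with hazard
h₀·exp(Σ_m β_m·score_m) based on the noiseless true scores, with
uniform-fraction censoring; the progression endpoint runs at twice the
baseline hazard (progressions precede deaths).

Default conditions — 2000 events, three modules of 60, 40 tumor and 12
normal samples, λ = 1.2, δ = 2, noise 0.05, 0.2% missing, β = 1, h₀ =
1/1000 per day, 30% censoring — were chosen once to emulate a
mid-sized TCGA cohort in the regime the thresholds target: within-
module |r| around 0.8, ΔPSI around 0.3, and near-complete recovery of
planted events by the differential stage. Survival calibration checks
run at 300 tumor samples with λ = 2 and δ = 1.2: a log-hazard
coefficient of 1 per unit score is a modest effect (observed score sd
≈ 0.25, so the induced high/low hazard ratio is ≈ 1.5, the magnitude
of the weaker published prognostic modules), and several hundred
subjects are what detecting it actually takes. Splice classes are
sampled from the empirical class mix of a large observed kidney-cancer
module (AA 41, AD 36, AT 229, ES 210, ME 3, RI 191 of 710 events) so
census outputs are nontrivial.

What the generator does *not* emulate — and hence what passing tests
do not show about real data: PSI missingness is uniform rather than
coverage-driven and event-clustered; events are independent given the
module factor (no gene-level correlation between events of one gene,
no splicing-factor regulons spanning modules); tumors are a single
population without subtypes, purity gradients, or batch structure; and
survival is exactly proportional-hazards exponential. Recovery of
planted modules at ARI ≈ 1 is therefore evidence the machinery is
correct, not that real cancer cohorts decompose this cleanly.

`generate_multitype()` gives every cancer type the same event
universe, plants designated shared modules on identical event blocks
with a common effect direction, and allocates each type's private
modules on globally disjoint blocks, so cross-type scoring, sign
calls, and the 15-of-16 commonality rule can be tested against known
truth.

## Problem sizes used by the checks

The bundled acceptance script and test-suite run at desk scale, chosen
so the full suite completes in a couple of minutes: eight to twenty
end-to-end recovery seeds at the 2000-event default; 100–200
simulations for the null calibration of the differential and log-rank
tests; 15–25 seeds at 300 tumors for survival detection; 30 Cox
recovery fits; a 16-type pan-cancer simulation at 700 events and 25
tumors per type. The published-table accounting, the two-triangle
walktrap optimum (Q = 5/14, verified against exhaustive enumeration of
all 203 partitions of six vertices), and the small-sample oracles
(exact Wilcoxon P = 0.1; BH q = 0.04; log-rank χ² ≈ 2.88; Cox HR ≈
2.56; Pearson r = 0.5) are deterministic.

## Known limitations

* The walktrap implementation recomputes candidate merges densely; it
  is comfortable to a few thousand vertices but is not an
  approximate-walk engine for very large graphs.
* No covariate-adjusted or multivariable survival models; no
  multiple-testing correction across modules at the retention stage.
* Enrichment consumes pre-flattened GMT files; no ontology-graph
  propagation or term-similarity reduction.
* Whether the original pan-cancer clustering used mean scores, sign
  profiles, or another summary is not determinable; mean scores were
  chosen and exposed.
* The paired signed-rank mode exists, but with unpaired cohorts the
  rank-sum default is the statistically valid reading.
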