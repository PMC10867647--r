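---
title: "Methods: time-resolved metabolomics with chronomet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved metabolomics with chronomet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronomet)
```

chronomet analyzes longitudinal untargeted LC-MS metabolomics studies in
which subjects from several treatment arms are sampled repeatedly over a
fixed day grid (by default days 0, 14, 28, 63 and 91, e.g. before,
during and after an intervention; three arms C, A and AE with 15
subjects each; positive and negative ionization analyzed separately).
This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic-study validation does and does
not demonstrate.

## Preprocessing

The pipeline starts from a quantified feature table (one row per LC-MS
feature with a metabolite annotation and an MS2 identification score,
one column per sample). Three steps:

* **MS2 filter.** Features with `ms2_score > 0.5` (strict) are retained;
  features with a missing score are treated as unidentified and dropped,
  because the filter is defined on the score. The threshold is
  `preprocess$ms2_threshold`.
* **Collapse.** When several features map to one metabolite name, the
  metabolite's per-sample value is the elementwise maximum over those
  features ("the highest value", read literally per sample), ignoring
  missing cells; a cell missing in every feature stays missing. This
  reading is deterministic; the alternative of keeping the single
  feature with the highest mean intensity is available as
  `preprocess$collapse = "best_feature"`.
* **QC report.** Instrument stability is summarized per metabolite as
  the coefficient of variation (sample standard deviation over mean,
  the usual n−1 convention) across the pooled QC injections, plus a PCA
  of all samples on log2 intensities (metabolites centered; metabolites
  with any missing value excluded). The CV is reported as evidence, not
  used as a filter, unless `preprocess$max_qc_cv` is set.

Intensities are strictly positive where present; missing cells are
explicit (empty fields on disk, never zeros), because all downstream
models work on the log2 scale. Samples missing entirely (e.g. animals
lost late in a long study, typically at day 63) are simply absent from
the table; every stage tolerates the resulting imbalance.

## Paired differential screening

For each arm, day 63 is compared against day 0 using only subjects with
both days observed for the metabolite at hand. The per-metabolite
statistic is the mean over subjects of the per-subject log2 ratio
$\log_2(x_{63}/x_{0})$ — robust to between-subject intensity scale —
and the p-value is a two-sided paired t-test on those log2 differences
(Wilcoxon signed-rank via `differential$test = "wilcoxon"`). A
metabolite with fewer than 3 complete pairs, or zero-variance
differences, is flagged with a missing p-value and excluded from
classification. The two-stage volcano screen is `p < 0.05` (strict) for
"changed", intersected with `|log2FC| > 1` (strict, i.e. beyond
2-fold) for "strong". No multiple-testing correction is applied to the
screen itself, mirroring common practice for this design; BH-adjusted
q-values are emitted as an extra column for transparency. Exclusive
Venn regions of the changed sets across arms are computed exactly.

## Soft clustering of temporal profiles

Within each arm, each metabolite's trajectory is summarized by the
median intensity over that arm's samples at each day. Profiles are kept
on the log2 scale (the log2 of the median equals the median of the
log2 values, so the choice of order is immaterial) and each row is then
z-scored across timepoints; zero-variance rows cannot be standardized
and are removed and recorded.

Clustering is fuzzy c-means: minimize
$J = \sum_i \sum_k u_{ik}^m \lVert x_i - v_k \rVert^2$ by alternating
the membership update
$u_{ik} = \left[\sum_j (d_{ik}/d_{ij})^{2/(m-1)}\right]^{-1}$ and the
centroid update $v_k = \sum_i u_{ik}^m x_i / \sum_i u_{ik}^m$, with
Euclidean distance on the standardized rows. A point coincident with
one or more centroids splits its membership equally among the
zero-distance centroids. Iteration stops when the largest absolute
membership change falls below `cluster$tol` (default 1e-6) or after
`cluster$max_iter` iterations; the objective trace is recorded and is
non-increasing by construction of the updates.

**Initialization.** Initial centroids are `c` distinct profile rows
drawn by the seeded RNG with D²-weighting: after a uniform first draw,
each further row is drawn with probability proportional to its squared
distance from the rows already chosen. Uniform draws frequently start
two centroids inside one cluster and converge to local optima with
near-duplicate centroids, which corrupts the minimum-centroid-distance
curve below; D²-weighted seeding removes almost all of these failures
while keeping runs fully reproducible from the seed.

**Fuzzifier.** The fuzzifier is `m = 2` by default, a reproducible
convention. Setting `cluster$m = "estimate"` applies the
dimension/size heuristic of Schwämmle and Jensen (2010),
$m = 1 + (1418/N + 22.05)D^{-2} + (12.33/N + 0.243)D^{-0.0406\ln N - 0.1134}$.

**Choosing the number of clusters.** For each candidate `c` the
minimum pairwise Euclidean distance between centroids (Dmin) is
computed as the median over `cluster$repeats` (default 3) seeded runs.
The original procedure picks the cluster number from this curve by
eye; chronomet automates it. The relative drop at `c` is
$r(c) = (D_{\min}(c) - D_{\min}(c+1))/D_{\min}(c)$, and a drop
qualifies as *the* elbow only when `r(c) >= cluster$delta` (default
0.2) **and** it lands in the curve's floor,
$D_{\min}(c+1) \le 2\min_c D_{\min}(c)$ — the regime where the extra
centroid is a near-duplicate of an existing one, the signature of
exceeding the true cluster number. The selected `c` is the smallest
qualifying drop. The floor condition matters: small relative drops
persist indefinitely inside the duplicate-centroid regime, so a rule
keyed on relative drops alone systematically overshoots on curves with
a clear cliff. A curve with no qualifying drop returns the smallest
candidate with a warning, and `cluster$force_c` always wins, preserving
the option of manual choice.

**Core sets and exports.** Each metabolite is assigned to its
argmax-membership cluster (exact ties to the lowest cluster index) and
is a *core* member iff that membership strictly exceeds
`cluster$membership_threshold` (default 0.7). The heatmap export orders
core metabolites by cluster and descending membership over the
standardized profiles.

## Temporal patterns and cross-arm comparison

Cluster centroids are mapped to a small library of standardized
canonical shapes on the study's day grid: rise-then-fall (peak at
`patterns$peak_day`, default day 28), its negative fall-then-rise,
monotone up, monotone down, and late rise (flat through the
intervention, rising in recovery). Assignment is by Pearson correlation
against each template — invariant to the affine scale of the centroid —
with exact ties to the lowest pattern id; a zero-variance centroid is an
error. The cross-arm report intersects two arms' core sets and flags,
per shared metabolite, whether the assigned pattern differs, alongside
both membership scores and their difference (the pattern can persist
while the membership changes, and both are of interest).

## Mixed-model trend classification

Per metabolite and arm, three nested linear mixed models are fitted to
the log2 intensities by maximum likelihood (lme4), with a random
intercept per subject to absorb between-individual level differences:
M0 intercept only; M1 adds scaled time $t = \mathrm{day}/\max(\mathrm{day})$,
centered; M2 adds $t^2$. Scaling and centering keep the quadratic term
numerically well conditioned. ML (not REML) estimation makes the
likelihood-ratio tests between fixed-effect nestings valid:
$p_{\mathrm{lin}}$ compares M1 vs M0 and $p_{\mathrm{quad}}$ M2 vs M1,
both against $\chi^2_1$. Missing samples leave the likelihood
unbalanced but well defined.

The four-way trend label is a two-stage gate: a significant quadratic
term wins (`model2_up`/`model2_down` by the sign of the quadratic
coefficient — up means convex, a late rise; down concave, a mid-course
peak); otherwise a significant linear term gives
`model1_up`/`model1_down` by the sign of the slope; otherwise `none`.
"Order of the variable" is thus read as polynomial order 1 vs 2 with
the quadratic tested on top of the linear term — the simplest nested
reading; AIC-based order selection is available
(`lmm$select = "aic"`), as is defining the model2 direction by the
fitted end-minus-start difference
(`lmm$model2_direction = "end_minus_start"`). Singular random-effect
fits (common under the null, where the subject variance estimates to
zero) are retained; only optimizer failures are flagged non-converged
and excluded.

**Concordance selection** keeps metabolites whose trend *direction*
agrees between the control and treated-plus-intervention arms (C and
AE, not `none`) and is opposite in the untreated arm A. Comparing
directions rather than full four-way labels is deliberate — a
`model1_up` in C and a `model2_up` in AE express the same biology at
different curvature — but strict label matching is available
(`lmm$concordance = "class"`).

Which single p-value the original "P < 0.05" screen refers to (linear,
quadratic, or an omnibus test) is not derivable from the method's
description; the two-stage LRT gate above is this package's documented
choice and all tests validate that choice.

## Enrichment

Over-representation of a selected set against a user-supplied pathway
annotation is the one-sided hypergeometric upper tail
$P[X \ge k]$ with $X \sim \mathrm{Hypergeom}(N, K, n)$, BH-adjusted
across the reported pathways but ranked by raw p. The background
(universe) is every metabolite surviving preprocessing — not all
annotated compounds — so the test asks about enrichment *within the
measured panel*. Pathways overlapping the selection by fewer than
`enrich$min_k` members are omitted before correction. A packaged toy
annotation (12 pathway themes dealt over the synthetic metabolite
names, with overlaps) makes the stage runnable without any external
service; real analyses should supply their own annotation table.
Compound-class composition is a simple tally with metabolites missing
from the class map reported as `unclassified`.

## The synthetic-study generator

Because the pipeline's statistical behavior cannot be validated on data
that are not redistributable, the generator emits complete studies with
known ground truth, emulating the target design: 3 arms × 15 subjects
× 5 days, two ionization modes, pooled QC injections, duplicated
features per metabolite with MS2 scores straddling the 0.5 filter (the
first feature always passes, so the filter is exercised without losing
metabolites), and a configurable fraction (default 10%) of day-63
samples deleted outright to reproduce late-study attrition.

The log2 intensity of metabolite $i$ in subject $s$ at day $d$ is
$b_i + \beta \cdot \mathrm{shape}_i(d) + u_{is} + \varepsilon$, with
baseline $b_i \sim N(15, 2^2)$ (arbitrary log2 abundance units),
standardized trajectory amplitude $\beta$ (`effect_size`, default 1.0
on the log2 scale), subject intercepts $u_{is} \sim N(0, 0.3^2)$ and
residual noise $\varepsilon \sim N(0, 0.3^2)$; intensities are
$2^{\mathrm{log2}}$, hence lognormal. Shapes come from the same
template library the pattern module uses (one source of truth):
`default5` for clustering studies, `trend4` (linear/quadratic up/down)
for trend-classification studies, a planted concordant set trending
up (or down) in C and AE and oppositely in A, plus null metabolites
with no time effect. A configured fraction of archetype metabolites is
re-assigned a different archetype in arm A (default 10%) so the
cross-arm pattern-change accounting has true positives. Defaults were
chosen once as a realistic mid-ground for serum LC-MS data (QC CV a
few percent; within-subject noise comparable to the subject effect;
effect sizes of one z-unit) and are not adjusted per analysis.

What the generator does *not* emulate: chromatographic drift, batch
effects, ion suppression, correlated metabolite panels, heavy-tailed
or missing-not-at-random intensities, or annotation errors. Passing
the validation suite therefore demonstrates correctness of the
algorithms under the stated statistical model, not robustness to every
artifact of real LC-MS data.

## Validation suite and problem sizes

The test suite and `scripts/acceptance.R` recompute, from scratch at a
chosen seed: exact agreement (1e-8) of the fuzzy c-means memberships
and objective with an independently coded naive reference from shared
initializations (25 random 20×5 instances); membership normalization
and objective monotonicity over 200 fuzzed instances; recovery of 5
planted archetypes × 40 metabolites over 10 seeds (selected cluster
number in [4,6], median adjusted Rand index vs truth ≥ 0.8); exactness
of the paired log2 fold change under doubling and a type-I fraction in
[0.03, 0.07] for 500 null metabolites × 10 subjects; ≥ 90% four-way
label accuracy on 200 planted trend metabolites and the LMM null
type-I in the same band (the χ²(1) LRT is mildly anticonservative at
this sample size, so the null fraction sits near the upper half of the
band); sensitivity ≥ 0.9 with ≤ 10% false selections for 30 planted
concordant metabolites among 300 nulls; hypergeometric tails equal to
exhaustive enumeration (1e-12) and BH q-values equal to a hand
step-up; and a byte-identical rerun of the full pipeline on the
default synthetic study. These sizes keep the whole suite at a few
minutes on a single core while leaving each statistical check with
enough replicates to be meaningful.

## Known limitations

* The cluster-number rule automates a judgment call; on curves without
  a clear duplicate-centroid floor it falls back conservatively and
  should be overridden via `cluster$force_c` when domain knowledge
  dictates.
* The LMM screen tests only polynomial (order ≤ 2) time trends; shapes
  like rise-then-return are captured by the quadratic term only
  insofar as they are symmetric. No random slopes are fitted.
* The paired screen and the trend screen use raw p-values by design;
  with hundreds of metabolites, some selections are false positives,
  and the emitted q-values should accompany any reported list.
* Enrichment results are only as good as the supplied annotation; the
  packaged toy annotation exists for testing and demonstration, not
  inference.
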