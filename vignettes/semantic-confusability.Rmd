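---
title: "Conceptual structure, perirhinal damage, and semantic confusability: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conceptual structure, perirhinal damage, and semantic confusability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semconf)
```

## The scientific problem

Feature-based accounts of conceptual knowledge represent a concept as a
bundle of semantic features with production frequencies taken from
property-norming studies. Concepts whose features are widely shared within
their category (typically living things: *has eyes*, *has legs*, *breathes*)
are mutually confusable, and differentiating them is hypothesised to depend
on the perirhinal cortex (PRc) at the apex of the ventral visual stream.
This package implements the statistics needed to test that hypothesis in a
lesion cohort: conceptual-structure measures from property norms, cosine
semantic distance, per-region damage quantification from binary lesion
masks, the behavioural test battery, and rank-based damage–behaviour
correlation tables.

## Conceptual structure statistics

From a concept-by-feature production-frequency matrix `pf`:

* **Distinctiveness** of a feature is `1 / n_concepts`, the reciprocal of
  the number of concepts listing it, so it lies in (0, 1] and a feature
  unique to one concept is maximally distinctive. The reciprocal form is the
  standard convention of the conceptual-structure literature; it is exposed
  as a pluggable function (`distinctiveness_fun`) should a squashed variant
  be preferred.
* A feature is **shared** when it occurs in at least `min_shared` concepts
  (default 3).
* **Correlational strength** of a feature is the mean of its *retained*
  pairwise Pearson correlations with other shared features, computed across
  all concepts' production-frequency columns. A correlation is retained when
  its two-tailed p-value is below `alpha` (default 0.05) and, by default,
  positive (`positive_only`). The originating literature specifies
  "significant pairwise correlations" without fixing the level or the sign
  convention; both are therefore explicit arguments, and widening `alpha`
  can only enlarge the retained set (a property the tests check).
* Concept-level **mean distinctiveness** averages feature distinctiveness
  over the concept's attested features; concept-level **correlational
  strength** averages the retained correlations among pairs of the
  concept's own shared features (not norm-wide partners), which matches the
  verbal definition "pairwise correlations between the shared features of a
  concept". Feature-level strength, in contrast, uses norm-wide partners.
* The **correlation-by-distinctiveness slope** is the unstandardised OLS
  slope of feature-level correlational strength on feature distinctiveness
  over the concept's features. Features with undefined strength enter with
  strength 0 by default (`undefined_strength_as_zero`): the measure is
  designed to contrast strongly intercorrelated shared features against
  weakly correlated distinctive ones, so treating "no retained partner" as
  zero strength is the substantive reading; a flag excludes them instead.
  Low slopes typify confusable concepts (animals), high slopes concepts
  with correlated distinctive features (tools).

Undefined statistics propagate as `NA`, never silently as zero (the slope
flag above is the single documented exception). The slope is `NA` when
fewer than two usable features remain or the predictor has no variance.
No feature-type filtering (e.g. taxonomic features) is applied: the
originating norms' precise preprocessing is not recoverable, so the neutral
default is to use every feature and leave filtering to the caller.

Cosine similarity between two concepts is the cosine of the angle between
their production-frequency vectors over the full feature space — in [0, 1]
for non-negative counts, 1 exactly for proportional vectors. It underlies
the close/distant manipulation of the word–picture matching task.

## Lesion quantification

Warped lesion masks carry interpolated values in [0, 1]; `binarize_mask`
restores a 0/1 mask with a *strict* `> 0.5` comparison (the boundary value
maps to intact; the source protocol states only "a threshold of 0.5", so
the tie rule had to be fixed and is documented and tested).

`build_max_prob_atlas` combines per-rater binary drawings into per-ROI
probability maps (fraction of raters marking each voxel, so values lie on
the `1/n_raters` grid) and assigns each voxel to the ROI with the highest
positive probability; exact ties are left undefined (code 0 by default — a
nonzero `tie_code` is registered in the legend as `undefined`). No
smoothing is applied to the drawings. `truncate_posterior` cuts listed ROIs
back to the anterior–posterior extent of a reference ROI; since grids here
carry no affine, each volume records which array axis runs
posterior-to-anterior (`anterior_axis`, default axis 2 with the index
increasing anteriorly), and the truncation consults it.

Damage to an ROI is the mean lesion value over the ROI's voxels — the
proportion damaged for a binary mask. Empty ROIs are reported `NA`, never
0. Grids must match exactly; resampling belongs to the upstream warping
step and is out of scope. Hemisphere-prefixed ROI names (`L_`/`R_`) are
pooled by stripped name by default, matching a cohort that pools left- and
right-lesion patients; `merge_hemispheres = FALSE` keeps them separate.
White matter is not modelled: damage confined to white matter is invisible
to these grey-matter ROIs, a known limitation of the ROI approach.

## Behavioural statistics

Naming responses are scored correct when the case-folded, trimmed response
equals the canonical name or a synonym; missing responses score 0 and are
counted. Accuracy summaries compute participant means per cell first, then
the cell mean and *between-participant* SEM, the unit of the group-level
analyses (the printed control SEMs cannot be checked against
per-participant data, so participants are assumed throughout).
Internally everything is an unrounded proportion; percentages are rounded
only for display.

The mixed ANOVA is the classical balanced-design univariate decomposition,
fitted with `stats::aov` and an `Error(participant/within)` stratum. The
design is validated (every participant in every within cell, at least two
participants per group); with a single-level within factor it reduces to
the one-way ANOVA on participant means (tested equivalence). Uncorrected
degrees of freedom are the default, matching the source analyses; a
Greenhouse–Geisser option exists for within factors with more than two
levels. When an error stratum's residual mean square is numerically zero
(below `1e-20` of the response scale — accumulated floating-point noise),
the affected F ratios are meaningless and are reported as 0 with a
`degenerate` flag rather than as spurious large values.

t tests wrap `stats::t.test` (pooled, Welch, paired) into a uniform result
record; one-tailed tests halve the two-tailed p in the hypothesised
direction and flag effects opposite to it. Two zero-variance samples with
equal means return t = 0, p = 1, flagged, instead of erroring. The
item-wise ANCOVA fits `accuracy ~ group * covariate` with items as
observations — the error stratum that matches the printed degrees of
freedom's order of magnitude — and reports the interaction F with the
model's own residual df (the exact composition behind the original df is
not derivable and is not forced). Per-participant effect scores are
item-wise point-biserial correlations Fisher-transformed to `z = atanh(r)`;
numerically perfect correlations give infinite z and are flagged for
exclusion from downstream damage correlations.

## Damage–effect mapping

Spearman's rho is the Pearson correlation of mid-ranks. The p-value uses
the t approximation with `n − 2` df; for the cohort sizes involved
(n = 6–8) an `exact = TRUE` flag enumerates the full permutation null
instead. The t approximation's exact one-tailed size at n = 8 and
alpha = 0.05 is 4.81% (established by full 8! enumeration), so it is kept
as the default. The partial Spearman rank-transforms all three vectors and
applies the first-order partial-correlation formula on ranks with
`n − 3` df — the convention consistent with the source's reported df.
Correlation tables are uncorrected for multiple comparisons by default (as
in the source); per-effect one-tailed directions are declared in
configuration (negative for damage–accuracy, positive for damage–slope
effects). ROIs with fewer than three patients with nonzero damage are
excluded as uninformative (the entorhinal exclusion rule).

## The synthetic generators

`gen_property_norms` emulates the one structural asymmetry the analyses
depend on: living concepts draw more features from a common shared pool
(target mean 12.7) than nonliving concepts (11.1), values taken from the
word–picture stimulus analysis; each concept adds
`distinctive_per_concept = 5` unique features, a figure in the typical
range of property-norm sets. Per-concept shared counts are
`round(Normal(mean, sd = 2))`, so a 30 + 30 draw lands within ±1 of the
targets with high probability. Production frequencies are truncated
geometric on 1..30 (feature-listing counts are small positive integers;
the exact distribution is not critical and is configurable). The realised
counts are returned as ground truth and equal what the pipeline measures
(exact round trip, tested).

`gen_lesion_cohort` lays six ROIs out as disjoint boxes on a
24 × 30 × 12 grid of 2 mm voxels and fills each ROI in raster order to the
target damage fraction, so realised fractions are exact at voxel
resolution; the default 8-patient design grades PRc damage 0–0.7 in steps
of 0.1 and gives only two patients entorhinal damage (exercising the
exclusion rule). A stochastic placement mode exists for robustness checks.

`gen_behaviour` draws per-trial Bernoulli responses with
`logit p = b0 + b_dmg·d + b_int·d·s + e`, `d` the patient's PRc damage,
`s` the item's standardised correlation-by-distinctiveness slope computed
through the package's own pipeline, and `e` Gaussian logit noise
(`noise_sd = 0.5`). Defaults `b0 = 2` (≈88% baseline accuracy, the healthy
range for familiar objects) and `b_dmg = −2` give damaged patients the
observed 10–20-point deficit. There are no participant random intercepts
by default — noise is Bernoulli plus logit jitter only.

What the generators do *not* emulate: realistic lesion morphology,
category-specific feature statistics beyond the shared-count asymmetry,
response-time structure, rater disagreement patterns, or the correlated
feature structure of real norms (the shared pool induces correlations
incidentally, not by design). Passing tests therefore demonstrate that the
statistics are computed correctly and that the pipeline recovers known
ground truth under its stated model — not that the model captures real
patient data.

## Calibration and problem sizes

Two simulation studies validate the pipeline end to end, at sizes chosen to
give stable rates while keeping the suite quick to run:

* **Type-I calibration**: 400 cohorts under `b_dmg = b_int = 0` (one norms
  and lesion draw, fresh behavioural noise each run; under the null the
  damage–effect association is exchangeable conditional on the covariates,
  so fixing the draw only removes simulation variance). The one-tailed
  damage-by-slope-effect Spearman at alpha = 0.05 should reject in
  5% ± 2.5%.
* **Power**: 200 full-pipeline runs (fresh norms each run, 200 concepts,
  200 items, 8 patients, `b_int = 3`) in which damage is measured from the
  masks and atlas, not read from ground truth; a significant positive PRc
  correlation should appear in at least 90% of runs.

A third check permutes group labels 500 times in a balanced 3 × 8 mixed
design with Gaussian data and verifies the group-effect p-values are
uniform (Kolmogorov–Smirnov).

## Known limitations

* The fixture tables are integer-rounded; statistics recomputed from them
  can differ from values computed on the original unrounded data by up to
  ~0.15 in t and one integer step in a group mean. The tests document the
  achievable precision case by case.
* Statistics that require the real property norms or patient images
  (stimulus-set cosine means, the real ROI-damage correlation tables) are
  out of reach by construction; they are covered by the property-based and
  oracle suites instead, and nothing in the package fabricates them.
* Exact string matching for concept and feature labels; no lemmatisation
  or synonym resolution inside the norms.
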