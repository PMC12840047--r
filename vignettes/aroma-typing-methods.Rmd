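---
title: "Methods: aroma typing and flavor metabolomics of rice"
author: "ricearoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aroma typing and flavor metabolomics of rice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricearoma)
```

This vignette is the package's own account of the models and procedures
it implements, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the design choices made where
the design was genuinely open.

## The study design

The packaged tables describe 11 commercial raw rice samples measured in
technical triplicate and grouped into three aroma types — A (sweet,
popcorn-forward; 3 samples), B (cereal/starchy; 4) and C (complex; 4) —
by a 10-person QDA panel scoring ten attributes (starchy, grainy,
floral, popcorn, sweet, grassy, woody, oatmeal, dairy, corn) on a 0–9
scale with 0.5 increments. `study_design()` encodes these sizes as its
defaults. The GC-MS table holds 74 identified volatiles with per-type
mean ± SD semi-quantified contents and literature odor thresholds; the
GC-IMS table holds 55 signals with per-type peak volumes.

## Sensory aggregation and aroma typing

`aggregate_qda()` validates that every score sits on the half-point grid
and averages over panelists; nothing else is done to the panel data (no
panelist-performance diagnostics — out of scope here). Ward clustering
(`ward_cluster()`) uses Euclidean distances and the `ward.D2` linkage,
i.e. the classical minimum-variance criterion. Attributes are **not**
standardized by default because all ten share the same 0–9 scale; a
`standardize` flag enables z-scoring for data on heterogeneous scales.

The cluster count comes from the within-cluster sum of squares curve
over nested tree cuts (`wcss_curve()`), which is non-increasing in k by
construction. The elbow is described only verbally in most applied work
("rapid decrease, then flat"); we operationalize it as the interior k
maximizing the second difference of the curve, with ties going to the
smallest k (`elbow_k()`). This is the simplest discrete-curvature
reading of the verbal rule and is exactly reproducible.

Greedy agglomerative Ward does not guarantee the globally
minimum-variance partition. The test suite compares it against an
exhaustive minimum-WCSS search on small problems: with well-separated
groups (center separation about six times the within-group spread —
the regime in which cluster analysis is actually informative, and far
milder than the archetype separations here) agreement is ≥95% of random
trials, and Ward's WCSS never undercuts the exhaustive optimum. On
completely unstructured noise the agreement rate drops to roughly 85%;
no claim is made there.

## The synthetic sensory generator

`simulate_sensory()` draws each panelist × sample × attribute score as
the group archetype mean plus Gaussian noise (default SD 0.5 score
units, a typical trained-panel spread on a 9-point scale), snapped to
the nearest 0.5 and clipped to [0, 9], exactly as a ballot would record
it. The archetype profiles live in
`inst/extdata/sensory_archetypes_synthetic.tsv` and are synthetic:
the source study's spider plots print no numbers, so the values are this
package's choice, made once. They encode A as sweet/popcorn-forward
without floral notes, B as starchy/grainy with clearly reduced sweet
and popcorn, and C as the balanced-high "complex" profile carrying
floral/corn notes the other types lack. That last point matters
geometrically: the three profiles must span distinct directions in
attribute space rather than sit on one axis, because a type lying midway
between the other two makes the k = 1→2 WCSS drop about twice the 2→3
drop and the elbow lands at 2 — whereas the reported WCSS geometry
(sharp drop to three clusters, then flat) requires roughly comparable
pairwise separations. The packaged profiles reproduce that geometry.

What the generator does *not* emulate: panelist-specific biases and
scale-use effects, attribute correlations beyond those induced by the
archetype means, sample-to-sample heterogeneity within a type, and any
non-Gaussian score behavior. Passing tests therefore demonstrate that
the clustering chain recovers a known three-type structure under honest
panel noise — not that three types exist in any particular real
dataset.

## Concentrations, retention indices, quantification

`simulate_concentrations()` draws replicate-level contents from a
normal with the tabulated group mean and SD, truncated at zero
(contents cannot be negative; a truncated normal matches the mean ± SD
reporting convention better than a lognormal for these single-decade
values), then averages the replicates into a sample value. Compounds
recorded as not detected stay exactly zero. Published tables do not
separate between-sample from replicate variance, so both enter as scale
factors (`replicate_sd_frac`, `between_sample_sd_frac`); the default
puts all tabulated SD at replicate level, which after averaging three
replicates makes sample-level spread conservative by a factor of √3 —
screens on synthetic data are correspondingly more sensitive than the
source screens, and counts of "significant" compounds should be read
with that in mind. GC-IMS volumes span several decades, so
`simulate_ims_volumes()` uses a lognormal with the tabulated value as
median and a user CV instead.

`retention_index()` implements the linear temperature-programmed
(van den Dool–Kratz) form, not logarithmic Kovats, since both the GC-MS
and GC-IMS runs are programmed; at a ladder rung the index is exactly
100 × carbon number. Matching against library values uses the strict
`|ΔRI| < 50` rule — a difference of exactly 50 fails. No extrapolation
outside the ladder span happens by default (`extrapolate = TRUE` allows
it with a warning, since published libraries sometimes cite wider
ladders than the one run). When several library entries fall inside the
tolerance, the closest wins and exact ties resolve alphabetically — an
arbitrary but deterministic rule. `semi_quantify()` is the standard
internal-standard ratio; the packaged tables label the same values µg/L
in one place and µg/kg in another, so the package stores one
IS-equivalent unit ("µg per kg of sample") and treats it as relative
throughout.

## ROAV

`compute_roav()` uses the max-normalized form
ROAV\_i = 100 (C\_i/OT\_i) / max\_j (C\_j/OT\_j). Contents are
IS-equivalent µg/kg while thresholds are µg/L in water; the ratio is
treated as a unitless activity, the universal practice in ROAV
screening (absolute odor-activity values would need matrix-specific
thresholds). Compounds with a missing threshold ("n.f.") or no detected
content are *excluded*, not scored zero — reports can then distinguish
"not scorable" from "weak". Ties for the maximum name the
alphabetically first compound as reference; scores are unaffected. The
boundaries ROAV ≥ 1 (principal) and 0.1 ≤ ROAV < 1 (modifier) are both
inclusive at the lower edge.

## Differential screening

`anova_oneway()` is the classical pooled one-way ANOVA;
`anova_from_summary()` rebuilds the identical F and p from per-group
means, SDs and sizes, which matters because published tables often
print only summaries. The identity of the two routes is property-tested
on random data. Degenerate inputs collapse to limits rather than NaN:
all-equal data give F = 0, p = 1; zero within-group variance with
unequal means gives F = ∞, p = 0 with a `degenerate` flag. Of note, the
packaged differential table's printed ANOVA p-values are *not*
recoverable from its own mean ± SD summaries under any plausible group
size (e.g. 6-undecanone's summaries give F ≈ 2.30, p ≈ 0.16 against a
printed p = 0.022); the raw per-sample data behind them were never
published, so the package verifies its ANOVA against oracles and
properties instead of against those printed values.

Pairwise screens use the pooled-variance Student t (not Welch,
following the source methodology) and require VIP > 1 from an OPLS-DA
model of the two groups; both thresholds are strict. Fold changes use
ε = half the smallest nonzero content of the matrix so that
fold changes over non-detected groups stay finite; two zero means give
0. No multiple-testing correction is applied in the primary screen (the
screens operate at raw p < 0.05; externally supplied Q-values are
passed through, never recomputed).

## OPLS-DA and VIP

`fit_oplsda()` implements orthogonal signal correction for a single
binary response: the predictive weight is w ∝ X'y; each orthogonal
component deflects the current loading against w, normalizes it, and
deflates X by the resulting score/loading pair; the final predictive
component is fit on the filtered matrix. With `n_ortho = 0` the model
is exactly 1-component PLS-DA, which the tests verify against an
independent NIPALS implementation. Orthogonal scores are uncorrelated
with the class by construction (the tests assert |cor| < 1e-8), and
orthogonal filtering can only raise the training predictive-score/class
correlation.

Variables are autoscaled to unit variance before OPLS-DA and PCA — the
metabolomics default, since volatile contents span orders of magnitude;
`scaling = "center"` switches it off. Constant variables cannot be
autoscaled and are an error naming the variable (in the pipeline's
pairwise screens, compounds that are constant across both groups —
e.g. ND in both — are assigned VIP 0 instead, since they carry no class
information). VIP uses the predictive-component-only convention
(VIP_pred): for the single predictive component VIP\_j = √p·|w\_j|, so
mean(VIP²) = 1 holds identically and VIP > 1 flags above-average
contributors. Model validation by permutation or cross-validated R²/Q²
is deliberately out of scope.

## GC-IMS fingerprints

Signals, not compounds, are the unit of analysis: a monomer and a dimer
row of the same analyte count separately, which is the only convention
under which the packaged table's class counts (14 ketones, 13 alcohols,
12 esters, 8 aldehydes, 4 heterocyclic, 3 aromatic hydrocarbons,
1 other) sum to its 55 rows. The peak table carries no class column, so
classes come from a curated name → class map shipped with the package
(acetophenone is counted among the ketones; limonene, α-pinene and
styrene as aromatic hydrocarbons; acetic acid as the single "other").
`build_fingerprint()` orders columns by retention time then drift time,
making the layout stable under input shuffling, and
`difference_matrix()` subtracts a reference group's row — the signed
analogue of the red/white/blue difference plots produced by instrument
software. Raw drift spectra, 2D/3D topographic plots and drift-time
calibration are out of scope; the analysis starts where the vendor
export ends.

## Numerical and reporting choices

- Category percentages are truncated toward zero at one decimal, not
  rounded: 15/74 = 20.27% must print as 20.2 and 5/74 = 6.76% as 6.7 to
  match the source figures, which only truncation achieves.
- The flavor-characterized count uses the plain non-empty-descriptor
  rule. On the packaged table 22 of 74 compounds have an empty
  descriptor field, so the rule yields exactly the published 52
  (70.27%); an exclusion-list argument exists for stricter readings
  (e.g. discounting bare class labels like "Alkane") but defaults to
  empty.
- Sentinels are preserved end to end: "ND" is an exact zero measurement
  with a `detected = FALSE` flag (downstream statistics treat it as
  zero, which is how ANOVA over groups containing ND is computed);
  "n.f." is a missing threshold. The packaged tables are kept verbatim,
  including their internal inconsistencies (one compound printed ND in
  one table but with a positive content in another; one dimer/monomer
  pair printing identical volumes in one group). These are documented,
  not resolved.
- One top-level seed fans out to fixed per-stream child seeds
  (concentrations / sensory / peaks / IMS), so stages can be
  regenerated independently and full runs are byte-reproducible.

## Problem sizes

The shipped analyses and tests run at the study's own scale — 11
samples, 74 compounds, 55 signals, 10 panelists — with 100-replicate
seed sweeps for the stochastic recovery properties and
1000-replicate sweeps for the exact algebraic identities; Monte-Carlo
checks of the generators use about 1000 samples. These sizes were
chosen as the smallest at which the stochastic assertions are stable
from seed to seed.

## Known limitations

- Identification models retention-index evidence only; mass-spectral
  similarity scoring is out of scope, so ambiguous co-eluters that a
  spectral match would separate are not separable here.
- ROAV inherits the threshold literature's water-matrix values;
  rankings are comparative, not absolute odor activities in rice.
- The differential screens on synthetic data are calibrated by the
  generator's variance convention (see above) and should not be read as
  re-estimates of the source study's hit counts.
- Ward + elbow is a heuristic pair; the elbow rule needs at least three
  consecutive k values and a genuine curvature maximum to be
  meaningful.
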