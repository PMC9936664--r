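---
title: "Methods and design decisions in ftmsflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design decisions in ftmsflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftmsflow)
```

## The problem

Direct-injection FT-ICR MS resolves a complex organic-matter sample into
thousands of exact masses, most of which receive a unique CHNOPS molecular
formula during upstream processing. Because compounds are not separated
chromatographically and identification of individual structures is not
possible, the analysis works at the level of the *formula assemblage*: what
elemental compositions are present, how reduced or aromatic they are, how
they differ between experimental groups, and which pairs of masses differ by
the exact mass of a known biochemical reaction. `ftmsflow` implements this
downstream workflow — filtering, annotation, normalization and its
selection, exploration, chemodiversity, multivariate statistics and
mass-difference transformation networks — on the report table produced by
formula-assignment software.

## Filtering

Four filters run in a fixed order, each with an audited removal count:
(1) a closed mass window (default 200–900 Da, where DI FT-ICR MS of natural
organic matter is typically informative), (2) removal of ¹³C-isotopologue
peaks (the monoisotopic peak carries the formula), (3) removal of
formula-bearing peaks whose absolute assignment error exceeds 0.5 ppm, and
(4) a minimum-presence rule (detected, i.e. intensity > 0, in at least
`presence_min` samples). All thresholds are inclusive: the original
criteria state magnitudes only, so the bound convention had to be fixed,
and inclusive bounds keep a peak sitting exactly at a published threshold.
Peaks whose error is not recorded, or which carry no formula at all, pass
the error filter — the quantity being filtered is undefined for them.
Formula-less peaks remain in the table and in diagnostics counts, but are
excluded from index computation, class assignment, exploration, diversity
traits and networks, where elemental composition is required.

## Indices

For every formula (with carbon present; neutral molecules, charge Z = 0):

* `NOSC = 4 − (4C + H − 3N − 2O + 5P − 2S)/C` — the mean oxidation state of
  carbon, from −4 (CH₄) to +4 (CO₂) for ordinary CHO compositions.
* `GFE = 60.3 − 28.5·NOSC` kJ (mol C)⁻¹ — the Gibbs free energy of the
  carbon oxidation half-reaction; an affine proxy for degradability (more
  oxidized carbon, lower GFE, more favorable oxidation).
* `DBE = 1 + (2C − H + N + P)/2` — rings plus π bonds.
* `AImod = (1 + C − O/2 − S − (N + P + H)/2) / (C − O/2 − N − S − P)` — the
  modified aromaticity index, counting only the carbon skeleton's possible
  C=C density after discounting carboxyl/carbonyl oxygen as ½O.

AImod is reported as 0 when its denominator is non-positive *or* when the
ratio is negative: a negative density of aromatic bonds is not meaningful,
and this clamping is the standard convention for the aromaticity index
family. It matters in practice — saturated, oxygen-rich formulas such as
glucose would otherwise get negative values.

## Compound classes

Classes are assigned from (O/C, H/C) alone, using the rectangular region
table in `compound_class_table()` (the boundary set in wide use for natural
organic matter van Krevelen analyses). Regions overlap at their borders, so
two conventions make the assignment deterministic: regions are checked in a
fixed order (lipid, protein, carbohydrate, unsaturated hydrocarbon, lignin,
tannin, condensed aromatic) and bounds are lower-inclusive,
upper-exclusive. Anything outside every region is `Other`; peaks without a
formula are `Unassigned`.

## Normalization and the zero convention

Six per-sample normalizations are supported (max, minmax, mean, median,
sum, z-score). A zero intensity means *not detected*, not "measured as
zero": zeros are therefore excluded from every column statistic and remain
exactly zero afterwards. The alternative — letting hundreds of absences
drag a sample's mean or minimum — would make the location-based methods
meaningless for sparse data. This is a deliberate design decision; whether
upstream tools treat zeros the same way is not documented, so results of
location-shifting methods (mean, median, z-score) on very sparse samples
should be interpreted with that in mind. Methods that divide by a range
fail loudly on constant columns rather than returning infinities.

## Choosing a normalization: the bias grid

`spans_grid()` scores each (peak subset × normalization method) pair for
group bias, in the spirit of the SPANS procedure for proteomics. Subsets
are taken on log₁₀ intensities: all peaks; the union of each sample's top-L
order statistics (L ∈ {0.05, 0.1, 0.2, 0.5}); and presence proportions
(≥ 50 %, 75 %, 100 % of samples). For each cell, the per-sample factors the
normalization would apply (its location statistic; also the scale statistic
for z-score) are computed from the subset and tested against the group
labels with a Kruskal–Wallis test (midranks, tie-corrected χ² p-value); the
score is the mean log₁₀ p over the method's factors. A score of 0 means the
factors carry no group signal (constant factors are scored p = 1, the
no-bias limit); large negative scores mean normalizing would remove or
fabricate group differences. `recommend_method()` returns the method of the
best cell, breaking ties in the canonical method order. This scoring is a
reimplementation designed around the same bias evidence — it is monotone in
the Kruskal–Wallis association and heatmap-comparable — not a port of any
existing SPANS code, whose exact internal score is not publicly specified.

## Chemodiversity

Diversity always works on **raw** intensities, sum-normalized per sample to
relative abundances p: normalized (especially signed) intensities are not
abundances. Shannon (−Σ p ln p, nats), Gini–Simpson (1 − Σ p²) and the
bias-corrected Chao1 estimator S + F₁(F₁−1)/(2(F₂+1)) are computed per
sample. Chao1 is defined for counts; intensities are converted to
pseudo-counts by dividing by the sample's smallest positive intensity and
rounding, so the faintest detected peak acts as a singleton. This is an
adaptation (the abundance-to-count convention for continuous intensity data
is not standardized) and Chao1 values should be read as relative, not
absolute, richness estimates.

Functional (trait-based) diversity is Rao's quadratic entropy
Q = Σᵢⱼ dᵢⱼ pᵢ pⱼ for three trait sets: elemental composition (C, H, O, N,
S, P counts), insaturation/aromaticity (DBE, AImod) and reactivity (GFE).
Distances are Gower dissimilarities with equal trait weights and per-trait
range scaling, so d ∈ [0, 1] and Q is comparable across trait sets; the
index itself does not prescribe a distance, and Gower is the conventional
choice for mixed-scale traits. Abundances are restricted to formula-bearing
peaks and renormalized.

## Multivariate statistics

Distances are computed between samples on the normalized matrix. The
distance must match the data's sign structure, so the default mapping is:
signed normalizations (z-score, mean, median) → Euclidean; non-negative
ones (max, minmax, sum, raw) → Bray–Curtis; Jaccard (presence/absence) by
explicit request only. PERMANOVA uses `vegan::adonis2` (Anderson's
pseudo-F on the partitioned squared distances) with sequential type-I sums
of squares; with two grouping variables the model is `g1 * g2` in the order
given, and the interaction is reported. p-values are
(1 + #{F\* ≥ F}) / (1 + n_perm) under free row permutation with a fixed
seed.

NMDS is implemented in-package: Kruskal stress-1 with primary monotone
(isotonic) regression of configuration distances on the dissimilarity
order, minimized by Guttman-transform updates with a backtracking
step-halving line search, so the recorded stress trace is non-increasing by
construction. Defaults: k = 2, 20 restarts (the first from the metric
principal-coordinates solution, the rest random), 300 iterations, stop when
the stress improvement falls below 1e-6. The best restart is returned,
centered and rotated to principal axes. `vegan::monoMDS` minimizes the same
criterion and serves as an independent cross-check in the test suite.

PCA summaries standardize their variables (z-score per column) before the
eigendecomposition and are computed twice: on per-sample compound-class
percentages, and on per-sample magnitude-averaged indices
Σ Iᵢ·indexᵢ / Σ Iᵢ over detected formula-bearing peaks (raw intensities).
Index distributions in the exploration step are deliberately *unweighted*
(one observation per detected peak per sample): the violin/Tukey view asks
"what kinds of formulas are present", the magnitude-averaged PCA asks "what
dominates the signal".

## Transformation networks

For each sample, all pairwise mass differences among detected
formula-bearing peaks are matched against a key of exact biochemical mass
differences; a pair matches entry δ when |Δm − δ| ≤ δ · tol · 10⁻⁶ with
tol = 1 ppm. The tolerance denominator is a genuine choice: 1 ppm *of the
key's mass difference* (the default) keeps the acceptance window
proportional to the quantity being matched; an alternative mode measures
the tolerance against the heavier peak's m/z, which is far more permissive
for small differences (1 ppm of 500 Da is 35× looser than 1 ppm of CH₂) and
is available behind a flag for comparability with tools that use it. A pair
matching several entries yields parallel edges by default (each named
transformation is a separate hypothesis); a best-match mode keeps only the
minimum-error entry. The matcher sorts masses once and sweeps a two-pointer
window per key entry; the test suite proves it identical to the full
O(n²K) enumeration.

The shipped key (28 entries: H₂, O, CH₂, NH₃, H₂O, CO, CO₂, sugar and
amino-acid residues, SO₃, HPO₃, …) has every mass computed from IUPAC
monoisotopic atomic masses and a curated biotic/abiotic label. It is
explicitly a general-purpose stand-in: transformation keys are
system-specific, and users are encouraged to supply their own CSV.
Networks are exported as per-sample edge CSVs and GraphML (nodes annotated
with mass, class and indices) with statistics (density 2E/(N(N−1)), mean
degree, components, per-key and per-category counts); rendering is left to
external graph tools.

## The synthetic-data generator

`generate_report()` emulates a Formularity-style report: random CHNOPS
formulas (C 4–40, H up to 2C+2+N+P with H/C between 0.4 and 2.2, O up to
min(C, 25), occasional N/S/P), exact monoisotopic masses, log-normal
intensities (baseline log₁₀ ≈ 6 ± 0.8, within-sample noise sd 0.4 — typical
orders of magnitude for DI FT-ICR MS peak heights), 10 % per-cell dropout,
5 % ¹³C rows, 5 % formula-less rows and 2 % rows with inflated assignment
errors to exercise every filter, optional per-group intensity fold changes,
and planted transformation ladders with exact masses and no dropout so the
expected network edges are known by construction. Mass jitter (≤ 0.2 ppm)
is off by default; at 1 ppm key tolerance, jitter of that size on a ~400 Da
mass would exceed the CH₂ acceptance window, and the planted truth is kept
exact. What the generator does **not** emulate: ion suppression,
intensity-dependent detection, isotope patterns, correlated chemical
families, or instrument drift — so passing tests demonstrate algorithmic
correctness on known ground truth, not robustness to every artifact of real
spectra.

## Numerical choices and degenerate inputs

Masses are handled as 64-bit doubles with no rounding before matching.
Constant normalization columns and empty samples raise errors naming the
sample; a sample with no detections is reported with zero diversity rather
than an error in the batch summary. Kruskal–Wallis on constant factors is
defined as p = 1. Tukey HSD is skipped (with a warning) for an index when a
group has fewer than two observations. PCA drops constant variables with a
warning; if every variable is constant the scores collapse to the origin.
NMDS breaks exact degeneracies of the metric start with 1e-8 jitter and
accepts only stress-reducing steps. Test and acceptance problem sizes (12
samples × ~800 peaks for the end-to-end runs; 500 × 10-sample null
simulations for PERMANOVA calibration; 50 × 200-peak instances for the
matcher equivalence) were chosen so the full suite exercises every code
path at desk scale.

## Known limitations

* The SPANS-style score is a reimplementation; absolute score values are
  not comparable with other SPANS implementations, only the ranking within
  a grid is meaningful. Like the original procedure, it is unreliable when
  the groups genuinely differ in their overall intensity distributions.
* Chao1 on intensity pseudo-counts inherits the arbitrariness of the
  count conversion.
* The builtin transformation key is generic; biological conclusions about
  transformation types should use a system-specific key.
* Two-way PERMANOVA uses sequential sums of squares: term order matters
  for unbalanced designs.
* KEGG/pathway mapping and raw-spectra processing are out of scope; the
  pipeline starts at the assigned-formula report.
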