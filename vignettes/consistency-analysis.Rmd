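---
title: "Test-retest consistency analysis of task-modulated connections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Test-retest consistency analysis of task-modulated connections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retestconn)
```

## The problem

Task studies of brain connectivity routinely report edges whose coupling
(here: source-space spectral coherence) differs between an active task —
picture naming — and a visual baseline. Whether those edges would appear
again if the same subjects were measured on another day is a separate,
and rarely asked, question. `retestconn` implements a two-session
consistency analysis for such task-contrast connections: it selects
candidate connections from the first session only, quantifies their
test-retest consistency across both sessions with the intraclass
correlation ICC(3,1), and then asks what distinguishes consistent from
inconsistent connections behaviorally, functionally, and structurally.

The basic quantity throughout is the *task contrast*: the
naming-minus-visual coherence difference of one connection, per subject
and session. Working on contrasts cancels condition-independent
artifacts (in real source-space data, most of the spatial-leakage bias).

## Pipeline

**1. Selection (session 1 only).** For every grid-point pair a paired
t-test over subjects of the session-1 contrast, two-sided, at one of two
uncorrected thresholds: selection A (p < 10⁻³) or selection B
(p < 10⁻⁴). Connections shorter than 4 cm between endpoints are removed
(in source space, short connections are leakage-dominated; the limit is
inclusive — exactly 4 cm survives). Selection uses only session 1 so
that the consistency analysis, which needs session 2, is not circular.

**2. Bundles.** Surviving connections are grouped into spatial bundles:
two connections are linked when their inter-connection distance is at
most 1.3 cm, and bundles are the connected components of that graph
(single linkage); components with fewer than 20 members are dropped.
The inter-connection distance of two undirected connections is defined
here as the smaller, over the two ways of pairing their endpoints, of
the larger endpoint-to-endpoint distance — the tightest reading of
"maximum distance between connections" that is symmetric, undirected,
and brute-force testable (the suite checks the components against a
transitive-closure oracle).

**3. Parcel edges.** Each bundle member maps to the parcel pair of its
endpoints; duplicate pairs merge, self-pairs and pairs touching excluded
(anterior) parcels are dropped. For every emitted parcel edge the
contrast is then summed over *all* grid pairs between the two parcels —
not only the significant ones — giving an n-subjects × 2-sessions
series per edge. The modulation direction (increase/decrease) is the
sign of the session-1 group mean of that series; an exact zero
(probability zero under continuous data) is labeled increase with a
warning.

**4. Consistency.** For each parcel edge the subjects × sessions series
enters a two-way ANOVA decomposition (no replicates): between-subjects
mean square BMS, between-sessions mean square JMS, residual EMS, and

$$\mathrm{ICC}(3,1) = \frac{\mathrm{BMS} - \mathrm{EMS}}
  {\mathrm{BMS} + (k-1)\,\mathrm{EMS}}, \qquad k = 2 .$$

This is the *consistency* form: an additive session offset (a global
day effect) does not change it, which the generator can demonstrate
directly via its optional session-offset parameter. An edge is labeled
consistent iff ICC > 0.4 strictly (0.5 as the stricter replication
threshold; both exposed in the configuration). Confidence intervals are
the Shrout–Fleiss F-based bounds: with F = BMS/EMS on
(n−1, (n−1)(k−1)) degrees of freedom, the 95% bounds are
(F/F₀.₉₇₅ − 1)/(F/F₀.₉₇₅ + k − 1) and symmetrically for the upper
bound. The interval method was an open choice; the F-based form is the
standard one for this ICC, and the suite validates it against a
Monte-Carlo simulation of the BMS/EMS pivot (10⁵ replicates, agreement
to 0.02).
Degenerate series (zero variance everywhere) are classified
inconsistent and logged rather than erroring the run.

**5. Properties.** Edges from all bands and windows are pooled
(edge identity = parcel pair × band × window). Per edge, a multiple
regression of the per-subject mean-over-sessions contrast on three
behavioral scores (letter fluency, category fluency, RAN/RAS naming
speed composite) with an overall F-test at p < 0.05 gives the `fitted`
flag — deliberately without multiple-testing correction, since the flag
is only compared *between* the consistent and inconsistent groups, for
which the inflation is symmetric. Group comparisons: chi-square of
consistency × fit and of laterality × direction (Yates continuity
correction automatically iff the table is 2 × 2 — the only convention
that reproduces both reference statistics, an uncorrected 2 × 3 and a
corrected 2 × 2), and two-sided Mann-Whitney U tests for absolute mean
strength, direct streamline count, structural shortest path length and
edge betweenness. The U test enumerates the exact distribution when
both groups have ≤ 20 untied observations and otherwise uses the
tie-corrected normal approximation with continuity correction.

**6. Structural metrics.** Structural connectomes are symmetric
parcel × parcel streamline-weight matrices. Edge length is the
reciprocal weight (stronger = closer; a −log alternative is provided),
shortest paths are Dijkstra's algorithm, and edge betweenness counts
all-pairs shortest paths through each edge with fractional credit for
ties, unnormalized (group comparisons are invariant to the
normalization constant, which is available as an option). Both
algorithms are implemented in the package and verified in the suite
against Floyd–Warshall, brute-force path enumeration, and an
independent graph library. Disconnected pairs propagate ∞; group
comparisons use finite values and log the infinite count.

## The synthetic-data generator

No raw recordings ship with the package; every stage is instead
exercised on synthetic studies with planted ground truth
(`synth_design()`, `simulate_study()`).

*Geometry.* Points on two hemispheric shells of radius 70 mm (left
x < 0), parcels by nearest-seed-centroid assignment within hemisphere,
seeds being sampled grid points (so parcels are never empty and the
nearest-centroid invariant is exactly testable). Parcels with centroid
y > 50 mm are flagged excluded, emulating the anterior exclusion.

*Connectivity.* For a planted parcel pair, every grid pair between the
two parcels draws a subject latent contrast δ ~ N(μ, σ_b²); each
session observes δ + ε with ε ~ N(0, σ_e²) i.i.d. The theoretical
consistency of such an edge is ρ = σ_b²/(σ_b² + σ_e²), and summing m
grid pairs multiplies both variance components by m, leaving ρ
invariant — which is why parcel aggregation recovers the planted level.
Values are realized as a uniform(0.2, 0.5) baseline for the visual task
and baseline + contrast for naming, clipped to [0, 1] with a warning
when clipping exceeds 1% (the pipeline consumes only differences, so
the baseline model is deliberately minimal). Non-planted connections
carry pure session noise.

*Behavior.* Three i.i.d. standard-normal scores per subject (hence
approximately uncorrelated predictors). For coupled edges the subject
latent δ gains β times the subject's behavioral axis (the mean of the
three scores) — on the latent, not the noise, matching the use of the
mean-over-days contrast as the regression outcome.

*Structure.* Streamline weights decay exponentially with inter-centroid
distance (scale 40 mm, level 500 at zero distance) under lognormal
multiplicative noise; weights below 0.5 are zeroed, leaving a
near-complete graph with occasional absent edges. Planted-reliable
pairs (ρ > 0.5) are multiplied by the design's `structural_boost`.

What the generator does *not* emulate: spatial leakage and its
correlation structure, non-Gaussian coherence distributions (real
coherence is bounded and skewed), session-specific head-position
effects beyond an additive offset, subject-level global connectivity
differences, and streamline-level tractography biases. Passing tests
therefore demonstrate correctness of the algorithms under the assumed
noise model, not robustness to these real-data features.

## Study conditions and problem sizes

The default design is the canonical two-session layout: 19 subjects, two
sessions, six frequency bands (theta 4–7 Hz to high gamma 60–90 Hz),
three time windows (0–400, 400–800, 800–1200 ms), 55 parcels per
hemisphere. The synthetic grid defaults to 300 points (the real
analysis used 5124 per hemisphere; a desk-scale grid preserves every
algorithmic property at a fraction of the memory). Session noise
defaults to σ_e = 0.003 coherence units, a small value on the coherence
scale consistent with contrasts of a few percent.

Three presets fix the remaining conditions once:

- `design_icc_recovery(rho)`: 200 planted parcel edges at one true ρ in
  a 200-point, 24-parcel, single-band/window study — the
  parameter-recovery condition (the suite checks the mean estimate
  against the 95% band of a 10⁵-replicate Monte-Carlo sampling oracle
  at n = 19, k = 2).
- `design_null()`: no planted effects over ~10⁴ connections — type-I
  calibration of the selection threshold.
- `design_strong_effects()`: 500 points over 16 parcels, one band, two
  windows; 12 planted edges with |μ| ≫ σ (8 at ρ = 0.8 with behavioral
  coupling and a 5-fold structural boost, 4 at ρ = 0.1). Two choices
  here were genuinely open. First, grid density: bundle linking at
  1.3 cm requires neighboring grid points within that range, so the
  preset uses 250 points per hemispheric shell (≈ 12 mm spacing).
  Second, planted pairs are chosen among well-separated (≥ 60 mm)
  parcel pairs *balanced by grid-pair count* across the two
  reliability groups: summed parcel strength scales with the number of
  member grid pairs, so without balancing, the strength comparison
  between groups would measure parcel size rather than the planted
  contrasts.

## Numerical choices and degenerate inputs

- Zero-variance connections in the t-test stage are flagged degenerate
  and excluded from selection (logged), rather than producing NaN.
- The 4 cm distance limit is inclusive; the 1.3 cm linkage and the
  bundle size 20 are inclusive thresholds (≥).
- Tied shortest paths are detected with a relative tolerance of 1e-12;
  betweenness credit is split fractionally among ties.
- ICC with BMS = EMS = 0 is undefined; such edges are reported as
  inconsistent. EMS = 0 with BMS > 0 gives ICC = 1 and a collapsed
  confidence interval (with a warning).
- The behavioral screen refuses rank-deficient predictor sets, naming
  the collinear columns.
- Chi-square tests error on zero margins; the pooled report skips (and
  notes) any comparison whose groups are empty or degenerate.
- All generators draw from seeded substreams of the design seed, so a
  design value-identical to another yields bit-identical data
  regardless of which generators are called, in which order.

## A small worked run

```{r, eval = FALSE}
study <- simulate_study(design_strong_effects(seed = 7))
run <- run_pipeline(study, pipeline_config(selection = "B"))
summary(run)
```

The run object carries the per-edge table (ICC with CI, label,
direction, behavioral fit, strength, laterality, structural profile),
per-stage selection counts, the pooled property report and a manifest
(configuration hash, versions, timings). `write_run()` exports
everything as TSV plus `manifest.json`; re-running with the same design
and configuration reproduces the files byte for byte.

## Known limitations

- The inter-connection distance definition is one defensible reading of
  an under-specified clustering rule; alternative readings (e.g.,
  minimum endpoint distance) would change bundle shapes, though not the
  downstream machinery.
- Consistency is estimated from k = 2 sessions; ICC estimates at this k
  are noisy (visible in the width of the recovery bands), so
  edge-level labels should be read together with their confidence
  intervals.
- The behavioral screen's per-edge p-values are uncorrected by design
  and must only be used comparatively between groups.
- With near-complete synthetic connectomes, betweenness medians are
  small but rarely exactly zero, unlike sparser real tractography
  graphs where zero medians occur.
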