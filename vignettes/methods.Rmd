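---
title: "Percentile-curve relapse prediction from flow cytometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Percentile-curve relapse prediction from flow cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes, which
assumptions that rests on, and where genuinely open design choices were
resolved. Nothing here states an empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## The clinical question and the data model

Childhood B-ALL is diagnosed with multicolour flow cytometry: per cell,
fluorescence intensities for ~20 immunophenotypic markers, acquired in
several tubes (aliquots) whose panels overlap in a set of backbone
markers (here CD19, CD45, CD10, CD34). Roughly a quarter of patients
later relapse. The package's premise is that the *distribution* of
marker expression over the leukaemic B-cell compartment — not only its
median — may differ between patients who relapse (class R) and those
who do not (class N), and that those differences are detectable at
diagnosis.

Each patient–marker pair is represented by its percentile vector: the
empirical quantiles of normalised intensity at levels 5, 10, ..., 95
(P = 19; the 15/50/85 levels used in the association stage are on this
grid, and a step-1 grid is available through the `grid` argument). The
grid spans the 5th–95th range because the normalisation (below) pins
exactly those two quantiles. Empirical quantiles use linear
interpolation between closest order statistics (R type 7), keeping the
curves continuous in the data.

## Preprocessing

* **Compensation** multiplies observed intensities by the inverse of
  the tube's spillover matrix (`observed = true %*% S`, unit-diagonal
  `S`).
* **Logicle transformation** with w = 0.75 decades, t = 262144,
  m = 4.5, a = 0. The biexponential and its constants are derived from
  the defining conditions (data zero at display position `w + a`; top
  of scale at `t`; vanishing second derivative at data zero, which
  yields the root condition `2 ln(d/b) + w(b + d) = 0`). The forward
  transform inverts the biexponential by vectorised Newton iteration
  from a monotone grid start; the round trip is accurate to better than
  1e-6 relative over `[-0.1 t, t]` (tested).
* **Tube merging.** The tube with the most markers is the reference
  (ties: first by id); every other tube is imputed independently onto
  it (star topology, no order dependence) by k = 1 nearest neighbour in
  Euclidean backbone space on the transformed scale; distance ties go
  to the lowest donor index. With ~4 backbone dimensions and thousands
  of events, 1-NN imputation approximately resamples the donor tube's
  conditional marker distribution; the acceptance suite checks the
  marginal distributions survive (KS < 0.1 at 5000 events).
* **Normalisation** maps, per marker and per patient,
  `x' = (x − q05)/(q95 − q05)`. By construction 10% of events fall
  outside [0, 1]; they are clipped by default (`clip = FALSE`
  available) so that percentile curves live on a fixed domain. A
  degenerate marker (q05 = q95) is an error. Applying the map twice
  would rescale with recomputed quantiles, so a state flag makes the
  second application an error.
* **CD19 gating** happens after merging and normalisation: a Gaussian
  KDE (Silverman bandwidth) on the gating marker, threshold at the
  deepest minimum between the two dominant modes, cells above retained.
  Two guards matter in practice: values clipped onto the domain
  boundaries are excluded from the density estimate (they form point
  masses that masquerade as modes), and the second mode must lie at
  least `min_sep` (default 0.15 of the range) from the first —
  closer maxima are ripples of one population, not a second one. If no
  separated second mode exists the function requires an explicit
  fallback threshold rather than guessing.
* **Subsampling** to a fixed event count per patient is uniform without
  replacement and seeded. A patient with fewer gated cells than
  requested is an error naming the patient — sampling with replacement
  would silently fabricate data.

The default subsample is 2000 events. With the default simulation
scale (5000 events/tube) and a B-cell fraction of ~0.85, gating leaves
roughly 4000–4500 cells, so a 5000-event subsample would always fail;
2000 keeps quantile noise at the 19-level grid well below the planted
effects studied here. A real-data analysis at instrument scale would
raise `events_per_tube` and `n_events` together.

## The Fisher's-Ratio model

For marker j and percentile k,
`FR_jk = (μ_Rjk − μ_Njk)² / (σ²_Rjk + σ²_Njk)`,
with μ the class *median* across patients (a mean option exists; the
median is the primary definition here) and σ the within-class sample
standard deviation (n − 1). Features with `FR > 0.5` are selected; when
nothing passes, the single best feature is used so a classifier can
always be built inside a cross-validation fold. σ estimation requires
at least two patients per class in every training set; stratified folds
plus this rule make the fold models well-defined (plain "at least one
patient of each class" would not suffice).

A new patient is scored per selected feature by comparing their value
with the two class references through a distance, and the two distances
share a denominator, so per-feature class probabilities sum to one
exactly. Two orientation conventions are implemented: the default
**proximity** convention (membership probability *increases* as the
patient approaches that class's reference — the behaviour the
classifier's design intends) and the inverted **as-printed** form kept
for literal reproduction; with a single feature the two produce
complementary hard labels, which the tests use as a sanity check of the
switch.

### The distance options, and why the default is what it is

Four distances are implemented (`fisher_fit(distance = ...)`):

* `"feature"` (default): per selected feature, `|v − μ_R|` vs
  `|v − μ_N|` — the patient's value against each class location on the
  common measurement scale. Any shared rescaling of the three
  quantities cancels in the probability ratio.
* `"marker_curve"`: one probability per marker, from Euclidean
  curve-to-curve distances over that marker's selected percentiles —
  the patient's percentile curve against each class's median curve.
* `"zscore"`: each class comparison in that class's own σ units.
* `"control_point"`: the scale-normalised construction in which the
  class references are `μ/σ` (each by its own σ) and the patient is
  scaled by the *average* of the two σs.

The control-point construction is kept because it is the literal
normalisation the control-point formulas state, but it is internally
inconsistent: the patient and the references are scaled by different
factors, so when σ_R ≠ σ_N the membership probability is driven by the
σ ratio rather than by the patient's value. On simulated cohorts with a
strongly planted CD38 shift the within-class dispersions differ
substantially between classes, and under the control-point distance
both classes receive near-identical probabilities even on features with
FR > 10 — the classifier stops discriminating for a reason that has
nothing to do with the data's information content. The `"feature"`
default measures the same distances on a common scale, which is also
exactly what the curve-to-curve picture of the method describes, and
recovers the planted effect reliably. This is a deliberate design
deviation, recorded here.

Aggregation is the unweighted mean of per-feature (or per-marker)
probabilities; the hard label uses threshold 0.5 with ties assigned to
N — the conservative choice for an imbalanced cohort where N is the
majority and the clinically less drastic call.

## Validation harness

* **Cross-validation**: stratified k-fold (k at most the smaller class
  size — the number of relapsing patients) and LOOCV, feature selection
  strictly inside each training fold. Per repeat, the pooled
  out-of-fold predictions give one confusion matrix and one trapezoidal
  ROC (rank/midrank computation; positive class R); the report is
  mean ± sd over repeats. LOOCV folds are deterministic, so with a
  deterministic classifier its repeats coincide (sd 0) — what varies
  across published repetitions of LOOCV is not well defined, and this
  package documents rather than invents it. K-fold repeats re-draw the
  stratified folds.
* **Feature frequency**: repeated stratified 75:25 splits (default
  100), per-split test accuracy and selected-marker sets, and marker
  usage frequencies among splits above each accuracy threshold.
* **Random-forest comparison**: repeated forests (default 100 × 50
  trees) on the flattened percentile matrix; OOB error per run and
  permutation importance (unscaled mean decrease in accuracy), summed
  from percentile-level features to marker level so total importance is
  preserved.
* **Summary comparisons**: per-marker two-sample t-tests (Welch by
  default) on per-patient median/mean/sd and, when supplied, on the
  fitted generalized-logistic α and γ. Flags at p < 0.05 with no
  multiplicity correction by default — the descriptive screening
  convention this analysis follows — with an optional
  Benjamini–Hochberg column.

A note on seeded functions: every routine that consumes randomness
takes an explicit seed and restores the caller's RNG state on exit, so
simulation loops written around the package (e.g. permutation tests)
draw what they appear to draw.

## The generalized-logistic fit

`F(I) = 1/(1 + A e^{−αI})^{1/γ}`; γ = 1 is the conventional logistic
and γ → 0 the Gompertz limit (tested against the closed form at
γ = 0.01). The carrying capacity is fixed at 1 and A is eliminated in
closed form by anchoring the curve through the first observed point of
the cumulative distribution — reading "the initial value is fixed to
the first percentile" as an exact interpolation constraint. Anchoring
on an observed point (rather than interpolating a level between points)
makes noise-free recovery exact; α and γ are then estimated by
Levenberg–Marquardt on log-parameters with a 3 × 3 grid of restarts,
and non-convergence returns a flagged fit instead of an error. Fitted
parameters are descriptive output only — they are not classification
features, since parameter-level class differences are not robust to the
location statistic used.

Both the percentile curve (levels/100 against values) and a full
empirical CDF are accepted as input; the anchoring rule treats either
uniformly.

## What the simulator emulates — and what it does not

Per marker, cells are drawn from a two-component (negative/positive)
Gaussian mixture on the logicle display scale, with per-marker baseline
locations, spreads and positive fractions chosen to look like a B-ALL
diagnostic panel (CD19 strongly bimodal with an ~0.85 B-cell fraction
so the gate has something to find; T-lineage markers mostly negative;
B-lineage markers mostly positive). Patient-level heterogeneity enters
through Gaussian shifts of the component locations (sd 0.15 decades
common to both components plus 0.15 specific to the positive one).
Mixing weights are patient-invariant by default (`sd_logit_pi = 0`):
mixture quantiles are discontinuous in the weight at plateau-crossing
percentile levels, so weight jitter creates bimodal across-patient
feature distributions whose class medians are uninformative — a regime
the percentile-curve representation is not designed for. The class
effect shifts the positive-component location of the configured markers
by δ (default CD38, δ = −1 decade, all cells) in relapse patients;
covariates (hyperdiploidy, sex, t(12;21)) are thresholded latent
Gaussians sharing the per-patient marker-location latent, giving
controllable point-biserial structure (defaults: −0.5, −0.4, +0.4 with
the CD38 level). Labels are assigned by exact prevalence counts; each
tube is an independent draw from the same patient model, which is what
makes nearest-neighbour merging statistically consistent. A single
master seed drives everything, split per patient by counter, so partial
regeneration (`include = "direct"`) reproduces the identical draws.

Deliberately not simulated: instrument artefacts (time drift, margin
events, debris, doublets — upstream manual QC removes these in
practice), non-B lineages, batch effects beyond what the per-patient
quantile normalisation addresses, and any dependence between markers
within a cell beyond the shared patient effects. Passing tests on this
generator therefore show that the pipeline recovers what it is supposed
to recover *under its own assumptions*; they cannot show that real
cohorts satisfy those assumptions.

Default problem sizes — 56 patients, prevalence 13/56, 3 tubes, 5000
events/tube, 2000 events retained — are the simulation analogue of a
two-centre retrospective cohort at desk scale; the acceptance studies
in `scripts/acceptance.R` and the test suite use these sizes directly.

## Numerical choices and degenerate inputs

* Logicle inversion: 512-point monotone grid start + Newton to
  machine tolerance; strictly increasing over all reals, so negative
  (compensated) values need no clamping.
* Quantile convention: type 7 everywhere.
* KDE gate: `stats::density`, Silverman `bw.nrd0`, 512 grid points;
  deterministic.
* Fisher: zero-variance features are dropped with a warning; an empty
  class or an all-zero-variance panel is an error.
* Tie-breaks: NN imputation → lowest donor index; classifier hard
  label at exactly 0.5 → N; merge reference → first tube id.
* Cross-validation rejects k beyond the smaller class size rather than
  silently shrinking folds.

## Known limitations

* The 5th–95th normalisation is unstable for markers whose 95th
  percentile falls in the low-density gap between a large negative and
  a small positive population (mostly-negative markers such as cyCD3):
  small sampling differences move q95 across the gap and shift the
  whole normalised curve. This is a property of the normalisation, and
  is visible in the preprocessing-fidelity measurements as those
  markers dominating the (still small) disagreement.
* Null-calibration behaviour: on effect-free cohorts the
  distance-ratio classifier's LOOCV accuracy centres near 0.6 — between
  coin-flipping and always-majority — because features selected by
  chance at FR > 0.5 have class-median gaps of about one within-class
  sd, which pulls an average patient toward the majority class only
  with probability ~0.7 per feature. An expectation that null accuracy
  sit at the majority-class rate (0.77 here) is not attainable for this
  classifier family at n = 56 with 13 relapse patients; the
  corresponding acceptance check is left failing by design and the
  permutation-AUC check (which is satisfied, ~0.5) is the calibration
  statement that does hold.
* LOOCV with in-fold selection is known to bias AUC pessimistically on
  small imbalanced cohorts; single-permutation AUCs as low as ~0.3
  occur under the null, which is why calibration statements here
  average over permutations.
* Percentile features of one marker are strongly correlated across
  levels; selected-feature counts overstate the effective number of
  independent features, and the mean-probability aggregation treats
  them as exchangeable votes.
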