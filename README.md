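# cytofisher

Percentile-curve and Fisher's-Ratio analysis of diagnostic flow
cytometry for relapse-risk stratification in childhood B-cell acute
lymphoblastic leukaemia (B-ALL).

## The problem and the method

At diagnosis, a B-ALL patient's bone-marrow aspirate is immunophenotyped
by multicolour flow cytometry: tens of thousands of cells are measured
on ~20 surface/intracellular markers (CD19, CD10, CD38, CD45, ...),
split across several staining tubes that share a set of *backbone*
markers. Clinically this is used to identify the leukaemic population;
this package asks whether the *expression level distributions* of those
markers carry prognostic information about relapse.

The analysis chain:

1. **Preprocessing.** Each tube is compensated with its spillover
   matrix, transformed with the logicle (biexponential) scale
   (w = 0.75, t = 262144, m = 4.5, a = 0), and the patient's tubes are
   merged into one complete event matrix by k = 1 nearest-neighbour
   imputation in backbone-marker space. Intensities are normalised per
   marker by the 5th–95th percentile map `x' = (x − q05)/(q95 − q05)`
   (clipped to [0, 1]), the CD19⁺ B-cell population is selected by a
   kernel-density threshold, and a fixed number of events is subsampled.
2. **Representation.** Each patient–marker pair becomes a percentile
   vector: the empirical quantiles at levels 5, 10, ..., 95 (so each
   patient is an M × P matrix `X`). Summary statistics (median, mean,
   sd) and generalized-logistic fits of the cumulative intensity
   `F(I) = K / (1 + A e^{−αI})^{1/γ}` (K = 1, A anchored at the first
   percentile) are also provided.
3. **Feature ranking.** For classes R (relapse) and N (non-relapse),
   the Fisher's-Ratio matrix
   `FR_jk = (μ_Rjk − μ_Njk)² / (σ²_Rjk + σ²_Njk)`
   ranks each (marker j, percentile k) feature, with μ the class median
   across patients and σ the within-class standard deviation. Features
   with `FR > 0.5` are selected.
4. **Classification.** A new patient is scored per selected feature by
   distances to the two class control points, converted to
   probabilities with a shared denominator
   (`P(∈R) + P(∈N) = 1`) and averaged over the selected features;
   relapse is called at probability > 0.5.
5. **Validation and association.** Repeated stratified k-fold and
   leave-one-out cross-validation with in-fold feature selection;
   accuracy/sensitivity/specificity/PPV/NPV and trapezoidal AUC;
   100-split feature-frequency analysis; a random-forest comparison
   (OOB error, permutation importance); and Pearson association of
   CD38 percentiles P15/P50/P85 with clinical and cytogenetic
   covariates.

Because no cohort of this kind is publicly deposited, the package
includes a first-class synthetic cohort simulator
(`simulate_cohort()`): per-cell expression from two-component
location–scale mixtures on the logicle scale, multi-tube acquisition
with backbone markers and spillover, an imbalanced relapse outcome, a
plantable class shift (default: CD38 down by one decade in relapse) and
covariates correlated with marker levels through shared latent
Gaussians. Every downstream stage is testable against this generator's
ground truth.

## Worked example

```r
library(cytofisher)

coh      <- simulate_cohort(n_patients = 24, prevalence = 0.25,
                            events_per_tube = 2000, seed = 42,
                            include = "direct")
samples  <- direct_samples(coh, n_events = 1000, seed = 42)
features <- percentile_features(samples)

model <- fisher_fit(features)
head(marker_fr(model), 3)
#>   marker mean_fr max_fr n_selected
#> 1 CD38    10.6   19.1           18
#> 2 cyCD3    0.688  1.26          15
#> 3 CD7      0.555  0.888         12

cross_validate(features, "loocv", repeats = 1, seed = 42)
#> <cv_result> loocv (k = 24), 1 repeats
#>   metric       mean    sd
#> 1 accuracy    0.875     0
#> 2 sensitivity 0.833     0
#> 3 specificity 0.889     0
#> 4 ppv         0.714     0
#> 5 npv         0.941     0
#> 6 auc         0.944     0

rep <- correlate_markers(coh$clinical, features)
dplyr::filter(tidy(rep), var1 == "CD38_P85",
              var2 %in% c("hyperdiploid", "relapse"))
#>   var1     var2              r        p     n significant
#> 1 CD38_P85 relapse      -0.929 5.95e-11    24 TRUE
#> 2 CD38_P85 hyperdiploid -0.498 1.57e- 2    23 TRUE
```

The planted CD38 under-expression dominates the Fisher's-Ratio ranking
(mean FR ≈ 10.6 against < 0.7 for every unshifted marker), drives
leave-one-out accuracy of 0.875 on this small cohort, and P85 of CD38
correlates negatively with both relapse and hyperdiploid karyotype, the
direction the generator plants.

The full FCS path is exercised by `run_pipeline()`: simulate → map to
raw scale with spillover → write FCS 3.0 + clinical CSV → read back →
preprocess → fit → cross-validate → associate, all from one (YAML-able)
config, bit-reproducible under its master seed. A thin command-line
wrapper lives in `inst/scripts/run_pipeline.R`.

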