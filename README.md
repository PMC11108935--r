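# msdimensions

Data-driven discovery of independent dimensions of multiple sclerosis (MS)
neuropathology from donor-level autopsy data.

MS brain donors differ widely in lesion burden, lesion stage composition
(active / mixed / inactive / remyelinated), microglia morphology, cortical
demyelination, and inflammatory features such as perivascular cuffs and
microglia nodules. `msdimensions` condenses a 13-variable mixed table of
such donor-level measurements into a few orthogonal dimensions and validates
them against clinical and neuropathological covariates. The core pipeline
is:

1. **Feature derivation** — lesion-type and morphology proportions, brainstem
   lesion load and reactive-site load, cortical lesion rate, activation
   score, cuff/nodule presence (`derive_features()`), with a strict
   zero-vs-missing distinction.
2. **Compositional transforms** — multiplicative zero replacement and
   centered log-ratio (CLR) per compositional block:
   `clr_j = ln(x_j / g(x))`, applied after zeros are replaced by a small
   delta that preserves nonzero ratios (`replace_zeros()`, `clr_transform()`).
3. **Imputation** — regularized iterative FAMD imputation of missing cells,
   with the number of components `ncp` chosen by cell-masking
   cross-validation, maximum 12 (`estimate_ncp()`, `impute_famd()`).
   Observed cells are never modified.
4. **FAMD** — factor analysis of mixed data: SVD of a matrix in which
   continuous variables are population-standardized and categorical
   indicator columns carry multiple-correspondence scaling, so each
   continuous variable contributes inertia 1 and each L-level categorical
   L − 1 (`famd()`). Dimensions with eigenvalue λ > 1.5 are retained
   (`select_dimensions()`).
5. **Outlier loop** — donors are removed only when they both (a) contribute
   to a selected dimension beyond the upper fence of a medcouple-adjusted
   boxplot of contributions and (b) are univariate adjusted-boxplot outliers
   on a continuous input; imputation and FAMD are repeated until no donor is
   removed (`medcouple()`, `adjusted_fences()`, `detect_outliers()`,
   `run_dimension_pipeline()`).
6. **Validation** — Spearman / Mann–Whitney / Kruskal–Wallis tests of the
   dimension scores against typed covariates, Benjamini–Hochberg FDR within
   families of related tests at q ≤ 0.1 (`run_validation_battery()`).

A synthetic-cohort generator (`generate_cohort()`, `inject_outliers()`)
emulates the study's data structure — three standard-normal latent
dimensions driving multinomial compositions, negative-binomial loads, a
gamma cortical rate and logistic binaries, with realistic missingness and
covariates calibrated to target Spearman correlations — so every stage is
testable with known ground truth.

## Worked example

```r
library(msdimensions)

coh <- generate_cohort(n = 228, seed = 42)   # synthetic cohort + ground truth
tab <- prepare_input(coh$input)              # 13-variable mixed table (CLR applied)
fit <- run_dimension_pipeline(tab, pipeline_config(), seed = 42)
fit
#> Neuropathology dimension fit
#>   final cohort: 222 donors; 6 removed in 2 round(s)
#>   ncp per round: 9, 10, 10
#>   selected dimensions (eigenvalue > 1.5): 1, 2, 3
#>   eigenvalues: 4.06 (31.23%), 3.09 (23.76%), 2.43 (18.70%)
```

Three dimensions exceed the eigenvalue threshold, together carrying ~74% of
the total inertia of 13; six donors met both outlier criteria and were
removed over two rounds, after which the loop reached its fixed point. The
scores are sign-anchored (dimension 1 correlates positively with lesion
load), so runs are comparable. Validating the scores against the cohort's
covariates:

```r
covs <- coh$covariates[match(fit$model$ids, coh$covariates$donor_id), ]
res <- run_validation_battery(fit$model$scores[, 1:3], covs,
  families = list(severity = c("age_at_death", "time_to_edss6"),
                  symptoms = "symptom_load_general"))
subset(res, significant, c(family, dimension, covariate, statistic, p_value, q_value))
#>     family dimension     covariate statistic p_value q_value
#> 1 severity         1  age_at_death     -0.52 4.6e-17 2.8e-16
#> 2 severity         2  age_at_death     -0.18 8.1e-03 1.2e-02
#> 4 severity         1 time_to_edss6     -0.27 4.2e-05 1.2e-04
#> 5 severity         2 time_to_edss6     -0.22 1.2e-03 2.4e-03
```

Dimension 1 shows the strong negative Spearman correlation with age at death
(ρ = −0.52 here; the generator's target is −0.48) that the covariate
calibration builds in — donors scoring high on the inflammatory axis died
younger. `write_pipeline_results(fit, "out/")` writes the eigenvalue table,
donor scores under both rank conventions, the variable-by-dimension summary,
and a JSON log of every parameter and removal decision.

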