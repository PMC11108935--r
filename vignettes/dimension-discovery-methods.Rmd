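---
title: "Discovering dimensions of MS neuropathology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering dimensions of MS neuropathology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msdimensions)
```

## The problem

Multiple sclerosis neuropathology at autopsy is heterogeneous: donors differ
in how many white-matter lesions they carry, what stage those lesions are in
(active, mixed active/inactive, inactive, remyelinated), how the microglia in
active and mixed lesions look (ramified, ameboid, foamy), how much cortical
demyelination is present, and whether perivascular cuffs and microglia
nodules occur. This package implements a data-driven pipeline that condenses
a donor-level table of such measurements into a small number of independent
*dimensions* of neuropathology, and then validates those dimensions against
clinical, demographic and immunological covariates that were not part of the
input.

The pipeline is: derived donor features → compositional transforms →
cross-validated low-rank imputation → factor analysis of mixed data (FAMD) →
iterative removal of highly contributing outlier donors → rank-based
validation with family-wise FDR control. A synthetic-cohort generator with
known latent structure makes every stage testable without the original
cohort.

## The input table

The mixed input table has 13 variables per donor:

* 4 CLR-transformed white-matter lesion-type proportions
  (active, mixed, inactive, remyelinated; over all dissected blocks),
* 3 CLR-transformed microglia-morphology proportions
  (ramified, ameboid, foamy; over active + mixed lesions),
* the microglia activation score (mean of per-lesion morphology scores,
  ramified = 0, ameboid = 0.5, foamy = 1),
* brainstem lesion load and reactive-site load (counts in standard blocks,
  free of sampling bias),
* the cortical lesion rate (lesions per cortex-containing block),
* binary presence of cuffs and of nodules.

That roster — 11 continuous plus 2 binary variables — is fixed by variance
accounting: FAMD total inertia equals the number of continuous variables
plus one per binary variable, and a leading eigenvalue of 2.60 carrying
19.98% of the variance implies a total of 13.0. Note the distinction between
zero and missing everywhere in the feature layer: a donor whose standard
brainstem blocks were dissected and lesion-free has load 0; a donor without
standard blocks has a missing load.

## Compositional handling

Proportions that sum to one cannot be analysed as if they were free
variables — the constant-sum constraint alone manufactures negative
correlations. Each compositional block is therefore centered-log-ratio (CLR)
transformed: each part is replaced by the log of its ratio to the geometric
mean of the block. Because zeros are possible (a donor may have no active
lesion), multiplicative zero replacement precedes the CLR: zero parts become
a small δ and nonzero parts shrink multiplicatively, preserving their ratios
exactly. The default δ per block is 0.65 × the smallest nonzero part
observed in that block across the cohort, the common choice when no
detection limit is known; δ is configurable per block and recorded in the
pipeline log. CLR is applied within each block, never across blocks.

Two consequences matter downstream. First, a CLR block is rank-deficient
(its parts sum to zero), so the processed 13-variable matrix has rank 11;
the factorisation computes at most 11 nontrivial dimensions even when 12 are
requested. Second, a 3-part CLR block *structurally* carries a leading
eigenvalue of at least 1.5 among its standardized parts, which is why the
eigenvalue threshold used for dimension selection (see below) must be judged
against the structured alternative, not against zero.

## FAMD

Factor analysis of mixed data balances continuous and categorical variables:
continuous columns are centered and scaled by their population standard
deviation (divisor n), so each contributes inertia 1; each categorical
level's indicator column is divided by the square root of its level
proportion and centered, so a variable with L levels contributes inertia
L − 1. The factorisation is the SVD of this weighted matrix under uniform
row weights 1/n. Eigenvalues are squared singular values; donor scores are
principal coordinates; the contribution of donor i to dimension s is
100 · F²ᵢₛ/(n λₛ); a variable's squared cosine on a dimension is its squared
correlation (continuous) or correlation ratio (categorical) with the
dimension scores. Fuzzy indicator rows produced by imputation enter
directly, with level proportions taken from column means.

Dimensions with eigenvalue strictly above 1.5 are selected. Because an SVD
determines each axis only up to sign, selected dimensions are anchored:
scores are negated if needed so that a designated variable (defaults:
lesion load for dimension 1, CLR active proportion for dimension 2, cortical
lesion rate for dimension 3) correlates non-negatively with the dimension.
Equal eigenvalues are ordered deterministically by the SVD's output order;
no randomness is involved anywhere in the factorisation.

## Missing-data imputation

Loads and the cortical lesion rate are missing for some donors (no standard
or no cortical blocks dissected). Missing cells are imputed by regularized
iterative FAMD: initialise with column means / observed level proportions;
FAMD-preprocess the completed table; reconstruct at rank ncp with each
retained singular value shrunk by (d² − σ²)/d, where σ² is the mean of the
discarded eigenvalues; overwrite only the originally missing cells (fuzzily
for indicators, clipped to [0, 1] and renormalised); iterate until the
relative change of fitted values falls below 10⁻⁶ (cap 1000 iterations).
ncp = 0 reduces to mean/proportion imputation; observed cells are never
touched.

ncp is chosen by cell-masking cross-validation: for each candidate
0..12, a random 5% of observed cells is masked in each of 5 repetitions,
imputed, and scored by squared error on the preprocessed scale; the
candidate with the lowest mean error wins (ties to the smaller). The 5%/5
settings are configurable; on pure-noise tables the differences between
small candidates sit within fold noise at 5% masking, so the test suite
demonstrates the noise→0 property at 20% masking, where it is robust.
Randomness enters only through the masking draws, which take an explicit
seed; imputation itself is deterministic given ncp.

## Outlier loop

A donor is removed only if it (a) contributes to at least one selected
dimension beyond the upper whisker fence of an adjusted boxplot of the
contributions, and (b) is a univariate outlier (outside either adjusted
fence) on at least one continuous input variable, evaluated on observed
values only. The adjusted boxplot scales Tukey's whiskers by exp(±c·MC)
with MC the medcouple, a robust skewness statistic computed here by exact
O(n²) enumeration (with the standard −1/0/+1 kernel for median ties), so
ordinary skewness does not flag donors. Quartiles use linear interpolation
of order statistics (R type 7); the decision boundary is the fence itself.
Removal triggers a fresh round — re-estimated ncp, re-imputation, re-fitted
FAMD — until no donor is removed (cap 10 rounds, abort if the cohort falls
below 50 donors).

A property worth knowing when interpreting this loop: when donor scores are
approximately Gaussian, contributions are approximately χ²₁-distributed, and
the adjusted fence on a χ²₁ sample of size 228 leaves at least one donor
outside it in roughly 40% of samples per dimension. Across three dimensions
most cohorts therefore flag *someone* under criterion (a), and flagged
donors often also satisfy (b), because the same extreme values drive both.
The dual criterion limits removals to donors whose influence comes from
singular extreme values, but the loop should not be expected to terminate
after one round with high probability on arbitrary data; on the synthetic
default cohort it typically removes a handful of genuine dual-criterion
donors over 1–3 rounds.

## Validation battery

Selected dimension scores are tested against covariates with rank-based
tests chosen by covariate type: Spearman correlation (Pearson on mid-ranks,
two-sided p from the t approximation) for continuous covariates;
Mann–Whitney U (exact for tie-free totals ≤ 8, otherwise normal
approximation with continuity and tie corrections) for binary covariates;
Kruskal–Wallis with tie correction for multi-level covariates, with
post-hoc pairwise Mann–Whitney contrasts kept in the same FDR family.
Missing covariate values are handled by pairwise deletion and the n used is
recorded per test. Benjamini–Hochberg adjustment is applied within each
family of closely related tests, with significance declared at q ≤ 0.1.
Two rank conventions are emitted for donor scores: mid-ranks for the tests,
and unique order-of-appearance ranks for plotting donors along an axis. For
plot overlays, a centered moving average over a window of 20 (10 before,
9 after — the even window has to be anchored on one side; left-of-center is
the package's convention) is emitted only where the window holds at most 10
missing slots.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes while
keeping ground truth known. Three independent standard-normal latent
dimensions drive: logistic-normal compositional probabilities, from which
integer lesion counts are drawn multinomially (so real structural zeros
occur and the CLR stage recovers linear latent structure); negative-binomial
loads and a gamma cortical rate with log-links; Bernoulli cuff/nodule with
logistic links; and the activation score computed from the morphology
counts exactly as the feature layer defines it. Missingness is MCAR at the
cohort's observed rates (loads jointly 14/228, cortical rate 25/228; an MAR
variant is not provided because no mechanism is reported). Validation
covariates are Gaussian copies of a designated latent, calibrated through
the exact Gaussian identity r = 2 sin(πρ/6) to hit a target Spearman ρ —
the defaults reproduce the strongest reported validation signals, e.g.
age at death at ρ = −0.48 against latent 1.

Default loadings use mutually orthogonal sum-zero contrasts within each
compositional block (e.g. active+mixed vs inactive+remyelinated for latent
1; mixed+inactive vs active+remyelinated for latent 3), with magnitudes
chosen once so that, at n = 228, the fitted spectrum has three well-separated
eigenvalues above 1.5 (≈ 4.1, 3.1, 2.3) and each oriented dimension tracks
its best-matched latent at mean |ρ| ≥ 0.8 over repeated cohorts. The
separation is deliberately larger than a near-degenerate spectrum would
give: with λ₂ ≈ λ₃ the corresponding latents mix freely under sampling
noise and per-dimension recovery becomes ill-defined. Injected outliers
displace a donor's loads and cortical rate to a configurable number of IQRs
beyond the cohort's adjusted upper fence, producing donors that are
simultaneously univariate outliers and dominant contributors.

What passing tests on this generator do *not* show: real cohorts have
measurement structure the generator omits (spatial sampling bias, reader
effects, non-MCAR missingness, covariate networks richer than one latent
per covariate), so recovery rates here are upper bounds on what real data
would give, not estimates of it.

## Numerical choices and degenerate inputs

* Population (divisor-n) standardization throughout, matching the FAMD
  convention; sample-SD scaling would change every eigenvalue.
* Rank is detected at 10⁻¹⁰ relative to the leading singular value;
  requesting more components than the rank truncates with a warning.
* Constant continuous columns and single-level categorical variables are
  errors naming the column; zero-frequency categorical levels are dropped
  with a warning.
* An all-zero composition cannot be zero-replaced (error); a zero-total
  proportion is missing, with a warning at the feature layer.
* Degenerate IQR = 0 collapses fences to [Q1, Q3] with a warning; an
  all-identical sample has medcouple 0 by convention.
* Ties in the CV argmin for ncp resolve to the smaller candidate.

## Problem sizes used by the test-suite

Unit and property tests run on tables of 20–228 rows; the statistical
acceptance checks use 100 cohorts for the eigenvalue-count rate, 20 full
pipeline runs each for latent recovery and outlier behaviour, and 500
replicates for the null FDR rate — sizes at which each check's Monte-Carlo
error is small relative to its assertion margin while the whole suite stays
fast.

## Known limitations

* The eigenvalue > 1.5 selection rule cannot distinguish compositional
  closure structure from genuine shared structure for small CLR blocks
  (a 3-part block alone reaches 1.5); it is informative only because the
  structured spectrum sits far above it.
* The outlier loop's one-round termination is a property of a particular
  dataset, not of the method; see the χ²₁ analysis above.
* Single imputation: imputation uncertainty is not propagated into the
  factorisation or the validation tests.
* The spreadsheet layout of externally deposited cohort files is not
  hard-coded; real data enters through the documented CSV schema of
  `read_feature_table()` / `prepare_input()`.
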