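---
title: "Methylation drift clocks for culture-expanded T cells: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation drift clocks for culture-expanded T cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftclock)
```

## The scientific problem

In vitro expansion of T cells, including CAR T-cell manufacturing, is
accompanied by a slow, near-linear accumulation of DNA methylation at
specific CpG sites — epigenetic drift. Two properties make this drift
analytically useful. First, it is linear enough in time that a sparse
penalized regression of days in culture on beta values works as a clock.
Second, it appears to carry prognostic information: in clinical CAR T-cell
products, higher drift-CpG methylation at a fixed nominal culture time
associates with worse overall survival, so the clock's *residual* variation
(product-intrinsic drift beyond nominal culture time) is itself a
biomarker. `driftclock` packages the full chain: filtering, screening,
clock training, survival modelling, and a read-level test that
distinguishes stochastic drift from coordinated (writer-driven)
methylation.

The pipeline operates downstream of array preprocessing: its unit of input
is a beta matrix (CpGs × samples, β ∈ [0, 1], `NA` allowed), a sample sheet
of covariates, and a probe annotation. IDAT handling, normalization and
bisulfite read alignment are deliberately out of scope.

## Stage-by-stage model and parameters

### Probe and composition filtering

Probes are excluded for SNP overlap (`snp_maf > 0.01`, i.e. MAF > 1%), X/Y
location, or cross-reactivity. Each removed probe is attributed to the
*first* matching rule in the fixed order SNP → XY → cross-reactive →
composition, so category counts partition the input — a property the tests
verify over all flag combinations.

Because the CD4⁺/CD8⁺ ratio falls during expansion, CpGs that differ
between purified CD4⁺ and CD8⁺ cells would register spurious "drift".
`composition_dmps()` flags CpGs with |Δ mean β| > 0.10 **or** BH-adjusted
p < 0.05 — the union, which is the conservative direction for an exclusion
filter. The per-CpG test defaults to limma's empirical-Bayes moderated t
(the standard for small-n methylation contrasts); a plain Welch t is
available via `method = "welch"`. BH adjustment spans all CpGs in the
reference matrix, not only candidates. A CpG with no variance in either
group and equal means is assigned p = 1.

### Deconvolution

`estimate_fractions()` solves min ‖s − R f‖₂ subject to f ≥ 0, Σf = 1, by
non-negative least squares on a system augmented with a heavily weighted
(1e6) sum-to-one row, followed by exact renormalization; the
pre-normalization sum already agrees with 1 to ~1e-10, so the
renormalization is numerically a no-op while making the simplex constraint
exact. Constrained projection was preferred over unconstrained projection
plus renormalization because the output must be reportable as proportions.
Up to 10% missing betas per sample are imputed by the reference row mean;
more is an error, as is a rank-deficient reference (reported with the
offending collinear cell types).

### Drift screen

`correlate_with_time()` treats every hybridization (not donor) as one
observation, computes per-CpG Pearson r against days in culture with
pairwise-complete handling of missing betas, drops CpGs with fewer than 3
complete pairs (flagged), and assigns r = 0 to zero-variance CpGs by
convention. Selection uses *strict* inequalities, `r > 0.9` and
`r < −0.9`: a CpG at exactly 0.9 is not selected, and the boundary is
unit-tested. Candidates whose methylation correlates with chronological age
(|r| > 0.3) in an independent reference are removed, so the clock measures
culture time rather than donor age; candidates absent from the reference
are kept with a warning rather than silently dropped. Day-0 vs day-22
differential methylation uses the conjunction |Δβ| > 0.20 **and** adjusted
p < 0.05, with explicit group-id lists so the caller decides which samples
enter each arm.

### Penalized clocks

`train_penalized_clock()` fits glmnet's elastic net (α = 0.5 for the sparse
clock, α = 0 for the ridge variant used on small survival-selected panels)
along a log-spaced λ path, choosing λ by 10-fold cross-validation. Folds
are stratified by day value — samples are ordered by the response and dealt
cyclically after a seeded shuffle — so no fold can lack the time gradient.
We take λ_min rather than λ_1se by default (exposed as
`lambda_choice`): the design goal is predictive accuracy, and the 1-SE rule
is available for users who prefer a sparser, flatter solution.

Numerical conventions worth knowing:

- glmnet standardizes the response internally; on the original day scale
  the L1 weight is exactly λα while the ridge weight carries a factor
  1/sd_n(y). The package's KKT tests verify stationarity under exactly this
  parametrization, and the λ = 0 limit is checked against closed-form least
  squares to 1e-6, the λ → ∞ limit against the intercept-only model
  exactly.
- Fixed-λ fits are computed at the end of a decreasing warm-start path with
  `thresh = 1e-16`; cold single-λ fits are noticeably less accurate.
- Predictions are never clipped: a negative predicted day is reported
  as-is, since downstream Cox models only use differences.
- `evaluate_clock()` reports r² as the squared Pearson correlation (the
  scatter-plot convention) alongside the coefficient of determination
  `r2_cod = 1 − SS_res/SS_tot`; the two differ under bias, and constant or
  anti-correlated predictions are flagged (`r_squared = 0` by convention
  for constant predictions).

### Survival models

Each CpG is screened with a multivariate Cox model of overall survival on
10·β — so one coefficient unit is a 10% DNAm difference — adjusted for
clinical trial and disease type as dummy-coded factors, with Efron handling
of ties (the default of the survival package; Breslow available behind a
flag) and two-sided Wald p-values. Constant covariate columns are dropped
with a warning; non-convergent fits are flagged, never silently removed.
Survival-CpG selection (HR > 1, p < 0.01) deliberately applies **no**
multiple-testing correction — the screen is a candidate generator, not an
inference — and says so in a message; BH q-values are printed alongside in
the screen table for transparency. `cox_on_prediction()` applies the same
model to predicted culture time, unscaled, so its HR reads per predicted
day.

`split_cohorts()` performs stratified randomization: patients are
cross-classified by the requested columns (numeric columns binned into
tertiles — the natural default when no binning rule is prescribed),
identification counts are allocated proportionally per stratum with
largest-remainder rounding and a seeded lottery for ties, and strata
smaller than 2 are merged into the largest stratum with a warning. This
guarantees exact total sizes (e.g. 82/32 from 114) with per-stratum
deviation at most one patient.

`km_stratify()` uses empirical quantiles with ties assigned to the lower
group; for the low/high dichotomy the median is the default cut, exposed as
an option since no canonical cut exists. Toxicity contrasts (CRS/ICANS) use
the pooled-variance Student t-test, two-sided.

### Read-level coherence

If drift were driven by a processive epigenetic writer, neighbouring CpGs
on one DNA strand would switch together. `within_read_coherence()`
formalizes the alternative: for every CpG pair in an amplicon it computes
the phi coefficient of the read-level 2×2 table (phi is bounded, signed,
closed-form, and for binary data equals Pearson correlation; mutual
information was considered and rejected as unsigned and unbounded).
Pairwise-complete reads are used per pair rather than dropping any read
with a missing call, preserving power at amplicon ends. The summary is the
mean |phi|; its null is built by independently permuting each CpG column
across reads — preserving every marginal methylation level while destroying
within-read linkage — with the add-one convention
p = (1 + #{null ≥ obs}) / (1 + B), B = 1000 by default, so p is never
exactly zero. Constant CpG columns contribute phi = 0 by convention and are
flagged.

## The synthetic cohort generator

The generator is the package's test bed and defines the conditions under
which every recovery claim is made. Its defaults are fixed to one coherent
study design:

| parameter | default | rationale |
|---|---|---|
| array size | 20,000 CpGs | large enough for realistic multiplicity, small enough for desk-scale runs |
| drift CpGs | 300 hyper + 3 hypo, 0.01 β/day | a few hundred near-linear gainers and a handful of losers, slope chosen so the 22-day course spans ~0.22 β |
| time course | days {0, 8, 15, 22} × 10 donors | a three-week expansion sampled at four points |
| assay noise | Gaussian, sd 0.02 β | typical EPIC-array technical scatter |
| age CpGs | 100 at 0.001 β/year (age centred at 40) | weak donor-age confounders for the exclusion step |
| composition CpGs | 100 at Δβ = 0.2; CD4 fraction 0.6 → 0.4 over 22 d | the declining CD4/CD8 ratio as a confounder |
| clinical arm | 114 patients, three trials with nominal days {9.5, 8.5, 14}, patient-intrinsic drift offset δ ~ N(0, 2 d) | three-trial structure with consistent within-trial culture time, so survival signal rides on intrinsic variation |
| hazard | 14 hazard CpGs ⊂ drift set, log-HR 0.4 per 10% DNAm, exponential baseline log(2)/365 per day, 30% censoring | a planted loss-of-potential effect with a ~1-year median-survival scale |

Noise is additive Gaussian with clipping to [0, 1] rather than
logit-normal: it is simple, bounded, and matches near-linear β
trajectories; the price is a small compression bias near 0 and 1, which is
why planted baselines are drawn away from the boundaries. Event times are
exponential — Cox estimation is invariant to baseline-hazard shape, and the
test suite confirms the same coefficient is recovered from a Weibull
generator. The Cox linear predictor is mean-centred before times are
drawn; hazard *ratios* are unaffected and event times stay on a realistic
scale regardless of how many hazard CpGs are planted. Censoring is
administrative at the empirical (1 − censor_rate) quantile of the drawn
event times, which hits the requested censor fraction exactly. CRS/ICANS
flags are drawn with log-odds decreasing in true culture-equivalent time
(−0.4 per day), mirroring the direction of the observed
toxicity–prediction association.

What the generator does **not** emulate: array chemistry (M/U intensities,
detection p-values), batch effects, genotype artifacts, non-linear or
saturating drift, correlated noise between neighbouring probes, informative
censoring, and competing risks. Passing recovery tests therefore
demonstrate that the estimators are correct and calibrated under the stated
generative model — not that real cohorts satisfy that model.

## Validation scale and reproducibility

The shipped acceptance checks run the screen at full array scale (20,000
CpGs × 40 samples, 20 replicate seeds), train/test the clock on a 40/20
donor-level split, calibrate the Cox screen on 50 null cohorts of n = 200
(2,000 null p-values) and 50 planted-hazard cohorts of n = 300, push 50
clinical cohorts of n = 200 through the full clock → Cox pipeline, sweep a
21-point mixture grid for the deconvolution, and calibrate the coherence
permutation test on 50 independent-read simulations of 1000 reads — sizes
chosen to keep the whole suite in the low minutes on a single core while
leaving Monte-Carlo error well below the asserted margins. Every simulator
takes an explicit seed and is bit-reproducible; `scripts/acceptance.R`
derives all of its seeds from one `--seed` argument.

## Known limitations

- The per-CpG screen treats repeated samples of one donor as independent
  observations, as the underlying study design does; donor random effects
  would be the next refinement.
- Probe filtering relies on the caller's annotation being current;
  cross-reactivity lists in particular vary between publications.
- The composition filter removes cell-type CpGs globally; it cannot rescue
  a CpG that is both composition- and culture-responsive.
- The survival selection is intentionally uncorrected for multiplicity and
  should be read as hypothesis generation; downstream validation cohorts
  are the guard against false positives.
- The deconvolution ships with a two-cell-type synthetic reference for
  demonstration; real analyses should supply a purified-cell reference of
  matching platform.
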