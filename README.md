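# driftclock

Culture expansion of therapeutic T cells — including CAR T-cell products —
leaves a reproducible mark on the DNA methylome: a set of CpG sites gains
(or, rarely, loses) methylation almost linearly with time in culture, while
neighbouring CpGs on the same DNA strand are modified independently of each
other, the signature of stochastic *epigenetic drift* rather than directed
regulation. Because the drift is linear in time, a small panel of CpGs can
be turned into an *epigenetic clock* for days in culture; and because the
same drift tracks a loss of therapeutic potential, methylation at a subset
of these CpGs is prognostic for patient survival after infusion.

`driftclock` implements that analysis end to end for users who start from
preprocessed beta matrices (CpGs × samples, β ∈ [0, 1]):

- **Probe and composition filtering** — exclude SNP-overlapping (MAF > 1%),
  X/Y and cross-reactive probes, plus CpGs differentially methylated between
  CD4⁺ and CD8⁺ T cells (|Δβ| > 0.10 **or** BH-adjusted p < 0.05, limma
  moderated t), so a shifting CD4/CD8 ratio cannot masquerade as drift.
- **Reference-based deconvolution** — cell-type fractions by constrained
  least squares (`f ≥ 0`, `Σf = 1`), as a QC check on composition.
- **Drift screen** — per-CpG Pearson correlation of β with days in culture;
  candidates at `r > 0.9` / `r < −0.9` (strict); exclusion of CpGs that
  correlate with donor age (|r| > 0.3) in an independent blood reference;
  day-0 vs day-22 differential methylation (|Δβ| > 0.20 **and** adjusted
  p < 0.05).
- **Epigenetic clocks** — elastic net (α = 0.5) or ridge (α = 0) regression
  of days in culture on candidate β values, λ by 10-fold day-stratified
  cross-validation (glmnet), with JSON serialization, `tidy()`/`glance()`
  methods and prediction.
- **Survival analysis** — per-CpG multivariate Cox screens (HR per 10% DNAm,
  adjusted for clinical trial and disease, Efron ties, Wald p), selection of
  survival CpGs (HR > 1, p < 0.01), Cox on predicted culture time (HR per
  predicted day), stratified identification/validation cohort splits,
  Kaplan–Meier quartile or median stratification with log-rank tests, and
  pooled t-tests of predictions between CRS/ICANS toxicity groups.
- **Read-level coherence** — for bisulfite amplicon data, per-read pairwise
  phi coefficients with a column-permutation null, quantifying whether
  neighbouring CpGs are modified coherently (writer-driven) or independently
  (drift).
- **Synthetic cohorts** — a generator that plants drift, age, composition
  and hazard effects with full ground truth, so every stage above is
  validated by recovery tests.

## Worked example

```r
library(driftclock)

cfg   <- sim_config(n_cpgs = 5000, n_drift_hyper = 100, seed = 42)
sim   <- simulate_culture_cohort(cfg)            # 4 timepoints x 10 donors
scr   <- drift_screen(sim$beta, sim$sheet$days_in_culture)
clock <- train_penalized_clock(sim$beta[scr$final, ],
                               sim$sheet$days_in_culture,
                               alpha = 0.5, seed = 1)
clock
#> Epigenetic clock: 92 CpG(s), alpha = 0.5, lambda = 0.4681
#>   intercept -17.823 days; training r2 1.000 (n = 40)

clin <- simulate_clinical_cohort(cfg, clock = clock)   # 114 patients
cox_on_prediction(clin$sheet$predicted_days, clin$sheet)
#> # A tibble: 1 x 8
#>    coef    hr ci_low ci_high  p_value     n n_events converged
#>   <dbl> <dbl>  <dbl>   <dbl>    <dbl> <int>    <dbl> <lgl>
#> 1 0.714  2.04   1.71    2.45 8.28e-15   114       80 TRUE
```

The screen finds 100 hypermethylating and 3 hypomethylating CpGs (exactly
the planted set), the cross-validated elastic net keeps 92 of them, and the
Cox model on predicted culture time estimates a hazard ratio of 2.04 per
predicted day (95% CI 1.71–2.45): in this simulated cohort, each additional
day of culture-equivalent drift roughly doubles the death hazard, which is
the planted effect. `km_stratify()` with a median split and
`autoplot()` give the corresponding Kaplan–Meier view (log-rank
p = 5.8e-16 here).

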