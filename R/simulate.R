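#' Configuration for the synthetic methylation cohort generator
#'
#' Bundles every knob of the generator with defaults fixed to the study
#' conditions the pipeline is validated under: a culture time course of
#' 4 timepoints (days 0/8/15/22) x 10 donors on a 20,000-CpG array with
#' 300 hypermethylating and 3 hypomethylating drift CpGs gaining/losing
#' 0.01 beta per day, assay noise sd 0.02 on the beta scale, 100
#' donor-age-associated CpGs and 100 CD4/CD8-composition-confounded CpGs.
#' The clinical arm plants a survival hazard on a subset of the drift CpGs.
#'
#' @param n_cpgs total CpGs on the synthetic array.
#' @param timepoints culture days sampled per donor.
#' @param n_donors donors in the culture time course.
#' @param n_drift_hyper,n_drift_hypo planted drift CpG counts.
#' @param drift_slope methylation gain per day of culture (beta/day) at
#'   hyper-drift CpGs; hypo-drift CpGs use its negative.
#' @param drift_baseline_hyper,drift_baseline_hypo uniform baseline range for
#'   drift CpGs, chosen so the full time course stays inside (0,1).
#' @param n_age_cpgs,age_slope planted donor-age CpGs and their slope in
#'   beta per year (applied to age centred at 40 years).
#' @param n_comp_cpgs,comp_delta planted CD4/CD8 composition CpGs and the
#'   beta difference between the two cell types.
#' @param comp_trajectory function day -> CD4 fraction; default declines
#'   linearly from 0.6 at day 0 to 0.4 at day 22, mirroring the falling
#'   CD4/CD8 ratio during expansion.
#' @param noise_sd sd of additive Gaussian noise on beta (clipped to \[0,1\]).
#' @param baseline_shape shape parameters of the bimodal Beta distribution
#'   baseline betas are drawn from at unplanted CpGs.
#' @param survival list of clinical-arm parameters: `n_patients`,
#'   `n_hazard_cpgs` (taken from the hyper-drift set), `log_hr_per_10pct`,
#'   `baseline_hazard` (events/day), `censor_rate`, `trial_nominal_days`
#'   (named vector of per-trial nominal culture days), `trial_effects` and
#'   `disease_effects` (named log-hazard offsets), `delta_sd` (sd in days of
#'   the patient-intrinsic drift offset), `tox_log_or_per_day` (log odds of
#'   CRS/ICANS per day of true culture-equivalent time).
#' @param seed integer; identical config + seed gives bit-identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cpgs = 20000L,
                       timepoints = c(0, 8, 15, 22),
                       n_donors = 10L,
                       n_drift_hyper = 300L,
                       n_drift_hypo = 3L,
                       drift_slope = 0.01,
                       drift_baseline_hyper = c(0.10, 0.35),
                       drift_baseline_hypo = c(0.65, 0.90),
                       n_age_cpgs = 100L,
                       age_slope = 0.001,
                       n_comp_cpgs = 100L,
                       comp_delta = 0.2,
                       comp_trajectory = function(day) 0.6 - 0.2 * pmin(day, 22) / 22,
                       noise_sd = 0.02,
                       baseline_shape = c(0.4, 0.4),
                       survival = list(),
                       seed = 1L) {
  surv_default <- list(
    n_patients = 114L,
    n_hazard_cpgs = 14L,
    log_hr_per_10pct = 0.4,
    baseline_hazard = log(2) / 365,
    censor_rate = 0.3,
    trial_nominal_days = c(trialA = 9.5, trialB = 8.5, trialC = 14),
    trial_weights = c(trialA = 43, trialB = 45, trialC = 26),
    trial_effects = c(trialA = 0, trialB = 0.2, trialC = -0.1),
    disease_effects = c(ALL = 0, NHL = 0.15),
    delta_sd = 2,
    tox_log_or_per_day = -0.4
  )
  survival <- utils::modifyList(surv_default, survival)
  cfg <- list(
    n_cpgs = as.integer(n_cpgs), timepoints = timepoints,
    n_donors = as.integer(n_donors),
    n_drift_hyper = as.integer(n_drift_hyper),
    n_drift_hypo = as.integer(n_drift_hypo),
    drift_slope = drift_slope,
    drift_baseline_hyper = drift_baseline_hyper,
    drift_baseline_hypo = drift_baseline_hypo,
    n_age_cpgs = as.integer(n_age_cpgs), age_slope = age_slope,
    n_comp_cpgs = as.integer(n_comp_cpgs), comp_delta = comp_delta,
    comp_trajectory = comp_trajectory,
    noise_sd = noise_sd, baseline_shape = baseline_shape,
    survival = survival, seed = as.integer(seed)
  )
  n_planted <- cfg$n_drift_hyper + cfg$n_drift_hypo + cfg$n_age_cpgs + cfg$n_comp_cpgs
  if (n_planted > cfg$n_cpgs) stop("planted CpG counts exceed n_cpgs", call. = FALSE)
  if (max(drift_baseline_hyper) + drift_slope * max(timepoints) > 0.99 ||
      min(drift_baseline_hypo) - drift_slope * max(timepoints) < 0.01) {
    stop("drift trajectory leaves (0,1): adjust baselines or slope", call. = FALSE)
  }
  if (survival$censor_rate < 0 || survival$censor_rate >= 1) {
    stop("censor_rate must be in [0, 1)", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# CpG id layout shared by both simulators: hyper drift first, then hypo,
# then age, then composition, then nulls; age/comp sets disjoint from drift.
planted_sets <- function(cfg) {
  ids <- sprintf("cg%07d", seq_len(cfg$n_cpgs))
  i <- 0L
  take <- function(n) {
    out <- ids[i + seq_len(n)]
    i <<- i + n
    out
  }
  list(ids = ids,
       hyper = take(cfg$n_drift_hyper),
       hypo = take(cfg$n_drift_hypo),
       age = take(cfg$n_age_cpgs),
       comp = take(cfg$n_comp_cpgs))
}

# Baselines per CpG: bimodal Beta for nulls, uniform mid-ranges for planted
# CpGs so drift never clips.
draw_baselines <- function(cfg, sets) {
  n <- cfg$n_cpgs
  base <- stats::rbeta(n, cfg$baseline_shape[1], cfg$baseline_shape[2])
  names(base) <- sets$ids
  base[sets$hyper] <- stats::runif(length(sets$hyper),
                                   cfg$drift_baseline_hyper[1],
                                   cfg$drift_baseline_hyper[2])
  base[sets$hypo] <- stats::runif(length(sets$hypo),
                                  cfg$drift_baseline_hypo[1],
                                  cfg$drift_baseline_hypo[2])
  base[sets$age] <- stats::runif(length(sets$age), 0.30, 0.60)
  base[sets$comp] <- stats::runif(length(sets$comp), 0.15, 0.60)
  base
}

# Systematic part of beta for a vector of samples with given day/age, as an
# n_cpgs x n_samples matrix (before noise and clipping).
beta_signal <- function(cfg, sets, base, days, ages) {
  n_s <- length(days)
  vals <- matrix(base, nrow = cfg$n_cpgs, ncol = n_s,
                 dimnames = list(sets$ids, NULL))
  slopes <- numeric(cfg$n_cpgs)
  names(slopes) <- sets$ids
  slopes[sets$hyper] <- cfg$drift_slope
  slopes[sets$hypo] <- -cfg$drift_slope
  vals <- vals + outer(slopes, days)
  if (length(sets$age)) {
    age_term <- outer(rep(cfg$age_slope, length(sets$age)), ages - 40)
    vals[sets$age, ] <- vals[sets$age, , drop = FALSE] + age_term
  }
  if (length(sets$comp)) {
    comp_shift <- cfg$comp_delta * (cfg$comp_trajectory(days) - cfg$comp_trajectory(0))
    vals[sets$comp, ] <- vals[sets$comp, , drop = FALSE] +
      matrix(comp_shift, nrow = length(sets$comp), ncol = n_s, byrow = TRUE)
  }
  vals
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Simulate a culture-expansion time course
#'
#' Generates a beta matrix, sample sheet and ground truth for a longitudinal
#' T-cell expansion: every donor contributes one sample per timepoint and
#' beta follows `clip(baseline + slope * day + age_term + comp_term + noise)`
#' with planted drift, donor-age and CD4/CD8-composition CpGs.
#'
#' @param config a [sim_config()].
#' @return list with `beta` (matrix CpGs x samples), `sheet` (sample sheet
#'   tibble with true days and ages) and `truth` (planted CpG identities,
#'   per-sample true days and CD4 fractions).
#' @export
simulate_culture_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    sets <- planted_sets(config)
    base <- draw_baselines(config, sets)
    n_tp <- length(config$timepoints)
    days <- rep(config$timepoints, times = config$n_donors)
    donor <- rep(sprintf("D%02d", seq_len(config$n_donors)), each = n_tp)
    ages_by_donor <- stats::runif(config$n_donors, 20, 60)
    ages <- rep(ages_by_donor, each = n_tp)
    condition <- rep(ifelse(seq_len(config$n_donors) %% 2 == 0, "CAR", "UT"),
                     each = n_tp)
    sample_ids <- sprintf("%s_d%02d", donor, days)
    vals <- beta_signal(config, sets, base, days, ages)
    if (config$noise_sd > 0) {
      vals <- vals + stats::rnorm(length(vals), 0, config$noise_sd)
    }
    vals <- clip01(vals)
    colnames(vals) <- sample_ids
    sheet <- validate_sample_sheet(tibble::tibble(
      sample_id = sample_ids, donor_id = donor, condition = condition,
      days_in_culture = days, age = ages
    ))
    truth <- list(
      drift_hyper_ids = sets$hyper, drift_hypo_ids = sets$hypo,
      age_cpg_ids = sets$age, comp_cpg_ids = sets$comp,
      baselines = base, true_days = stats::setNames(days, sample_ids),
      true_cd4_fraction = stats::setNames(config$comp_trajectory(days), sample_ids)
    )
    list(beta = beta_matrix(vals), sheet = sheet, truth = truth)
  })
}

#' Simulate a clinical CAR T-cell cohort with survival outcomes
#'
#' Each patient receives a product whose methylation reflects a trial-specific
#' nominal culture time plus a patient-intrinsic drift offset
#' `delta_i ~ N(0, delta_sd)`. The death hazard is log-linear in beta at the
#' planted hazard CpGs (a subset of the hyper-drift set), plus trial and
#' disease offsets: `h_i = h0 * exp(sum_j b_j * 10 * beta_ij + trial + disease)`
#' with `b_j` the log hazard ratio per 10% DNAm. Event times are exponential
#' (the Cox screen is invariant to baseline hazard shape); censoring is
#' administrative at the empirical `1 - censor_rate` quantile of the drawn
#' event times. The linear predictor is mean-centred before drawing times,
#' which leaves all hazard ratios untouched and keeps event times on a
#' realistic day scale. CRS/ICANS flags are drawn with log-odds decreasing in
#' true culture-equivalent time, mirroring the observed association of
#' toxicity with shorter predicted culture.
#'
#' @param config a [sim_config()] whose `survival` block is used.
#' @param clock optional [train_penalized_clock()] model; when supplied, a
#'   `predicted_days` column is added to the sheet.
#' @return list with `beta`, `sheet` (os_time/os_event/trial/disease/CRS/
#'   ICANS filled) and `truth` (hazard CpGs with true log-HRs, per-patient
#'   true culture-equivalent days and intrinsic offsets).
#' @export
simulate_clinical_cohort <- function(config, clock = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sv <- config$survival
  withr::with_seed(config$seed + 1L, {
    sets <- planted_sets(config)
    base <- draw_baselines(config, sets)
    n <- sv$n_patients
    trials <- names(sv$trial_nominal_days)
    trial <- sample(trials, n, replace = TRUE,
                    prob = sv$trial_weights[trials] / sum(sv$trial_weights[trials]))
    disease <- sample(names(sv$disease_effects), n, replace = TRUE)
    ages <- stats::runif(n, 20, 70)
    delta <- stats::rnorm(n, 0, sv$delta_sd)
    true_day <- as.numeric(sv$trial_nominal_days[trial]) + delta
    true_day <- pmax(true_day, 0)
    sample_ids <- sprintf("P%03d", seq_len(n))
    vals <- beta_signal(config, sets, base, true_day, ages)
    if (config$noise_sd > 0) {
      vals <- vals + stats::rnorm(length(vals), 0, config$noise_sd)
    }
    vals <- clip01(vals)
    colnames(vals) <- sample_ids

    n_hz <- min(sv$n_hazard_cpgs, length(sets$hyper))
    hazard_ids <- sets$hyper[seq_len(n_hz)]
    b <- rep(sv$log_hr_per_10pct, n_hz)
    lp <- drop(crossprod(vals[hazard_ids, , drop = FALSE] * 10, b)) +
      as.numeric(sv$trial_effects[trial]) +
      as.numeric(sv$disease_effects[disease])
    lp <- lp - mean(lp)
    event_time <- stats::rexp(n, rate = sv$baseline_hazard * exp(lp))
    cens_time <- stats::quantile(event_time, 1 - sv$censor_rate, names = FALSE)
    os_time <- pmin(event_time, cens_time)
    os_event <- as.numeric(event_time <= cens_time)
    os_time <- pmax(os_time, 1e-6)

    tox_lp <- sv$tox_log_or_per_day * (true_day - mean(true_day))
    crs <- stats::rbinom(n, 1, stats::plogis(tox_lp - 0.5))
    icans <- stats::rbinom(n, 1, stats::plogis(tox_lp - 1))

    sheet <- tibble::tibble(
      sample_id = sample_ids, trial = trial, disease = disease, age = ages,
      os_time = os_time, os_event = os_event, crs = crs, icans = icans
    )
    beta <- beta_matrix(vals)
    if (!is.null(clock)) {
      sheet <- dplyr::left_join(sheet, predict_days(clock, beta), by = "sample_id")
    }
    truth <- list(
      hazard_cpg_ids = hazard_ids,
      hazard_log_hr = stats::setNames(b, hazard_ids),
      drift_hyper_ids = sets$hyper, drift_hypo_ids = sets$hypo,
      true_days = stats::setNames(true_day, sample_ids),
      delta = stats::setNames(delta, sample_ids),
      linear_predictor = stats::setNames(lp, sample_ids)
    )
    list(beta = beta, sheet = validate_sample_sheet(sheet), truth = truth)
  })
}

#' Simulate per-read bisulfite amplicon calls
#'
#' Draws binary methylation calls for `n_reads` reads over the CpGs of one
#' amplicon. With probability `coherence` a read follows the comonotone model
#' (one latent uniform `u` per read; CpG `i` methylated iff `u < m_i`), which
#' maximises within-read coherence at fixed marginals; otherwise each CpG is
#' an independent `Bernoulli(m_i)`. Either way every CpG's marginal mean is
#' `m_i`, so `coherence` tunes read-level linkage without moving the bulk
#' methylation level.
#'
#' @param mean_levels named numeric vector of per-CpG beta values in \[0,1\];
#'   names (or positions 1..k) become CpG coordinates.
#' @param n_reads number of reads (default 1000, the typical per-amplicon
#'   coverage of barcoded bisulfite amplicon sequencing).
#' @param coherence probability a read is comonotone, in \[0,1\].
#' @param seed integer seed.
#' @param amplicon_id,sample_id identifiers stored in the result.
#' @return a [read_set()].
#' @export
simulate_reads <- function(mean_levels, n_reads = 1000L, coherence = 0,
                           seed = 1L, amplicon_id = "amplicon",
                           sample_id = "sample") {
  if (any(mean_levels < 0 | mean_levels > 1)) {
    stop("mean_levels must lie in [0,1]", call. = FALSE)
  }
  if (coherence < 0 || coherence > 1) stop("coherence must be in [0,1]", call. = FALSE)
  if (n_reads < 1) stop("n_reads must be >= 1", call. = FALSE)
  k <- length(mean_levels)
  pos <- names(mean_levels)
  if (is.null(pos)) pos <- as.character(seq_len(k))
  withr::with_seed(seed, {
    comono <- stats::runif(n_reads) < coherence
    u <- stats::runif(n_reads)
    calls <- matrix(0L, n_reads, k, dimnames = list(NULL, pos))
    for (j in seq_len(k)) {
      indep <- stats::rbinom(n_reads, 1L, mean_levels[j])
      calls[, j] <- ifelse(comono, as.integer(u < mean_levels[j]), indep)
    }
    read_set(calls, positions = as.numeric(pos), amplicon_id = amplicon_id,
             sample_id = sample_id)
  })
}
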