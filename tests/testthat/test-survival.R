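toy_surv <- function() {
  # 5 patients, one tied event time to exercise the Efron correction
  tibble::tibble(
    sample_id = paste0("p", 1:5),
    os_time = c(5, 5, 8, 11, 14),
    os_event = c(1, 1, 1, 0, 1)
  )
}

test_that("Cox coefficients match the grid-maximised Efron partial likelihood", {
  surv <- toy_surv()
  x <- c(0.9, 0.7, 0.4, 0.3, 0.1)
  beta <- make_beta(matrix(x, 1, 5), cpgs = "cg1", samples = surv$sample_id)
  tab <- cox_screen_cpgs(beta, surv)
  # the screen scales beta by 10, so compare on the scaled covariate
  oracle <- efron_mle(10 * x, surv$os_time, surv$os_event)
  expect_equal(tab$coef, oracle, tolerance = 1e-4)
  expect_true(tab$converged)
  expect_equal(tab$hr, exp(tab$coef))
  expect_true(tab$ci_low < tab$hr && tab$hr < tab$ci_high)
})

test_that("screen plus selection equals a brute-force per-CpG loop", {
  clin <- simulate_clinical_cohort(small_config(seed = 33L,
                                                survival = list(n_patients = 80L)))
  beta <- clin$beta[1:30, ]
  tab <- cox_screen_cpgs(beta, clin$sheet)
  expect_equal(nrow(tab), 30L)
  df <- data.frame(os_time = clin$sheet$os_time, os_event = clin$sheet$os_event,
                   trial = factor(clin$sheet$trial),
                   disease = factor(clin$sheet$disease))
  for (i in c(1, 7, 30)) {
    df$x <- 10 * beta[i, ]
    fit <- survival::coxph(survival::Surv(os_time, os_event) ~ x + trial + disease,
                           data = df, ties = "efron")
    expect_equal(tab$coef[i], unname(stats::coef(fit)["x"]), tolerance = 1e-10)
    expect_equal(tab$p_value[i],
                 unname(2 * stats::pnorm(abs(stats::coef(fit)["x"] /
                                               sqrt(diag(fit$var))[1]),
                                         lower.tail = FALSE)),
                 tolerance = 1e-10)
  }
  suppressMessages({
    sel <- select_survival_cpgs(tab)
    brute <- tab$cpg_id[tab$hr > 1 & tab$p_value < 0.01]
  })
  expect_setequal(sel, brute)
})

test_that("survival CpG selection filters on direction and p", {
  tab <- tibble::tibble(
    cpg_id = c("up_sig", "down_sig", "up_ns"),
    coef = c(log(1.2), log(0.8), log(1.5)),
    hr = c(1.2, 0.8, 1.5), ci_low = NA, ci_high = NA,
    p_value = c(0.005, 0.001, 0.2), converged = TRUE, q_bh = NA
  )
  expect_message(sel <- select_survival_cpgs(tab), "unadjusted")
  expect_identical(sel, "up_sig")
})

test_that("cox_on_prediction is affine-equivariant and null-safe", {
  clin <- simulate_clinical_cohort(small_config(
    seed = 44L,
    survival = list(log_hr_per_10pct = 0, n_patients = 120L)
  ))
  set.seed(1)
  noise_pred <- stats::setNames(rnorm(120, 10, 2), clin$sheet$sample_id)
  res <- cox_on_prediction(noise_pred, clin$sheet)
  expect_true(res$ci_low < 1 && 1 < res$ci_high)

  clin2 <- simulate_clinical_cohort(small_config(seed = 45L))
  pred_days <- clin2$truth$true_days
  r1 <- cox_on_prediction(pred_days, clin2$sheet)
  r2 <- cox_on_prediction(pred_days * 24, clin2$sheet)   # in hours
  expect_equal(r2$coef, r1$coef / 24, tolerance = 1e-6)
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-6)
})

test_that("cohort split hits exact sizes with per-stratum balance and determinism", {
  clin <- simulate_clinical_cohort(small_config(seed = 46L))
  sheet <- clin$sheet
  expect_equal(nrow(sheet), 114L)
  suppressWarnings(  # a 1-patient stratum is merged by design
    split1 <- split_cohorts(sheet, 82L, 32L, strata = c("trial", "disease"),
                            seed = 9L)
  )
  expect_equal(sum(split1$cohort == "identification"), 82L)
  expect_equal(sum(split1$cohort == "validation"), 32L)
  # per-stratum proportions within +/- 1 patient of the 82/114 share
  lab <- paste(split1$trial, split1$disease)
  for (st in unique(lab)) {
    in_st <- lab == st
    expected <- sum(in_st) * 82 / 114
    expect_lte(abs(sum(split1$cohort[in_st] == "identification") - expected), 1 + 1e-9)
  }
  suppressWarnings(
    split2 <- split_cohorts(sheet, 82L, 32L, strata = c("trial", "disease"),
                            seed = 9L)
  )
  expect_identical(split1$cohort, split2$cohort)
  suppressWarnings(
    split3 <- split_cohorts(sheet, 82L, 32L,
                            strata = c("trial", "disease", "age"), seed = 10L)
  )
  expect_false(identical(split1$cohort, split3$cohort))
  expect_equal(sum(split3$cohort == "identification"), 82L)
  expect_equal(sum(split3$cohort == "validation"), 32L)

  simple <- split_cohorts(sheet, 60L, 40L, strata = NULL, seed = 2L)
  expect_equal(table(simple$cohort)[["identification"]], 60L)
  expect_equal(table(simple$cohort)[["unassigned"]], 14L)
  expect_error(split_cohorts(sheet, 100L, 100L), "exceed")
})

test_that("Kaplan-Meier estimator steps 1/n at distinct uncensored events", {
  surv <- tibble::tibble(sample_id = paste0("p", 1:8),
                         os_time = c(1, 2, 3, 4, 5, 6, 7, 8) * 10,
                         os_event = 1)
  km <- km_stratify(stats::setNames(c(1:4, 101:104), surv$sample_id), surv,
                    mode = "median")
  low <- km$curves[km$curves$group == "low", ]
  expect_equal(low$survival, c(0.75, 0.5, 0.25, 0), tolerance = 1e-12)
  expect_true(all(diff(km$curves$survival[km$curves$group == "high"]) <= 0))
})

test_that("log-rank separates extreme groups and is null for identical groups", {
  surv <- tibble::tibble(
    sample_id = paste0("p", 1:40),
    os_time = c(rep(1, 20), rep(100, 20)),
    os_event = c(rep(1, 20), rep(0, 20))
  )
  score <- c(rep(10, 20), rep(1, 20))  # high score group dies at t = 1
  km <- km_stratify(stats::setNames(score, surv$sample_id), surv, mode = "median")
  expect_lt(km$logrank_p, 0.001)

  # two groups with identical survival experience -> chi-square ~ 0
  surv2 <- tibble::tibble(
    sample_id = paste0("q", 1:40),
    os_time = rep(c(3, 6, 9, 12, 15), 8),
    os_event = rep(c(1, 1, 0, 1, 0), 8)
  )
  score2 <- rep(c(1, 2), each = 20)[order(rep(1:20, 2))]  # interleaved
  score2 <- c(rep(1, 20), rep(2, 20))
  km2 <- km_stratify(stats::setNames(score2 + 0.0, surv2$sample_id), surv2,
                     mode = "median")
  expect_gt(km2$logrank_p, 0.9)
})

test_that("quartile stratification needs 8 patients and handles ties", {
  surv <- tibble::tibble(sample_id = paste0("p", 1:6), os_time = 1:6,
                         os_event = 1)
  expect_error(km_stratify(stats::setNames(1:6, surv$sample_id), surv), ">= 8")
})

test_that("toxicity comparison matches the pooled t-test by hand", {
  g0 <- c(10, 11, 12)
  g1 <- c(8, 9, 10)
  res <- compare_toxicity_groups(c(g0, g1), c(0, 0, 0, 1, 1, 1))
  sp2 <- (2 * stats::var(g0) + 2 * stats::var(g1)) / 4
  t_hand <- (mean(g1) - mean(g0)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 4)

  ident <- compare_toxicity_groups(c(g0, g0), c(0, 0, 0, 1, 1, 1))
  expect_equal(ident$p_value, 1, tolerance = 1e-12)

  set.seed(6)
  big0 <- rnorm(20, 11, 1)
  big1 <- rnorm(20, 9, 1)
  res2 <- compare_toxicity_groups(c(big0, big1), rep(c(0, 1), each = 20))
  expect_lt(res2$p_value, 0.001)
  expect_error(compare_toxicity_groups(c(1, 2, 3), c(0, 0, 1)), ">= 2")
})

test_that("a planted per-CpG hazard is recovered without material bias", {
  coefs <- numeric(50)
  covered <- logical(50)
  for (s in 1:50) {
    cfg <- sim_config(n_cpgs = 400L, n_drift_hyper = 20L, n_drift_hypo = 0L,
                      n_age_cpgs = 0L, n_comp_cpgs = 0L,
                      survival = list(n_patients = 300L, n_hazard_cpgs = 1L,
                                      log_hr_per_10pct = 0.4),
                      seed = 8200L + s)
    clin <- simulate_clinical_cohort(cfg)
    tab <- cox_screen_cpgs(clin$beta[clin$truth$hazard_cpg_ids, , drop = FALSE],
                           clin$sheet)
    coefs[s] <- tab$coef
    covered[s] <- tab$ci_low <= exp(0.4) && exp(0.4) <= tab$ci_high
  }
  # geometric mean HR (exp of the mean log-HR) within 5% of the truth
  expect_lt(abs(exp(mean(coefs)) - exp(0.4)), 0.05 * exp(0.4))
  expect_gte(mean(covered), 0.9)
})

test_that("Cox estimates are invariant to the baseline hazard shape", {
  # same linear predictor, exponential vs Weibull event times
  set.seed(77)
  n <- 800L
  x <- runif(n, 0, 1)
  lp <- 0.8 * x
  surv_from_times <- function(tt) {
    cens <- stats::quantile(tt, 0.7, names = FALSE)
    tibble::tibble(sample_id = sprintf("p%03d", 1:n),
                   os_time = pmin(tt, cens), os_event = as.numeric(tt <= cens))
  }
  t_exp <- rexp(n, rate = 0.01 * exp(lp))
  u <- runif(n)
  shape <- 1.5
  t_wei <- (-log(u) / (0.001 * exp(lp)))^(1 / shape)
  beta1 <- make_beta(matrix(x / 10, 1, n), cpgs = "cg1",
                     samples = sprintf("p%03d", 1:n))
  c_exp <- cox_screen_cpgs(beta1, surv_from_times(t_exp))$coef
  c_wei <- cox_screen_cpgs(beta1, surv_from_times(t_wei))$coef
  expect_equal(c_exp, 0.8, tolerance = 0.35)
  expect_equal(c_wei, 0.8, tolerance = 0.35)
})
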