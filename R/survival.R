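#' Validate per-patient survival data
#'
#' @param surv data frame with `sample_id`, `os_time` (> 0, days),
#'   `os_event` (0/1, >= 1 event overall), and optional categorical `trial`
#'   and `disease` covariates.
#' @return validated tibble.
#' @export
validate_survival_data <- function(surv) {
  surv <- tibble::as_tibble(surv)
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, names(surv))
  if (length(miss)) stop("survival data missing: ", paste(miss, collapse = ", "), call. = FALSE)
  surv$os_time <- as.numeric(surv$os_time)
  surv$os_event <- as.numeric(surv$os_event)
  if (any(is.na(surv$os_time)) || any(surv$os_time <= 0)) {
    stop("os_time must be > 0", call. = FALSE)
  }
  if (!all(surv$os_event %in% c(0, 1))) stop("os_event must be 0/1", call. = FALSE)
  if (sum(surv$os_event) < 1) stop("need >= 1 event", call. = FALSE)
  surv
}

# Build the covariate data frame for a Cox fit, dropping constant
# trial/disease columns with a warning (a single-level factor cannot be
# dummy-coded).
cox_covariates <- function(surv) {
  covs <- character()
  for (cc in c("trial", "disease")) {
    if (cc %in% names(surv)) {
      if (length(unique(surv[[cc]])) > 1L) {
        covs <- c(covs, cc)
      } else {
        warning("covariate '", cc, "' is constant and was dropped")
      }
    }
  }
  covs
}

# One Cox fit of Surv(os_time, os_event) ~ x + covariates; returns
# coefficient of x, its SE, Wald p, and a convergence flag.
cox_fit_one <- function(x, surv, covs, ties = "efron") {
  df <- data.frame(x = x, os_time = surv$os_time, os_event = surv$os_event)
  for (cc in covs) df[[cc]] <- factor(surv[[cc]])
  fml <- stats::as.formula(paste(
    "survival::Surv(os_time, os_event) ~ x",
    if (length(covs)) paste("+", paste(covs, collapse = " + ")) else ""
  ))
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = ties),
    warning = function(w) {
      f <- suppressWarnings(survival::coxph(fml, data = df, ties = ties))
      attr(f, "flagged") <- TRUE
      f
    },
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(coef = NA_real_, se = NA_real_, p = NA_real_, converged = FALSE))
  }
  co <- stats::coef(fit)["x"]
  se <- sqrt(diag(fit$var))[1L]
  z <- co / se
  list(coef = unname(co), se = unname(se),
       p = unname(2 * stats::pnorm(abs(z), lower.tail = FALSE)),
       converged = is.null(attr(fit, "flagged")))
}

#' Per-CpG Cox proportional-hazards screen
#'
#' Fits one multivariate Cox model per CpG: overall survival on the CpG's
#' beta (rescaled by x10 so one unit equals a 10% DNAm difference) with
#' `trial` and `disease` as categorical covariates (first level reference),
#' Efron handling of tied event times, two-sided Wald p-values. The reported
#' hazard ratio is therefore per 10% DNAm difference, adjusted for trial and
#' disease. Non-convergent fits are flagged, not dropped. A BH-adjusted
#' q-value column (`q_bh`) is printed alongside for transparency; the
#' selection rule in [select_survival_cpgs()] deliberately does not use it.
#'
#' @param beta beta matrix (CpGs x patients).
#' @param surv survival data (see [validate_survival_data()]); rows matched
#'   to beta columns by `sample_id`.
#' @param ties "efron" (default) or "breslow".
#' @return tibble per CpG: `cpg_id`, `coef` (log HR per 10% DNAm), `hr`,
#'   `ci_low`, `ci_high` (95%), `p_value`, `q_bh`, `converged`.
#' @export
cox_screen_cpgs <- function(beta, surv, ties = c("efron", "breslow")) {
  beta <- beta_matrix(beta)
  surv <- validate_survival_data(surv)
  ties <- match.arg(ties)
  idx <- match(colnames(beta), surv$sample_id)
  if (anyNA(idx)) stop("samples in beta missing from survival data", call. = FALSE)
  surv <- surv[idx, ]
  covs <- cox_covariates(surv)
  rows <- purrr::map(seq_len(nrow(beta)), function(i) {
    f <- cox_fit_one(10 * beta[i, ], surv, covs, ties)
    tibble::tibble(
      cpg_id = rownames(beta)[i], coef = f$coef, hr = exp(f$coef),
      ci_low = exp(f$coef - 1.96 * f$se), ci_high = exp(f$coef + 1.96 * f$se),
      p_value = f$p, converged = isTRUE(f$converged)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$q_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Select survival-associated CpGs from a Cox screen
#'
#' Keeps CpGs with hazard ratio above `hr_min` AND Wald p below `p_max`.
#' The p-values are deliberately not adjusted for multiple testing across
#' the screened CpGs (a message states this); the screen table carries
#' BH q-values for transparency.
#'
#' @param table result of [cox_screen_cpgs()].
#' @param hr_min hazard-ratio floor (default 1, i.e. harmful direction only).
#' @param p_max Wald p ceiling (default 0.01).
#' @return character vector of selected CpG ids.
#' @export
select_survival_cpgs <- function(table, hr_min = 1.0, p_max = 0.01) {
  message("selection uses unadjusted Wald p-values (no multiple-testing ",
          "correction across screened CpGs)")
  ok <- !is.na(table$hr) & !is.na(table$p_value)
  table$cpg_id[ok & table$hr > hr_min & table$p_value < p_max]
}

#' Cox model of survival on predicted culture time
#'
#' Single multivariate Cox fit of overall survival on the clock's predicted
#' days in culture (unscaled: the hazard ratio is per day of predicted
#' culture time), adjusted for trial and disease.
#'
#' @param predicted_days numeric vector of predictions (named by sample id,
#'   or in `surv` row order), or the tibble returned by [predict_days()].
#' @param surv survival data.
#' @param ties "efron" or "breslow".
#' @return one-row tibble: `coef` (log HR per predicted day), `hr`,
#'   `ci_low`, `ci_high`, `p_value`, `n`, `n_events`, `converged`.
#' @export
cox_on_prediction <- function(predicted_days, surv, ties = c("efron", "breslow")) {
  surv <- validate_survival_data(surv)
  if (is.data.frame(predicted_days)) {
    predicted_days <- stats::setNames(predicted_days$predicted_days,
                                      predicted_days$sample_id)
  }
  if (!is.null(names(predicted_days))) {
    predicted_days <- predicted_days[surv$sample_id]
  }
  if (length(predicted_days) != nrow(surv) || anyNA(predicted_days)) {
    stop("predicted_days must cover every patient in surv", call. = FALSE)
  }
  covs <- cox_covariates(surv)
  f <- cox_fit_one(as.numeric(predicted_days), surv, covs, match.arg(ties))
  tibble::tibble(
    coef = f$coef, hr = exp(f$coef),
    ci_low = exp(f$coef - 1.96 * f$se), ci_high = exp(f$coef + 1.96 * f$se),
    p_value = f$p, n = nrow(surv), n_events = sum(surv$os_event),
    converged = isTRUE(f$converged)
  )
}

#' Stratified random split into identification and validation cohorts
#'
#' Randomly assigns patients to an identification and a validation cohort
#' with the requested sizes, balancing the split within strata formed by the
#' cross-classification of the given columns (numeric columns such as age
#' are binned into tertiles). Within each stratum the identification count
#' is the proportional share; fractional remainders are settled by a seeded
#' lottery so the totals are hit exactly. Strata with fewer than 2 patients
#' are merged into the largest stratum with a warning.
#'
#' @param sheet sample sheet.
#' @param n_identification,n_validation cohort sizes
#'   (`n_id + n_val <= n` patients; any surplus stays `unassigned`).
#' @param strata character vector of column names to balance on (NULL for a
#'   simple random split).
#' @param seed integer seed.
#' @return the sheet with `cohort` filled.
#' @export
split_cohorts <- function(sheet, n_identification = 82L, n_validation = 32L,
                          strata = NULL, seed = 1L) {
  sheet <- validate_sample_sheet(sheet)
  n <- nrow(sheet)
  n_id <- as.integer(n_identification)
  n_val <- as.integer(n_validation)
  if (n_id + n_val > n) stop("cohort sizes exceed patient count", call. = FALSE)
  if (is.null(strata) || !length(strata)) {
    lab <- rep("all", n)
  } else {
    miss <- setdiff(strata, names(sheet))
    if (length(miss)) stop("unknown strata column(s): ", paste(miss, collapse = ", "), call. = FALSE)
    parts <- lapply(strata, function(cc) {
      v <- sheet[[cc]]
      if (is.numeric(v)) {
        br <- unique(stats::quantile(v, c(0, 1 / 3, 2 / 3, 1), na.rm = TRUE))
        as.character(cut(v, breaks = br, include.lowest = TRUE))
      } else {
        as.character(v)
      }
    })
    lab <- do.call(paste, c(parts, sep = "|"))
    lab[is.na(lab)] <- "missing"
  }
  tab <- table(lab)
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    warning("merging ", length(small), " stratum/strata with < 2 patients into the largest stratum")
    biggest <- names(tab)[which.max(tab)]
    lab[lab %in% small] <- biggest
  }
  withr::with_seed(seed, {
    strata_ids <- split(seq_len(n), lab)
    total_assigned <- n_id + n_val
    # proportional share of each stratum in the assigned pool, then of the
    # identification cohort within it; remainders by largest-remainder with
    # seeded random tie-breaks
    alloc_counts <- function(sizes, total) {
      raw <- sizes / sum(sizes) * total
      base <- floor(raw)
      rem <- total - sum(base)
      if (rem > 0) {
        frac <- raw - base
        ord <- order(-frac, stats::runif(length(frac)))
        base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
      }
      base
    }
    sizes <- vapply(strata_ids, length, integer(1))
    assigned_per <- alloc_counts(sizes, total_assigned)
    id_per <- alloc_counts(assigned_per, n_id)
    id_per <- pmin(id_per, assigned_per)
    # fix any shortfall caused by the cap
    short <- n_id - sum(id_per)
    if (short > 0) {
      room <- assigned_per - id_per
      ord <- order(-room, stats::runif(length(room)))
      for (k in ord) {
        if (short == 0) break
        add <- min(short, room[k])
        id_per[k] <- id_per[k] + add
        short <- short - add
      }
    }
    cohort <- rep("unassigned", n)
    for (k in seq_along(strata_ids)) {
      ids <- sample(strata_ids[[k]])
      take <- ids[seq_len(assigned_per[k])]
      cohort[take[seq_len(id_per[k])]] <- "identification"
      if (assigned_per[k] > id_per[k]) {
        cohort[take[(id_per[k] + 1L):assigned_per[k]]] <- "validation"
      }
    }
    sheet$cohort <- cohort
  })
  sheet
}

#' Kaplan-Meier stratification of a patient score
#'
#' Groups patients by empirical quantiles of a continuous score (quartiles,
#' or a median low/high split), estimates a Kaplan-Meier curve per group
#' (right-censored), and tests the curves with a log-rank test. Ties at a
#' quantile boundary go to the lower group. Groups emptied by ties are
#' dropped (i.e. merged) with a warning.
#'
#' @param values per-patient score (e.g. predicted days or mean DNAm),
#'   named by sample id or in `surv` row order.
#' @param surv survival data.
#' @param mode "quartiles" (requires >= 8 patients) or "median".
#' @return object of class `km_strata`: `curves` tibble
#'   (`group`, `time`, `n_risk`, `n_event`, `survival`), `logrank_p`,
#'   `groups` (per-patient assignment tibble).
#' @export
km_stratify <- function(values, surv, mode = c("quartiles", "median")) {
  mode <- match.arg(mode)
  surv <- validate_survival_data(surv)
  if (is.data.frame(values)) {
    values <- stats::setNames(values[[2L]], values[[1L]])
  }
  if (!is.null(names(values))) values <- values[surv$sample_id]
  values <- as.numeric(values)
  if (length(values) != nrow(surv) || anyNA(values)) {
    stop("values must cover every patient", call. = FALSE)
  }
  if (mode == "quartiles" && nrow(surv) < 8L) {
    stop("quartile stratification needs >= 8 patients", call. = FALSE)
  }
  probs <- if (mode == "quartiles") c(0.25, 0.5, 0.75) else 0.5
  br <- unique(c(-Inf, stats::quantile(values, probs), Inf))
  labels_all <- if (mode == "quartiles") paste0("Q", seq_len(length(br) - 1L)) else
    c("low", "high")[seq_len(length(br) - 1L)]
  grp <- cut(values, breaks = br, labels = labels_all, right = TRUE)
  n_expected <- if (mode == "quartiles") 4L else 2L
  if (nlevels(droplevels(grp)) < n_expected) {
    warning("tied quantile boundaries left empty group(s); groups merged")
  }
  grp <- droplevels(grp)
  if (nlevels(grp) < 2L) stop("stratification produced a single group", call. = FALSE)
  df <- data.frame(os_time = surv$os_time, os_event = surv$os_event, group = grp)
  sf <- survival::survfit(survival::Surv(os_time, os_event) ~ group, data = df)
  sd <- survival::survdiff(survival::Surv(os_time, os_event) ~ group, data = df)
  logrank_p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1L, lower.tail = FALSE)
  strata_names <- sub("^group=", "", rep(names(sf$strata), sf$strata))
  curves <- tibble::tibble(
    group = strata_names, time = sf$time, n_risk = sf$n.risk,
    n_event = sf$n.event, survival = sf$surv
  )
  structure(list(
    curves = curves, logrank_p = unname(logrank_p),
    groups = tibble::tibble(sample_id = surv$sample_id, value = values,
                            group = as.character(grp))
  ), class = "km_strata")
}

#' @export
print.km_strata <- function(x, ...) {
  cat("Kaplan-Meier stratification:",
      paste(unique(x$groups$group), collapse = ", "), "\n")
  cat(sprintf("  log-rank p = %.4g\n", x$logrank_p))
  invisible(x)
}

#' Compare predicted culture time between toxicity groups
#'
#' Two-sided Student's t-test (pooled variance) of a per-patient score
#' between patients with and without a binary toxicity flag (e.g. CRS or
#' ICANS).
#'
#' @param predicted_days per-patient score, named or aligned with `flags`.
#' @param flags 0/1 per patient; both groups need >= 2 patients.
#' @return one-row tibble: group means, `t_statistic`, `df`, `p_value`, ns.
#' @export
compare_toxicity_groups <- function(predicted_days, flags) {
  if (is.data.frame(predicted_days)) predicted_days <- predicted_days$predicted_days
  predicted_days <- as.numeric(predicted_days)
  flags <- as.numeric(flags)
  if (length(flags) != length(predicted_days)) {
    stop("flags must align with predicted_days", call. = FALSE)
  }
  keep <- !is.na(flags) & !is.na(predicted_days)
  predicted_days <- predicted_days[keep]
  flags <- flags[keep]
  if (!all(flags %in% c(0, 1))) stop("flags must be 0/1", call. = FALSE)
  g0 <- predicted_days[flags == 0]
  g1 <- predicted_days[flags == 1]
  if (length(g0) < 2L || length(g1) < 2L) {
    stop("each toxicity group needs >= 2 patients", call. = FALSE)
  }
  tt <- stats::t.test(g1, g0, var.equal = TRUE)
  tibble::tibble(
    mean_flagged = mean(g1), mean_unflagged = mean(g0),
    t_statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, n_flagged = length(g1), n_unflagged = length(g0)
  )
}
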