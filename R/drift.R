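#' Per-CpG Pearson correlation with time in culture
#'
#' Correlates each CpG's beta values with days in culture across samples.
#' Every sample (not donor) is one observation. Missing betas are handled
#' pairwise-complete; a CpG with fewer than 3 complete pairs gets `r = NA`
#' and is flagged, and a CpG with zero variance gets `r = 0` by convention.
#'
#' @param beta beta matrix (CpGs x samples).
#' @param days numeric vector of days in culture, one per sample (in column
#'   order, or named by sample id).
#' @return tibble with `cpg_id`, `r`, `n_complete`, `flag`
#'   (`"ok"`, `"zero_variance"` or `"too_few_pairs"`).
#' @export
correlate_with_time <- function(beta, days) {
  beta <- beta_matrix(beta)
  if (!is.null(names(days))) days <- days[colnames(beta)]
  days <- as.numeric(days)
  if (length(days) != ncol(beta)) stop("days must have one value per sample", call. = FALSE)
  if (length(unique(days[!is.na(days)])) < 2L) {
    stop("no time gradient: all days identical", call. = FALSE)
  }
  if (sum(!is.na(days)) < 3L) stop("need >= 3 samples with days", call. = FALSE)
  r <- suppressWarnings(
    drop(stats::cor(t(beta), days, use = "pairwise.complete.obs"))
  )
  n_complete <- rowSums(!is.na(beta) & !is.na(matrix(days, nrow(beta),
                                                     ncol(beta), byrow = TRUE)))
  flag <- rep("ok", nrow(beta))
  too_few <- n_complete < 3L
  zero_var <- is.na(r) & !too_few
  r[zero_var] <- 0
  r[too_few] <- NA_real_
  flag[zero_var] <- "zero_variance"
  flag[too_few] <- "too_few_pairs"
  tibble::tibble(cpg_id = rownames(beta), r = unname(r),
                 n_complete = as.integer(n_complete), flag = flag)
}

#' Select drift CpGs from a time-correlation table
#'
#' Candidate cultivation-time CpGs are those whose Pearson correlation with
#' days in culture exceeds the threshold with strict inequality:
#' hypermethylating if `r > r_hi`, hypomethylating if `r < -r_hi`. A CpG with
#' `r` exactly at the threshold is not selected.
#'
#' @param r_tbl result of [correlate_with_time()].
#' @param r_hi correlation threshold (default 0.9).
#' @return list with character vectors `hyper` and `hypo`.
#' @export
select_drift_cpgs <- function(r_tbl, r_hi = 0.9) {
  ok <- !is.na(r_tbl$r)
  list(hyper = r_tbl$cpg_id[ok & r_tbl$r > r_hi],
       hypo = r_tbl$cpg_id[ok & r_tbl$r < -r_hi])
}

#' Remove age-associated CpGs from a candidate set
#'
#' Drift candidates may overlap CpGs that track donor age rather than
#' culture time. Each candidate's beta values are correlated with
#' chronological age in an independent reference dataset (e.g. peripheral
#' blood across a wide age span); candidates with `|r| > r_age` are removed.
#' Candidates absent from the reference are kept with a warning.
#'
#' @param candidates character vector of candidate CpG ids.
#' @param age_beta beta matrix of the age-reference dataset.
#' @param ages numeric donor ages (years), one per reference sample.
#' @param r_age absolute-correlation threshold (default 0.3).
#' @return list with `kept` and `removed` character vectors.
#' @export
exclude_age_cpgs <- function(candidates, age_beta, ages, r_age = 0.3) {
  age_beta <- beta_matrix(age_beta)
  ages <- as.numeric(ages)
  if (length(ages) != ncol(age_beta)) stop("ages must have one value per sample", call. = FALSE)
  if (length(unique(ages[!is.na(ages)])) < 2L) {
    stop("all ages identical: no age gradient", call. = FALSE)
  }
  absent <- setdiff(candidates, rownames(age_beta))
  if (length(absent)) {
    warning(length(absent), " candidate CpG(s) absent from age reference; kept")
  }
  present <- intersect(candidates, rownames(age_beta))
  removed <- character()
  if (length(present)) {
    r <- suppressWarnings(drop(stats::cor(
      t(age_beta[present, , drop = FALSE]), ages,
      use = "pairwise.complete.obs"
    )))
    r[is.na(r)] <- 0
    removed <- present[abs(r) > r_age]
  }
  list(kept = setdiff(candidates, removed), removed = removed)
}

#' Drift screen: time correlation + age exclusion in one call
#'
#' Convenience wrapper running [correlate_with_time()],
#' [select_drift_cpgs()] and (when an age reference is given)
#' [exclude_age_cpgs()].
#'
#' @inheritParams correlate_with_time
#' @inheritParams select_drift_cpgs
#' @inheritParams exclude_age_cpgs
#' @param age_beta,ages optional age-reference matrix and ages.
#' @return list with the correlation table (`correlations`), `hyper`,
#'   `hypo`, `age_excluded` and the `final` candidate set
#'   `(hyper U hypo) \ age_excluded`.
#' @export
drift_screen <- function(beta, days, r_hi = 0.9, age_beta = NULL, ages = NULL,
                         r_age = 0.3) {
  r_tbl <- correlate_with_time(beta, days)
  sel <- select_drift_cpgs(r_tbl, r_hi)
  candidates <- c(sel$hyper, sel$hypo)
  age_excluded <- character()
  if (!is.null(age_beta)) {
    ex <- exclude_age_cpgs(candidates, age_beta, ages, r_age)
    age_excluded <- ex$removed
  }
  list(correlations = r_tbl, hyper = sel$hyper, hypo = sel$hypo,
       age_excluded = age_excluded,
       final = setdiff(candidates, age_excluded))
}

#' Differential methylation between two sample groups
#'
#' Per-CpG comparison of mean beta between two groups (e.g. day 0 vs day 22
#' samples), testing with limma's moderated t (default) or Welch's t and
#' adjusting with Benjamini-Hochberg across all CpGs. A CpG is significant
#' when `|delta mean| > delta` AND adjusted p < `alpha` (conjunction);
#' direction is `hyper` when group B exceeds group A.
#'
#' @param beta beta matrix.
#' @param group_a,group_b sample ids of the two groups (>= 2 each).
#' @param delta mean-difference cutoff (default 0.20).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param method "moderated" or "welch".
#' @return tibble with `cpg_id`, group means, `delta` (B - A), `p_value`,
#'   `p_adj`, `direction`, `significant`.
#' @export
differential_methylation <- function(beta, group_a, group_b, delta = 0.20,
                                     alpha = 0.05,
                                     method = c("moderated", "welch")) {
  beta <- beta_matrix(beta)
  ia <- match(group_a, colnames(beta))
  ib <- match(group_b, colnames(beta))
  if (anyNA(ia) || anyNA(ib)) stop("unknown sample id in group list", call. = FALSE)
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("each group needs >= 2 samples", call. = FALSE)
  }
  tab <- dm_test(beta, ia, ib, method = match.arg(method))
  tab |>
    dplyr::rename(mean_a = "mean_group1", mean_b = "mean_group2") |>
    dplyr::mutate(
      direction = dplyr::if_else(.data$delta > 0, "hyper", "hypo"),
      significant = abs(.data$delta) > !!delta & .data$p_adj < alpha
    )
}
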