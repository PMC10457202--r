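#' Exclude problematic array probes from a beta matrix
#'
#' Applies the standard exclusion rules for Illumina methylation arrays:
#' probes overlapping common SNPs (minor-allele frequency above
#' `maf_threshold`), probes on the X and Y chromosomes, probes flagged as
#' cross-reactive, and (optionally) a caller-supplied set of cell-composition
#' CpGs. Each removed CpG is attributed to exactly one category, the first
#' matching rule in the fixed order SNP -> XY -> cross-reactive ->
#' composition, so category counts add up to the total removed.
#'
#' @param beta beta matrix (CpGs x samples).
#' @param ann probe annotation (see [validate_probe_annotation()]).
#' @param maf_threshold SNP minor-allele frequency cutoff; probes with
#'   `snp_maf > maf_threshold` are removed (default 0.01, i.e. MAF > 1%).
#' @param composition_cpgs optional character vector of composition CpGs to
#'   exclude (e.g. from [composition_dmps()]).
#' @param strict if `TRUE` (default) CpGs absent from the annotation are an
#'   error; if `FALSE` they are retained with a warning.
#' @return list with `beta` (the filtered matrix, row order preserved) and
#'   `report` (a `filter_report` with per-category counts and ids).
#' @export
filter_probes <- function(beta, ann, maf_threshold = 0.01,
                          composition_cpgs = NULL, strict = TRUE) {
  beta <- beta_matrix(beta)
  ann <- validate_probe_annotation(ann)
  cpgs <- rownames(beta)
  idx <- match(cpgs, ann$cpg_id)
  unknown <- cpgs[is.na(idx)]
  if (length(unknown)) {
    if (strict) {
      stop("CpGs missing from annotation: ",
           paste(utils::head(unknown, 10L), collapse = ", "), call. = FALSE)
    }
    warning(length(unknown), " CpG(s) missing from annotation retained")
  }
  maf <- ann$snp_maf[idx]
  chrom <- ann$chromosome[idx]
  xr <- ann$cross_reactive[idx]
  is_snp <- !is.na(maf) & maf > maf_threshold
  is_xy <- !is.na(chrom) & chrom %in% c("X", "Y", "chrX", "chrY")
  is_xr <- !is.na(xr) & xr
  is_comp <- cpgs %in% (composition_cpgs %||% character())
  # first-match attribution in the fixed rule order
  cat <- rep("retained", length(cpgs))
  cat[is_comp] <- "composition"
  cat[is_xr] <- "cross_reactive"
  cat[is_xy] <- "xy"
  cat[is_snp] <- "snp"
  keep <- cat == "retained"
  report <- structure(list(
    n_input = length(cpgs),
    n_removed_snp = sum(cat == "snp"),
    n_removed_xy = sum(cat == "xy"),
    n_removed_crossreactive = sum(cat == "cross_reactive"),
    n_removed_composition = sum(cat == "composition"),
    n_retained = sum(keep),
    removed_ids = list(snp = cpgs[cat == "snp"], xy = cpgs[cat == "xy"],
                       cross_reactive = cpgs[cat == "cross_reactive"],
                       composition = cpgs[cat == "composition"])
  ), class = "filter_report")
  list(beta = beta[keep, , drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Probe filter report\n")
  cat("  input CpGs:      ", x$n_input, "\n")
  cat("  removed SNP:     ", x$n_removed_snp, "\n")
  cat("  removed X/Y:     ", x$n_removed_xy, "\n")
  cat("  removed cross-reactive:", x$n_removed_crossreactive, "\n")
  cat("  removed composition:   ", x$n_removed_composition, "\n")
  cat("  retained:        ", x$n_retained, "\n")
  invisible(x)
}

#' @export
tidy.filter_report <- function(x, ...) {
  tibble::tibble(
    category = c("snp", "xy", "cross_reactive", "composition", "retained"),
    n = c(x$n_removed_snp, x$n_removed_xy, x$n_removed_crossreactive,
          x$n_removed_composition, x$n_retained)
  )
}

# Per-CpG two-group comparison on a beta matrix. method "moderated" uses
# limma's empirical-Bayes moderated t (lmFit + eBayes on a two-group design);
# "welch" is a vectorised plain Welch t-test. Returns one row per CpG with
# group means, delta (group2 - group1), p and BH-adjusted p across all CpGs.
dm_test <- function(beta, idx1, idx2, method = c("moderated", "welch")) {
  method <- match.arg(method)
  x1 <- beta[, idx1, drop = FALSE]
  x2 <- beta[, idx2, drop = FALSE]
  m1 <- rowMeans(x1, na.rm = TRUE)
  m2 <- rowMeans(x2, na.rm = TRUE)
  if (method == "moderated") {
    grp <- factor(c(rep("g1", length(idx1)), rep("g2", length(idx2))),
                  levels = c("g1", "g2"))
    design <- stats::model.matrix(~grp)
    fit <- limma::eBayes(limma::lmFit(cbind(x1, x2), design))
    p <- fit$p.value[, 2L]
  } else {
    v1 <- apply(x1, 1L, stats::var, na.rm = TRUE)
    v2 <- apply(x2, 1L, stats::var, na.rm = TRUE)
    n1 <- rowSums(!is.na(x1))
    n2 <- rowSums(!is.na(x2))
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m2 - m1) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  }
  # degenerate CpGs: no variance anywhere and equal means -> p = 1
  degen <- which(!is.finite(p))
  if (length(degen)) p[degen] <- ifelse(abs(m2 - m1)[degen] < .Machine$double.eps^0.5, 1, 0)
  tibble::tibble(
    cpg_id = rownames(beta),
    mean_group1 = unname(m1), mean_group2 = unname(m2),
    delta = unname(m2 - m1),
    p_value = unname(p), p_adj = unname(stats::p.adjust(p, method = "BH"))
  )
}

#' Identify cell-composition CpGs between two purified cell types
#'
#' Flags CpGs differentially methylated between two reference cell
#' populations (e.g. purified CD4+ vs CD8+ T cells) so that downstream drift
#' analyses are not confounded by shifting cell composition. A CpG is
#' selected when the absolute mean beta difference exceeds `delta` OR its
#' Benjamini-Hochberg-adjusted p-value from a per-CpG two-sample test falls
#' below `alpha` (the union of the two rules). The default test is limma's
#' empirical-Bayes moderated t; `method = "welch"` gives a plain Welch t.
#' BH adjustment is applied across all CpGs in the reference matrix.
#'
#' @param beta_ref beta matrix of the reference samples.
#' @param groups two-level vector (factor/character) of cell-type labels,
#'   one per column of `beta_ref`, each level with >= 2 samples.
#' @param delta mean-difference cutoff (default 0.10, i.e. 10% DNAm).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param method "moderated" (default) or "welch".
#' @return character vector of selected CpG ids, with the full per-CpG table
#'   attached as attribute `"table"`.
#' @export
composition_dmps <- function(beta_ref, groups, delta = 0.10, alpha = 0.05,
                             method = c("moderated", "welch")) {
  beta_ref <- beta_matrix(beta_ref)
  groups <- as.character(groups)
  if (length(groups) != ncol(beta_ref)) {
    stop("groups must have one label per sample", call. = FALSE)
  }
  lv <- sort(unique(groups))
  if (length(lv) != 2L) stop("exactly two group levels required", call. = FALSE)
  idx1 <- which(groups == lv[1L])
  idx2 <- which(groups == lv[2L])
  if (length(idx1) < 2L || length(idx2) < 2L) {
    stop("each group needs >= 2 samples", call. = FALSE)
  }
  tab <- dm_test(beta_ref, idx1, idx2, method = match.arg(method))
  sel <- tab$cpg_id[abs(tab$delta) > delta | tab$p_adj < alpha]
  attr(sel, "table") <- tab
  sel
}
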