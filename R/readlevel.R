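#' Construct a per-read methylation call set
#'
#' Binary per-read x per-CpG methylation calls for one bisulfite amplicon in
#' one sample. Positions are 1-based genomic coordinates on the reference
#' strand and must be strictly increasing; calls are 0/1 with `NA` for
#' unobserved CpGs, and every read must carry at least one non-missing call.
#'
#' @param calls reads x CpGs matrix with values in \{0, 1, NA\}.
#' @param positions numeric CpG coordinates (defaults to the numeric column
#'   names of `calls`).
#' @param amplicon_id,sample_id identifiers.
#' @return object of class `read_set`.
#' @export
read_set <- function(calls, positions = NULL, amplicon_id = "amplicon",
                     sample_id = "sample") {
  calls <- as.matrix(calls)
  if (nrow(calls) < 1L) stop("read set needs >= 1 read", call. = FALSE)
  if (is.null(positions)) positions <- as.numeric(colnames(calls))
  positions <- as.numeric(positions)
  if (anyNA(positions) || length(positions) != ncol(calls)) {
    stop("positions must be numeric, one per CpG column", call. = FALSE)
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("CpG positions must be strictly increasing", call. = FALSE)
  }
  ok <- is.na(calls) | calls == 0 | calls == 1
  if (!all(ok)) {
    bad <- calls[which(!ok)[1L]]
    stop("calls must be 0/1/NA; found ", bad, call. = FALSE)
  }
  storage.mode(calls) <- "integer"
  if (any(rowSums(!is.na(calls)) == 0L)) {
    stop("every read needs >= 1 non-missing call", call. = FALSE)
  }
  colnames(calls) <- as.character(positions)
  rownames(calls) <- NULL
  structure(list(amplicon_id = amplicon_id, sample_id = sample_id,
                 positions = positions, calls = calls),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("ReadSet '%s' (%s): %d reads x %d CpGs\n", x$amplicon_id,
              x$sample_id, nrow(x$calls), length(x$positions)))
  invisible(x)
}

#' Read per-read amplicon calls from TSV
#'
#' One row per read, one column per CpG; the header holds the CpG
#' coordinates and cells are 0, 1 or NA.
#'
#' @param path TSV path.
#' @param amplicon_id,sample_id identifiers to attach.
#' @return a [read_set()].
#' @export
read_amplicon_calls <- function(path, amplicon_id = "amplicon",
                                sample_id = "sample") {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_double()),
                        na = "NA", progress = FALSE)
  if (nrow(df) == 0L) stop("empty amplicon file: ", path, call. = FALSE)
  m <- as.matrix(df)
  read_set(m, positions = as.numeric(colnames(df)),
           amplicon_id = amplicon_id, sample_id = sample_id)
}

#' Write per-read amplicon calls to TSV
#' @param rs a [read_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_amplicon_calls <- function(rs, path) {
  stopifnot(inherits(rs, "read_set"))
  df <- tibble::as_tibble(rs$calls, .name_repair = "minimal")
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Per-CpG mean methylation of a read set
#'
#' `beta_i` = methylated calls / non-missing calls at CpG `i`. A CpG with no
#' non-missing calls gets `NA` and is flagged.
#'
#' @param rs a [read_set()].
#' @return tibble: `position`, `beta`, `n_calls`, `flag`.
#' @export
mean_methylation <- function(rs) {
  stopifnot(inherits(rs, "read_set"))
  n_calls <- colSums(!is.na(rs$calls))
  beta <- colSums(rs$calls == 1L, na.rm = TRUE) / n_calls
  beta[n_calls == 0L] <- NA_real_
  tibble::tibble(position = rs$positions, beta = unname(beta),
                 n_calls = unname(as.integer(n_calls)),
                 flag = ifelse(n_calls == 0L, "no_calls", "ok"))
}

#' Correlation of amplicon CpGs with culture time across samples
#'
#' Takes per-sample mean methylation vectors over the CpGs of one amplicon
#' and correlates each CpG with days in culture, reporting the CpG with the
#' highest correlation (ties broken by the lowest coordinate; all-degenerate
#' amplicons are flagged).
#'
#' @param beta_by_sample matrix of per-CpG beta (rows = CpG positions,
#'   columns = samples), e.g. stacked [mean_methylation()] results.
#' @param days days in culture per sample.
#' @return tibble per CpG: `position`, `r`, `is_top`, plus attribute
#'   `"degenerate"` (TRUE when every r is zero).
#' @export
neighbor_time_correlation <- function(beta_by_sample, days) {
  r_tbl <- correlate_with_time(beta_by_sample, days)
  pos <- as.numeric(r_tbl$cpg_id)
  r <- r_tbl$r
  degenerate <- all(is.na(r) | r == 0)
  r_rank <- ifelse(is.na(r), -Inf, r)
  top <- which(r_rank == max(r_rank))
  top <- top[which.min(pos[top])]
  out <- tibble::tibble(position = pos, r = r,
                        is_top = seq_along(pos) == top)
  attr(out, "degenerate") <- degenerate
  out
}

# Pairwise phi coefficients of binary columns, pairwise-complete over reads;
# phi is the Pearson correlation of the 2x2 table. Pairs involving a
# constant CpG get phi = 0 by convention (flagged via the attribute).
pairwise_phi <- function(calls) {
  suppressWarnings(ph <- stats::cor(calls, use = "pairwise.complete.obs"))
  constant <- apply(calls, 2L, function(v) {
    v <- v[!is.na(v)]
    length(unique(v)) < 2L
  })
  ph[is.na(ph)] <- 0
  diag(ph) <- 1
  attr(ph, "constant_cpgs") <- colnames(calls)[constant]
  ph
}

mean_abs_offdiag <- function(m) {
  mean(abs(m[upper.tri(m)]))
}

#' Within-read methylation coherence with a permutation null
#'
#' Quantifies whether neighbouring CpGs on the same DNA strand are modified
#' coherently or independently. For every CpG pair the phi coefficient of
#' the read-level 2x2 table is computed (pairwise-complete reads); the
#' summary statistic is the mean absolute phi. The null distribution is
#' built by independently permuting each CpG column across reads, which
#' preserves every marginal methylation level while destroying within-read
#' linkage; the p-value uses the add-one convention
#' `(1 + #\{null >= observed\}) / (1 + n_permutations)`. Coordinated
#' (writer-driven) methylation gives a small p; stochastic drift gives phi
#' near zero and a uniform p.
#'
#' @param rs a [read_set()] with >= 2 CpGs and >= 20 reads.
#' @param n_permutations permutation count (default 1000).
#' @param seed integer seed.
#' @return list: `phi` (CpG x CpG matrix), `mean_abs_phi`, `p_value`,
#'   `null_stats` (permutation statistics), `constant_cpgs` (flagged ids).
#' @export
within_read_coherence <- function(rs, n_permutations = 1000L, seed = 1L) {
  stopifnot(inherits(rs, "read_set"))
  calls <- rs$calls
  if (ncol(calls) < 2L) stop("coherence needs >= 2 CpGs", call. = FALSE)
  if (nrow(calls) < 20L) stop("coherence needs >= 20 reads", call. = FALSE)
  ph <- pairwise_phi(calls)
  obs <- mean_abs_offdiag(ph)
  withr::with_seed(seed, {
    null_stats <- vapply(seq_len(n_permutations), function(b) {
      perm <- apply(calls, 2L, sample)
      mean_abs_offdiag(pairwise_phi(perm))
    }, numeric(1))
  })
  p <- (1 + sum(null_stats >= obs)) / (1 + n_permutations)
  list(phi = ph, mean_abs_phi = obs, p_value = p, null_stats = null_stats,
       constant_cpgs = attr(ph, "constant_cpgs"))
}
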