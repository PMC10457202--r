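#' Construct a cell-type reference profile matrix
#'
#' @param values numeric matrix of mean beta per cell type: rows are
#'   discriminating CpGs, columns are cell types, all values in \[0,1\].
#'   At least two cell types; the matrix must be full column rank.
#' @return validated reference matrix of class `reference_profiles`.
#' @export
reference_profiles <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("reference must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("reference needs CpG rownames and cell-type colnames", call. = FALSE)
  }
  if (ncol(values) < 2L) stop("reference needs >= 2 cell types", call. = FALSE)
  if (any(values < 0 | values > 1, na.rm = TRUE)) {
    stop("reference betas must lie in [0,1]", call. = FALSE)
  }
  if (qr(values)$rank < ncol(values)) {
    cm <- suppressWarnings(stats::cor(values))
    cm[!is.finite(cm)] <- 1   # constant columns are trivially collinear
    diag(cm) <- 0
    worst <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    stop("reference is rank deficient; collinear cell types: ",
         paste(colnames(values)[worst], collapse = " ~ "), call. = FALSE)
  }
  structure(values, class = c("reference_profiles", class(values)))
}

#' Read a reference profile matrix from CSV
#' @param path CSV with first column `cpg_id` and one column per cell type.
#' @return a [reference_profiles()] matrix.
#' @export
read_reference_profiles <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  reference_profiles(m)
}

# Non-negative least squares with a sum-to-one constraint: solve
# min ||s - R f||_2 s.t. f >= 0 by NNLS on the system augmented with a
# heavily weighted row of ones, then renormalise so the simplex constraint
# holds exactly. The augmentation weight makes the pre-normalisation sum
# agree with 1 to ~1e-10, so the renormalisation is a no-op numerically.
nnls_simplex <- function(R, s, weight = 1e6) {
  A <- rbind(R, rep(weight, ncol(R)))
  b <- c(s, weight)
  f <- pracma::lsqnonneg(A, b)$x
  if (sum(f) <= 0) stop("deconvolution failed: all-zero solution", call. = FALSE)
  f / sum(f)
}

#' Estimate cell-type fractions from methylation profiles
#'
#' Reference-based deconvolution in the Houseman tradition: for each sample,
#' fractions minimise `||sample - ref %*% f||_2` subject to `f >= 0` and
#' `sum(f) = 1` (constrained quadratic projection onto the simplex). Used as
#' a QC consistency check of bulk T-cell profiles against the expected
#' CD4/CD8 composition.
#'
#' @param beta beta matrix (or a named vector for a single sample) over the
#'   reference CpGs; up to 10% missing values per sample are imputed by the
#'   reference row mean, more is an error.
#' @param ref a [reference_profiles()] matrix.
#' @return tibble with one row per sample x cell type: `sample_id`,
#'   `cell_type`, `fraction`, plus the per-sample `residual` norm.
#' @export
estimate_fractions <- function(beta, ref) {
  ref <- reference_profiles(unclass(ref))
  if (is.null(dim(beta))) {
    beta <- matrix(beta, ncol = 1L,
                   dimnames = list(names(beta), "sample"))
  }
  miss_cpg <- setdiff(rownames(ref), rownames(beta))
  if (length(miss_cpg)) {
    stop("sample beta missing reference CpGs: ",
         paste(utils::head(miss_cpg, 5L), collapse = ", "), call. = FALSE)
  }
  X <- beta[rownames(ref), , drop = FALSE]
  ref_mean <- rowMeans(ref)
  out <- purrr::map_dfr(seq_len(ncol(X)), function(j) {
    s <- X[, j]
    na <- is.na(s)
    if (all(na)) stop("sample '", colnames(X)[j], "' has no observed betas",
                      call. = FALSE)
    if (mean(na) > 0.10) {
      stop("sample '", colnames(X)[j], "' has >10% missing reference CpGs",
           call. = FALSE)
    }
    s[na] <- ref_mean[na]
    f <- nnls_simplex(unclass(ref), s)
    tibble::tibble(
      sample_id = colnames(X)[j],
      cell_type = colnames(ref),
      fraction = f,
      residual = sqrt(sum((s - drop(unclass(ref) %*% f))^2))
    )
  })
  out
}
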