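#' Construct and validate a beta matrix
#'
#' A beta matrix is the universal currency of the pipeline: a numeric matrix
#' of methylation fractions (beta values) with CpGs in rows and samples in
#' columns. Values must lie in \[0, 1\]; `NA` marks failed probes. Row and
#' column names are the CpG and sample identifiers and must be unique.
#'
#' @param values numeric matrix, CpGs in rows, samples in columns, with
#'   unique non-empty dimnames.
#' @return the validated matrix (invisibly classed as used throughout the
#'   package: a plain numeric matrix).
#' @export
beta_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("beta matrix must be a numeric matrix", call. = FALSE)
  }
  cpg_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(cpg_ids) || is.null(sample_ids)) {
    stop("beta matrix must have CpG rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(cpg_ids)) {
    stop("duplicate CpG ids: ",
         paste(unique(cpg_ids[duplicated(cpg_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.na(values) & (values < 0 | values > 1))
  if (length(bad)) {
    rows <- unique(cpg_ids[(bad - 1L) %% nrow(values) + 1L])
    stop("beta values outside [0,1] at CpG(s): ",
         paste(utils::head(rows, 5L), collapse = ", "), call. = FALSE)
  }
  values
}

#' Read a beta matrix from TSV
#'
#' Expects a tab-separated file whose first column (`cpg_id`) holds CpG
#' identifiers and whose remaining columns are samples, one header row of
#' sample ids. Orientation is fixed as CpGs-in-rows (the GEO series-matrix
#' convention); transposed input fails validation rather than being
#' auto-detected, since silent transposition is the classic methylation
#' pipeline bug. Missing values are written/read as `NA`.
#'
#' @param path path to a TSV file.
#' @return numeric beta matrix (CpGs x samples).
#' @export
read_beta_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), na = character(), progress = FALSE)
  if (ncol(df) < 2L) stop("beta TSV needs a cpg_id column plus >=1 sample", call. = FALSE)
  cpg_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  vals <- matrix(NA_real_, nrow(df), length(sample_ids),
                 dimnames = list(cpg_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    cell <- df[[j + 1L]]
    missing <- cell == "NA" | cell == ""
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !missing)
    if (length(bad)) {
      stop(sprintf("non-numeric beta value '%s' at CpG '%s', sample '%s'",
                   cell[bad[1L]], cpg_ids[bad[1L]], sample_ids[j]), call. = FALSE)
    }
    num[missing] <- NA_real_
    vals[, j] <- num
  }
  beta_matrix(vals)
}

#' Write a beta matrix to TSV
#'
#' @param beta beta matrix (CpGs x samples).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  beta <- beta_matrix(beta)
  df <- tibble::as_tibble(beta, rownames = "cpg_id")
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

sheet_numeric_cols <- c("days_in_culture", "cumulative_pd", "age",
                        "os_time", "os_event", "crs", "icans")
sheet_character_cols <- c("sample_id", "donor_id", "condition", "trial",
                          "disease", "cohort")

#' Validate a sample sheet
#'
#' A sample sheet is a tibble with one row per sample carrying the covariates
#' the pipeline uses: `sample_id` (required, unique), and the optional columns
#' `donor_id`, `condition`, `days_in_culture` (days, >= 0), `cumulative_pd`,
#' `age` (years), `trial`, `disease`, `os_time` (days, > 0), `os_event` (0/1),
#' `crs`, `icans` (0/1), `cohort` (identification / validation / unassigned).
#' Unknown columns are preserved untouched.
#'
#' @param sheet data frame.
#' @return a validated tibble.
#' @export
validate_sample_sheet <- function(sheet) {
  sheet <- tibble::as_tibble(sheet)
  if (!"sample_id" %in% names(sheet)) stop("sample sheet needs a sample_id column", call. = FALSE)
  sheet$sample_id <- as.character(sheet$sample_id)
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  for (cc in intersect(sheet_numeric_cols, names(sheet))) {
    sheet[[cc]] <- as.numeric(sheet[[cc]])
  }
  for (cc in intersect(setdiff(sheet_character_cols, "sample_id"), names(sheet))) {
    sheet[[cc]] <- as.character(sheet[[cc]])
  }
  if ("days_in_culture" %in% names(sheet)) {
    d <- sheet$days_in_culture
    if (any(!is.na(d) & d < 0)) stop("negative days_in_culture", call. = FALSE)
  }
  if ("os_time" %in% names(sheet)) {
    has_time <- !is.na(sheet$os_time)
    if (!"os_event" %in% names(sheet) || any(has_time & is.na(sheet$os_event))) {
      stop("os_time present without matching os_event", call. = FALSE)
    }
    if (any(sheet$os_time[has_time] <= 0)) stop("os_time must be > 0", call. = FALSE)
    ev <- sheet$os_event[has_time]
    if (!all(ev %in% c(0, 1))) stop("os_event must be 0/1", call. = FALSE)
  }
  if (!"cohort" %in% names(sheet)) {
    sheet$cohort <- "unassigned"
  } else {
    sheet$cohort[is.na(sheet$cohort)] <- "unassigned"
    ok <- sheet$cohort %in% c("identification", "validation", "unassigned")
    if (!all(ok)) stop("cohort must be identification/validation/unassigned", call. = FALSE)
  }
  sheet
}

#' Read a sample sheet from CSV
#'
#' @param path path to a CSV file with a `sample_id` column; see
#'   [validate_sample_sheet()] for the recognised columns. Unknown columns
#'   are kept as opaque extras.
#' @return validated tibble.
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_guess()),
                        na = c("NA", ""), progress = FALSE, show_col_types = FALSE)
  validate_sample_sheet(df)
}

#' Write a sample sheet to CSV
#' @param sheet sample sheet tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_csv(validate_sample_sheet(sheet), path, na = "NA", progress = FALSE)
  invisible(path)
}

region_vocabulary <- c("promoter", "body", "other")

#' Validate a probe annotation table
#'
#' Columns: `cpg_id` (unique), `chromosome` (labels, including X/Y),
#' `snp_maf` (minor-allele frequency in \[0,1\] or NA), `cross_reactive`
#' (logical), `region_class` (promoter / body / other, where promoter
#' collapses TSS1500, TSS200 and 5'UTR and body collapses Body, 1stExon and
#' 3'UTR), optional `gene`.
#'
#' @param ann data frame.
#' @return validated tibble.
#' @export
validate_probe_annotation <- function(ann) {
  ann <- tibble::as_tibble(ann)
  need <- c("cpg_id", "chromosome", "snp_maf", "cross_reactive", "region_class")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  ann$cpg_id <- as.character(ann$cpg_id)
  if (anyDuplicated(ann$cpg_id)) stop("duplicate cpg_id in annotation", call. = FALSE)
  ann$chromosome <- as.character(ann$chromosome)
  ann$snp_maf <- as.numeric(ann$snp_maf)
  if (any(!is.na(ann$snp_maf) & (ann$snp_maf < 0 | ann$snp_maf > 1))) {
    stop("snp_maf outside [0,1]", call. = FALSE)
  }
  ann$cross_reactive <- as.logical(ann$cross_reactive)
  ann$region_class <- as.character(ann$region_class)
  bad <- setdiff(stats::na.omit(unique(ann$region_class)), region_vocabulary)
  if (length(bad)) {
    stop("region_class outside vocabulary (promoter/body/other): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ann
}

#' Read a probe annotation CSV
#' @param path path to a CSV; see [validate_probe_annotation()].
#' @return validated tibble.
#' @export
read_probe_annotation <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_guess()),
                        na = c("NA", ""), progress = FALSE, show_col_types = FALSE)
  validate_probe_annotation(df)
}

#' Write a probe annotation CSV
#' @param ann annotation tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_annotation <- function(ann, path) {
  readr::write_csv(validate_probe_annotation(ann), path, na = "NA", progress = FALSE)
  invisible(path)
}
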