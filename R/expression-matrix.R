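#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median sd quantile
NULL

EXPR_MODALITIES <- c("mRNA", "protein", "phosphosite",
                     "PAM", "CNV_amp", "CNV_del", "truncation")
EXPR_SCALES <- c("raw_count", "tpm", "log2_intensity", "log2_tpm",
                 "binary", "count", "log2_fc")

#' Expression matrix container
#'
#' A light wrapper around a numeric matrix (rows = biomolecules, columns =
#' samples) carrying a modality tag (what kind of biomolecule is quantified)
#' and a scale tag (how the values are expressed). Missing values are `NA`.
#'
#' @param values Numeric matrix with unique row names (biomolecule ids) and
#'   unique column names (sample ids).
#' @param modality One of `r paste0('"', EXPR_MODALITIES, '"', collapse = ", ")`.
#' @param scale One of `r paste0('"', EXPR_SCALES, '"', collapse = ", ")`.
#'   Binary modalities may contain only 0, 1 and `NA`; count scales only
#'   non-negative integers and `NA`.
#'
#' @return An `expr_matrix` object (a classed numeric matrix).
#' @export
expression_matrix <- function(values, modality, scale) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  modality <- match.arg(modality, EXPR_MODALITIES)
  scale <- match.arg(scale, EXPR_SCALES)
  ids <- rownames(values)
  smp <- colnames(values)
  if (is.null(ids) || is.null(smp)) {
    stop("`values` must have row names (biomolecule ids) and column names (sample ids)",
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicated biomolecule id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(smp)) {
    stop("duplicated sample id(s): ",
         paste(unique(smp[duplicated(smp)]), collapse = ", "), call. = FALSE)
  }
  finite <- values[!is.na(values)]
  if (scale == "binary" && !all(finite %in% c(0, 1))) {
    stop("binary matrix contains values other than 0/1/NA", call. = FALSE)
  }
  if (scale %in% c("count", "raw_count") &&
      (any(finite < 0) || any(finite != round(finite)))) {
    stop("count matrix contains negative or non-integer values", call. = FALSE)
  }
  structure(values, modality = modality, scale = scale,
            class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d biomolecules x %d samples [%s, %s], %d missing\n",
              nrow(x), ncol(x), attr(x, "modality"), attr(x, "scale"),
              sum(is.na(x))))
  invisible(x)
}

#' @export
as_tibble.expr_matrix <- function(x, ...) {
  tibble(
    biomolecule_id = rep(rownames(x), times = ncol(x)),
    sample_id = rep(colnames(x), each = nrow(x)),
    value = as.vector(unclass(x))
  )
}

# rebuild the class/attrs after matrix surgery
restore_expr <- function(values, template, scale = NULL) {
  expression_matrix(values, attr(template, "modality"),
                    scale %||% attr(template, "scale"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an expression matrix from TSV
#'
#' Expects a UTF-8 tab-separated file whose first column holds biomolecule
#' ids (header `id`) and whose remaining header fields are sample ids. Empty
#' cells or `NA` denote missing values.
#'
#' @param path Path to the TSV file.
#' @inheritParams expression_matrix
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, modality, scale) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""), quote = "",
                           fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stop("expression TSV needs an id column plus >= 1 sample",
                          call. = FALSE)
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample id(s) in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicated biomolecule id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_ids),
                 dimnames = list(ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   col[bad[1]], ids[bad[1]], sample_ids[j]), call. = FALSE)
    }
    vals[, j] <- num
  }
  expression_matrix(vals, modality, scale)
}

#' Write an expression matrix to TSV
#'
#' Values are written with 17 significant digits so that a read/write round
#' trip reproduces finite entries bit-exactly; missing values are written as
#' `NA`.
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  chr <- matrix(sprintf("%.17g", unclass(x)), nrow = nrow(x))
  chr[is.na(unclass(x))] <- "NA"
  lines <- c(paste(c("id", colnames(x)), collapse = "\t"),
             paste(rownames(x), apply(chr, 1, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read and validate a sample metadata table
#'
#' The TSV must carry exactly the columns `sample_id`, `patient_id`,
#' `tissue` (tumor/normal), `ischemia_min`, `age`, `gender`, `alcohol`,
#' `meat`, `grade`, `stage`, `run_label`.
#'
#' @param path Path to the metadata TSV.
#' @return A validated tibble.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, na.strings = c("NA", ""),
                          quote = "", fileEncoding = "UTF-8",
                          stringsAsFactors = FALSE)
  validate_metadata(as_tibble(md))
}

METADATA_COLUMNS <- c("sample_id", "patient_id", "tissue", "ischemia_min",
                      "age", "gender", "alcohol", "meat", "grade", "stage",
                      "run_label")

#' Validate a sample metadata table
#'
#' Checks the paired design: each patient contributes at most one tumor and
#' one normal sample, and the cold ischemia time is identical within a
#' patient's tumor/normal pair (both pieces of tissue are frozen together).
#'
#' @param metadata A data frame with the columns listed in
#'   [read_sample_metadata()].
#' @return The metadata as a tibble, invisibly checked.
#' @export
validate_metadata <- function(metadata) {
  missing_cols <- setdiff(METADATA_COLUMNS, names(metadata))
  if (length(missing_cols)) {
    stop("metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  md <- as_tibble(metadata)
  if (anyDuplicated(md$sample_id)) {
    stop("duplicated sample_id in metadata", call. = FALSE)
  }
  if (!all(md$tissue %in% c("tumor", "normal"))) {
    stop("tissue must be 'tumor' or 'normal'", call. = FALSE)
  }
  if (any(md$ischemia_min < 0, na.rm = TRUE)) {
    stop("negative ischemia_min", call. = FALSE)
  }
  dup <- md |>
    dplyr::count(.data$patient_id, .data$tissue) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop("patient(s) with more than one sample of the same tissue: ",
         paste(unique(dup$patient_id), collapse = ", "), call. = FALSE)
  }
  mism <- md |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::filter(dplyr::n_distinct(.data$ischemia_min) > 1) |>
    dplyr::ungroup()
  if (nrow(mism)) {
    stop("ischemia_min differs within pair for patient(s): ",
         paste(unique(mism$patient_id), collapse = ", "), call. = FALSE)
  }
  md
}

#' Paired tumor/normal design
#'
#' Extracts the aligned patient/tumor-sample/normal-sample triples from a
#' metadata table, keeping only patients with both tissues present.
#'
#' @inheritParams validate_metadata
#' @return A tibble with columns `patient_id`, `tumor_sample_id`,
#'   `normal_sample_id`, one row per complete pair.
#' @export
paired_design <- function(metadata) {
  md <- validate_metadata(metadata)
  tum <- md |> dplyr::filter(.data$tissue == "tumor") |>
    dplyr::select("patient_id", tumor_sample_id = "sample_id")
  nrm <- md |> dplyr::filter(.data$tissue == "normal") |>
    dplyr::select("patient_id", normal_sample_id = "sample_id")
  dplyr::inner_join(tum, nrm, by = "patient_id")
}

#' Convert raw counts to transcripts per million (TPM)
#'
#' Per sample, the count of each transcript is divided by its length in
#' kilobases to a rate, and rates are rescaled so that each sample sums to
#' one million over the non-missing transcripts.
#'
#' @param counts An [expression_matrix()] on the `raw_count` scale.
#' @param lengths Numeric vector of transcript lengths in bases, named by or
#'   aligned with the rows of `counts`; all positive.
#' @return An `expr_matrix` on the `tpm` scale.
#' @export
counts_to_tpm <- function(counts, lengths) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (attr(counts, "scale") != "raw_count") {
    stop("`counts` must be on the raw_count scale", call. = FALSE)
  }
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  if (length(lengths) != nrow(counts) || any(is.na(lengths)) ||
      any(lengths <= 0)) {
    stop("`lengths` must be positive and cover every biomolecule", call. = FALSE)
  }
  rate <- unclass(counts) / (lengths / 1000)
  tot <- colSums(rate, na.rm = TRUE)
  zero <- colnames(counts)[tot == 0]
  if (length(zero)) {
    stop("zero total rate for sample(s): ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  restore_expr(tpm, counts, scale = "tpm")
}

#' Log2-transform a TPM matrix with a +1 offset
#'
#' mRNA analyses run on `log2(TPM + 1)`; the offset handles zero counts.
#'
#' @param tpm An `expr_matrix` on the `tpm` scale.
#' @return An `expr_matrix` on the `log2_tpm` scale.
#' @export
log2_tpm1 <- function(tpm) {
  stopifnot(inherits(tpm, "expr_matrix"))
  if (attr(tpm, "scale") != "tpm") {
    stop("`tpm` must be on the tpm scale", call. = FALSE)
  }
  restore_expr(log2(unclass(tpm) + 1), tpm, scale = "log2_tpm")
}

#' Per-run median normalization of log2 intensities
#'
#' Shifts every analysis run so that its median matches the global median of
#' the input matrix: the run median is subtracted from each value and the
#' global median added back. On the log2 scale this is a multiplicative
#' rescaling of raw intensities.
#'
#' @param x An `expr_matrix` of log2-scale intensities.
#' @param run_labels Character vector of run/batch labels, named by or
#'   aligned with the columns of `x`.
#' @return The normalized `expr_matrix`; every run's median equals the
#'   global median of the input.
#' @export
median_normalize <- function(x, run_labels) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!is.null(names(run_labels))) run_labels <- run_labels[colnames(x)]
  if (length(run_labels) != ncol(x)) {
    stop("`run_labels` must cover every sample", call. = FALSE)
  }
  vals <- unclass(x)
  global_med <- median(vals, na.rm = TRUE)
  out <- vals
  for (r in unique(run_labels)) {
    idx <- which(run_labels == r)
    block <- vals[, idx, drop = FALSE]
    if (all(is.na(block))) {
      stop("run with all-missing values: ", r, call. = FALSE)
    }
    out[, idx] <- block - median(block, na.rm = TRUE) + global_med
  }
  restore_expr(out, x)
}

#' Per-patient log2 fold changes (tumor minus normal)
#'
#' @param tumor,normal `expr_matrix` objects on the log2 scale with identical
#'   biomolecule lists.
#' @param design A [paired_design()] tibble.
#' @return An `expr_matrix` whose columns are patients and whose values are
#'   tumor minus normal log2 expression; missing wherever either side is
#'   missing.
#' @export
log2_fold_changes <- function(tumor, normal, design) {
  stopifnot(inherits(tumor, "expr_matrix"), inherits(normal, "expr_matrix"))
  if (!identical(rownames(tumor), rownames(normal))) {
    stop("tumor and normal matrices must share the same biomolecule list",
         call. = FALSE)
  }
  miss_t <- setdiff(design$tumor_sample_id, colnames(tumor))
  miss_n <- setdiff(design$normal_sample_id, colnames(normal))
  if (length(miss_t) || length(miss_n)) {
    stop("design sample(s) absent from matrices: ",
         paste(c(miss_t, miss_n), collapse = ", "), call. = FALSE)
  }
  fc <- unclass(tumor)[, design$tumor_sample_id, drop = FALSE] -
    unclass(normal)[, design$normal_sample_id, drop = FALSE]
  colnames(fc) <- design$patient_id
  restore_expr(fc, tumor, scale = "log2_fc")
}

#' Row standardization (mean 0, SD 1)
#'
#' Centers each biomolecule at its mean and scales by its sample standard
#' deviation (denominator n - 1) over non-missing entries.
#'
#' @param x An `expr_matrix`; every row needs at least two non-missing values
#'   and nonzero standard deviation.
#' @return The standardized `expr_matrix`.
#' @export
standardize_rows <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  vals <- unclass(x)
  n_ok <- rowSums(!is.na(vals))
  sds <- apply(vals, 1, sd, na.rm = TRUE)
  bad <- rownames(x)[n_ok < 2 | is.na(sds) | sds == 0]
  if (length(bad)) {
    stop("zero-variance or under-observed row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- (vals - rowMeans(vals, na.rm = TRUE)) / sds
  restore_expr(out, x)
}

#' Write a sample metadata table to TSV
#'
#' @inheritParams validate_metadata
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(metadata, path) {
  md <- validate_metadata(metadata)
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}
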