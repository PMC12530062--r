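## Matrix I/O, validation and feature alignment.
##
## All on-disk matrices are delimited text: first column feature identifiers,
## header row sample (or cell-type) labels. Tab is the default separator;
## comma is auto-detected from the header line.

MODALITIES <- c("rna_counts", "dnam_beta", "dnam_counts")

#' Construct a validated bulk data object
#'
#' A bulk object carries a features x samples value matrix plus a modality
#' tag. For `"dnam_counts"` the values are methylated read counts and a
#' parallel `coverage` matrix holds total read counts per locus and sample.
#'
#' @param values Numeric matrix, features in rows (rownames required),
#'   samples in columns (colnames required). For `"dnam_counts"` these are
#'   methylated counts.
#' @param modality One of `"rna_counts"`, `"dnam_beta"`, `"dnam_counts"`.
#' @param coverage Total-count matrix, same shape and dimnames as `values`;
#'   required for (and only for) `"dnam_counts"`.
#'
#' @return A list of class `"emixed_bulk"` with elements `values`,
#'   `modality` and (for counts) `coverage`.
#' @export
bulk_matrix <- function(values, modality = MODALITIES, coverage = NULL) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("bulk matrix needs feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature identifiers in bulk matrix: ",
         paste(utils::head(unique(rownames(values)[duplicated(rownames(values))]), 3),
               collapse = ", "))
  if (ncol(values) < 1L) stop("bulk matrix has no samples")
  drop <- !stats::complete.cases(values)
  if (is.null(coverage) && any(drop)) {
    emixed_log("WARN", sum(drop), " feature row(s) with missing values dropped")
    values <- values[!drop, , drop = FALSE]
  }
  if (!nrow(values)) stop("bulk matrix has no usable features")
  if (modality == "rna_counts") {
    if (any(values < 0))
      stop("negative RNA count at ", .first_bad_cell(values, values < 0))
    if (any(colSums(values) <= 0))
      stop("sample(s) with zero total counts: ",
           paste(colnames(values)[colSums(values) <= 0], collapse = ", "))
    if (any(values != floor(values)))
      emixed_log("WARN", "non-integer RNA values accepted as-is; ",
                 "the model is defined for raw counts")
  } else if (modality == "dnam_beta") {
    if (any(values < 0 | values > 1))
      stop("beta value out of range [0,1] at ",
           .first_bad_cell(values, values < 0 | values > 1))
  } else { # dnam_counts
    if (is.null(coverage))
      stop("modality 'dnam_counts' requires a coverage matrix")
    coverage <- as.matrix(coverage)
    storage.mode(coverage) <- "double"
    if (!identical(dim(values), dim(coverage)))
      stop("shape mismatch between methylated (", nrow(values), "x",
           ncol(values), ") and coverage (", nrow(coverage), "x",
           ncol(coverage), ") matrices")
    if (!identical(rownames(values), rownames(coverage)) ||
        !identical(colnames(values), colnames(coverage)))
      stop("dimnames of methylated and coverage matrices differ")
    drop <- !(stats::complete.cases(values) & stats::complete.cases(coverage))
    if (any(drop)) {
      emixed_log("WARN", sum(drop), " locus row(s) with missing values dropped")
      values <- values[!drop, , drop = FALSE]
      coverage <- coverage[!drop, , drop = FALSE]
    }
    if (any(coverage < 0))
      stop("negative coverage at ", .first_bad_cell(coverage, coverage < 0))
    if (any(values < 0 | values > coverage))
      stop("methylated count outside [0, coverage] at ",
           .first_bad_cell(values, values < 0 | values > coverage))
    if (any(values != floor(values)) || any(coverage != floor(coverage)))
      stop("methylation read counts must be integer-valued")
  }
  out <- list(values = values, modality = modality)
  if (modality == "dnam_counts") out$coverage <- coverage
  class(out) <- "emixed_bulk"
  out
}

.first_bad_cell <- function(m, bad) {
  idx <- which(bad, arr.ind = TRUE)[1L, ]
  sprintf("[%s, %s] (value %g)", rownames(m)[idx[1L]], colnames(m)[idx[2L]],
          m[idx[1L], idx[2L]])
}

## delimiter sniffing on the header line: comma wins only if it out-counts tab
.detect_sep <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_comma <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_comma > n_tab) "," else "\t"
}

#' Read a delimited numeric matrix with feature rownames
#'
#' Lower-level reader used by [read_bulk_matrix()] and suitable for
#' reference matrices (cell types in columns). The first column holds
#' feature identifiers; the header row holds column labels.
#'
#' @param path File path (TSV by default; comma auto-detected).
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2L)
    stop("malformed matrix file (need a feature-ID column plus >= 1 data column): ",
         path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate feature identifiers in ", path, ": ",
         paste(utils::head(unique(ids[duplicated(ids)]), 3), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric values in ", path)
  rownames(m) <- ids
  m
}

#' Write a numeric matrix as delimited text with a feature-ID column
#'
#' Inverse of [read_matrix_file()]: first column `feature`, header row of
#' column labels, tab-separated, full double precision.
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output file path.
#' @export
write_matrix_file <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(feature = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read bulk data from delimited text
#'
#' @param path Path to the bulk matrix (for `"dnam_counts"`, the methylated
#'   counts).
#' @param modality One of `"rna_counts"`, `"dnam_beta"`, `"dnam_counts"`.
#' @param coverage_path For `"dnam_counts"`, path to the parallel total
#'   coverage matrix (same shape and dimnames).
#' @return An `"emixed_bulk"` object (see [bulk_matrix()]).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write.table(cbind(gene = c("g1", "g2"), s1 = c(5, 3), s2 = c(0, 7)),
#'             tf, sep = "\t", quote = FALSE, row.names = FALSE)
#' b <- read_bulk_matrix(tf, "rna_counts")
#' dim(b$values)
#' @export
read_bulk_matrix <- function(path, modality = MODALITIES, coverage_path = NULL) {
  modality <- match.arg(modality)
  values <- read_matrix_file(path)
  coverage <- NULL
  if (modality == "dnam_counts") {
    if (is.null(coverage_path))
      stop("modality 'dnam_counts' requires coverage_path")
    coverage <- read_matrix_file(coverage_path)
  }
  bulk_matrix(values, modality, coverage)
}

#' Match reference features against bulk features
#'
#' Returns the intersection of the two identifier sets, kept in reference
#' order, together with a small report of how many identifiers were dropped
#' on each side. Matching is by exact string identity; deconvolution then
#' uses only the shared features.
#'
#' @param ref_features Character vector of reference feature identifiers.
#' @param bulk An `"emixed_bulk"` object, or a matrix with feature rownames,
#'   or a plain character vector of bulk feature identifiers.
#' @return A list with `features` (shared identifiers, reference order),
#'   `ref_index` and `bulk_index` (integer positions into each input), and
#'   `report` (counts of kept/dropped identifiers).
#' @export
align_features <- function(ref_features, bulk) {
  bulk_features <-
    if (inherits(bulk, "emixed_bulk")) rownames(bulk$values)
    else if (is.matrix(bulk)) rownames(bulk)
    else as.character(bulk)
  stopifnot(length(ref_features) >= 1L, length(bulk_features) >= 1L)
  shared <- ref_features[ref_features %in% bulk_features]
  if (!length(shared))
    stop("no shared features between reference (e.g. ",
         paste(utils::head(ref_features, 3), collapse = ", "),
         ") and bulk (e.g. ",
         paste(utils::head(bulk_features, 3), collapse = ", "), ")")
  report <- list(n_shared = length(shared),
                 n_ref_dropped = length(ref_features) - length(shared),
                 n_bulk_dropped = length(bulk_features) - length(shared))
  if (report$n_ref_dropped || report$n_bulk_dropped)
    emixed_log("INFO", "feature alignment: ", report$n_shared, " shared, ",
               report$n_ref_dropped, " reference-only and ",
               report$n_bulk_dropped, " bulk-only identifiers dropped")
  list(features = shared,
       ref_index = match(shared, ref_features),
       bulk_index = match(shared, bulk_features),
       report = report)
}

#' Validate a cell-fraction matrix
#'
#' Checks that rows (samples) are non-negative and sum to one within
#' `tol`; invoked by the writers and integrators.
#'
#' @param fractions Numeric matrix, samples x cell types, with dimnames.
#' @param tol Simplex tolerance.
#' @return The matrix, invisibly, after validation.
#' @export
validate_fractions <- function(fractions, tol = 1e-9) {
  fractions <- as.matrix(fractions)
  if (is.null(rownames(fractions)) || is.null(colnames(fractions)))
    stop("fraction matrix needs sample rownames and cell-type colnames")
  if (any(fractions < -tol))
    stop("negative cell fraction at ",
         .first_bad_cell(fractions, fractions < -tol))
  rs <- rowSums(fractions)
  if (any(abs(rs - 1) > tol))
    stop("fraction rows must sum to 1; worst deviation ",
         format(max(abs(rs - 1))), " in sample ",
         rownames(fractions)[which.max(abs(rs - 1))])
  invisible(fractions)
}

#' Write cell fractions to TSV
#'
#' Samples as rows, cell types as columns, full double precision so that
#' a read-back reproduces the input exactly (to ~1e-15 relative error).
#'
#' @param fractions Samples x cell-types matrix (rows on the simplex).
#' @param path Output file path.
#' @export
write_fractions <- function(fractions, path) {
  validate_fractions(fractions)
  df <- data.frame(sample = rownames(fractions),
                   format(fractions, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cell fractions written by [write_fractions()]
#'
#' @param path Input TSV path.
#' @return Samples x cell-types numeric matrix.
#' @export
read_fractions <- function(path) {
  m <- read_matrix_file(path)
  validate_fractions(m, tol = 1e-6)
  m
}
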