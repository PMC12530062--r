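## EM deconvolution of bulk RNA-seq counts.
##
## Generative model, per sample: each of the R_n reads picks a cell type
## from theta (multinomial), then a gene from that type's column of the
## profile matrix A (columns sum to one). Only gene totals X_in are
## observed; aggregating reads to genes gives closed-form E and M steps in
## the gene x cell-type expected allocation psi.

#' Normalize a raw reference profile to a column-stochastic matrix
#'
#' Divides every cell-type column of the raw cell-type-specific expression
#' matrix by its sum, so each column is a probability distribution over
#' genes (the per-read gene emission probabilities of the model). Rows that
#' are zero in every cell type carry no information and are removed with a
#' logged count.
#'
#' @param raw_ref Non-negative matrix, genes x cell types, with gene
#'   rownames and cell-type colnames.
#' @return Column-stochastic profile matrix (column sums exactly 1).
#' @examples
#' raw <- matrix(c(2, 3, 5, 1, 1, 2), ncol = 2,
#'               dimnames = list(paste0("g", 1:3), c("A", "B")))
#' colSums(normalize_profile(raw))
#' @export
normalize_profile <- function(raw_ref) {
  raw_ref <- as.matrix(raw_ref)
  storage.mode(raw_ref) <- "double"
  if (is.null(rownames(raw_ref)) || is.null(colnames(raw_ref)))
    stop("reference needs gene rownames and cell-type colnames")
  if (anyDuplicated(rownames(raw_ref)))
    stop("duplicate gene identifiers in reference")
  drop <- !stats::complete.cases(raw_ref)
  if (any(drop)) {
    emixed_log("WARN", sum(drop), " reference row(s) with missing values dropped")
    raw_ref <- raw_ref[!drop, , drop = FALSE]
  }
  if (any(raw_ref < 0))
    stop("negative reference expression at ",
         .first_bad_cell(raw_ref, raw_ref < 0))
  zero_rows <- rowSums(raw_ref) == 0
  if (any(zero_rows)) {
    emixed_log("INFO", sum(zero_rows), " all-zero gene row(s) removed from reference")
    raw_ref <- raw_ref[!zero_rows, , drop = FALSE]
  }
  if (!nrow(raw_ref)) stop("reference has no non-zero genes")
  cs <- colSums(raw_ref)
  if (any(cs <= 0))
    stop("cell type(s) with zero total expression: ",
         paste(colnames(raw_ref)[cs <= 0], collapse = ", "))
  sweep(raw_ref, 2L, cs, "/")
}

#' E-step of the RNA model for one sample
#'
#' Expected read allocations psi[i, k] = X_i * A[i, k] * theta_k /
#' sum_k'(A[i, k'] * theta_k'): the observed count of gene i split across
#' cell types in proportion to their current explanatory weight. Rows with
#' X_i = 0 are all zero, and row sums reproduce X exactly.
#'
#' @param x_col Non-negative count vector over genes (one sample).
#' @param profile Column-stochastic profile matrix A (genes x cell types).
#' @param theta Current fraction vector on the simplex.
#' @return Matrix psi, genes x cell types.
#' @export
rna_e_step <- function(x_col, profile, theta) {
  .check_theta(theta, ncol(profile))
  if (length(x_col) != nrow(profile))
    stop("length of count vector does not match profile rows")
  if (any(x_col < 0)) stop("negative counts")
  mix <- drop(profile %*% theta)
  bad <- x_col > 0 & mix <= 0
  if (any(bad))
    stop("reference cannot explain observed reads for gene(s): ",
         paste(utils::head(rownames(profile)[bad], 5), collapse = ", "))
  w <- sweep(profile, 2L, theta, "*")
  psi <- w * ifelse(mix > 0, x_col / pmax(mix, .Machine$double.xmin), 0)
  dimnames(psi) <- dimnames(profile)
  psi
}

#' M-step of the RNA model
#'
#' New fractions are the column sums of the expected allocations,
#' normalized by the total read count.
#'
#' @param psi Expected allocation matrix from [rna_e_step()].
#' @return Fraction vector on the simplex.
#' @export
rna_m_step <- function(psi) {
  if (any(psi < 0)) stop("negative responsibilities")
  tot <- sum(psi)
  if (tot <= 0) stop("no reads: all responsibilities are zero")
  colSums(psi) / tot
}

#' Observed-data log-likelihood of the RNA model (up to a constant)
#'
#' `sum_i X_i * log(sum_k A[i,k] * theta_k)`; the multinomial coefficient
#' does not depend on theta and is omitted. Used for convergence
#' diagnostics and to verify the EM monotonicity guarantee.
#'
#' @inheritParams rna_e_step
#' @return Scalar log-likelihood (theta-dependent part).
#' @export
rna_log_likelihood <- function(x_col, profile, theta) {
  .check_theta(theta, ncol(profile))
  mix <- drop(profile %*% theta)
  keep <- x_col > 0
  if (any(keep & mix <= 0))
    stop("log-likelihood undefined: observed reads with zero reference mass")
  sum(x_col[keep] * log(mix[keep]))
}

.check_theta <- function(theta, k) {
  if (length(theta) != k)
    stop("theta has length ", length(theta), ", expected ", k)
  if (any(theta < -1e-12) || abs(sum(theta) - 1) > 1e-6)
    stop("theta must be non-negative and sum to 1")
  invisible(theta)
}

## one sample: multiplicative EM update; E and M collapsed for speed,
## algebraically identical to rna_m_step(rna_e_step(...))
.fit_rna_sample <- function(x, profile, control) {
  K <- ncol(profile)
  keep <- x > 0
  xs <- x[keep]
  A <- profile[keep, , drop = FALSE]
  theta <- rep(1 / K, K)
  total <- sum(xs)
  ll <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mix <- drop(A %*% theta)
    bad <- mix <= 0
    if (any(bad))
      stop("reference cannot explain observed reads for gene(s): ",
           paste(utils::head(rownames(A)[bad], 5), collapse = ", "))
    ll <- c(ll, sum(xs * log(mix)))
    theta_new <- theta * drop(crossprod(A, xs / mix)) / total
    theta_new <- theta_new / sum(theta_new)
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    if (delta < control$tol) { converged <- TRUE; break }
    if (iter >= control$max_iter) break
  }
  names(theta) <- colnames(profile)
  list(theta = theta, iterations = iter, loglik = ll, converged = converged)
}

#' Fit cell-type fractions from bulk RNA-seq counts
#'
#' Runs the closed-form EM for each sample independently: the E-step splits
#' each gene's reads across cell types, the M-step renormalizes the totals.
#' The log-likelihood is concave in theta, so the fit does not depend on
#' initialization (uniform is used). Genes with zero counts in a sample are
#' skipped for that sample; the result is unchanged.
#'
#' @param bulk Bulk RNA counts: an `"emixed_bulk"` object with modality
#'   `"rna_counts"`, or a genes x samples matrix with dimnames.
#' @param reference Raw cell-type-specific expression matrix (genes x cell
#'   types); normalized internally with [normalize_profile()]. A matrix
#'   whose columns already sum to one passes through unchanged.
#' @param cell_sizes Optional positive vector of average transcript yields
#'   per cell type (names matching the reference columns). When supplied,
#'   the transcript fractions are additionally converted to cell fractions
#'   with [adjust_cell_size()].
#' @param control An [emixed_control()] object.
#' @return An `"emixed_fit"` list: `fractions` (samples x cell types, RNA
#'   i.e. transcript fractions), `cell_fractions` (cell-size-adjusted, or
#'   `NULL` when no sizes given), `iterations`, `converged`, `loglik`
#'   (per-sample traces), `modality`, and the alignment `report`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_samples = 4, n_genes = 60,
#'                                    depth = 5e4, seed = 7))
#' fit <- fit_rna(sim$rna$bulk, sim$rna$reference)
#' round(fit$fractions, 2)
#' @export
fit_rna <- function(bulk, reference, cell_sizes = NULL,
                    control = emixed_control()) {
  if (inherits(bulk, "emixed_bulk")) {
    if (bulk$modality != "rna_counts")
      stop("fit_rna needs modality 'rna_counts', got '", bulk$modality, "'")
  } else {
    bulk <- bulk_matrix(bulk, "rna_counts")
  }
  profile <- normalize_profile(reference)
  aln <- align_features(rownames(profile), bulk)
  profile <- normalize_profile(profile[aln$ref_index, , drop = FALSE])
  x <- bulk$values[aln$bulk_index, , drop = FALSE]
  if (any(colSums(x) <= 0))
    stop("sample(s) with zero counts on the shared features: ",
         paste(colnames(x)[colSums(x) <= 0], collapse = ", "))
  .warn_degenerate_profile(profile)
  fits <- lapply(seq_len(ncol(x)), function(j)
    .fit_rna_sample(x[, j], profile, control))
  out <- .collect_fits(fits, colnames(x), colnames(profile))
  out$modality <- "rna_counts"
  out$report <- aln$report
  if (!is.null(cell_sizes)) {
    s <- .match_cell_sizes(cell_sizes, colnames(profile))
    out$cell_sizes <- s
    out$cell_fractions <- t(apply(out$fractions, 1L, adjust_cell_size, S = s))
    dimnames(out$cell_fractions) <- dimnames(out$fractions)
  }
  out
}

.warn_degenerate_profile <- function(profile) {
  if (ncol(profile) < 2L) return(invisible())
  spread <- max(abs(profile - rowMeans(profile)))
  if (spread < 1e-12)
    emixed_log("WARN", "all reference columns are identical: ",
               "fractions are not identifiable and the likelihood is flat")
  invisible()
}

.collect_fits <- function(fits, sample_names, type_names) {
  theta <- do.call(rbind, lapply(fits, `[[`, "theta"))
  dimnames(theta) <- list(sample_names, type_names)
  structure(list(fractions = theta,
                 cell_fractions = NULL,
                 iterations = vapply(fits, `[[`, integer(1), "iterations"),
                 converged = vapply(fits, `[[`, logical(1), "converged"),
                 loglik = stats::setNames(lapply(fits, `[[`, "loglik"),
                                          sample_names)),
            class = "emixed_fit")
}

.match_cell_sizes <- function(cell_sizes, types) {
  if (any(cell_sizes <= 0) || any(!is.finite(cell_sizes)))
    stop("cell sizes must be strictly positive and finite")
  if (!is.null(names(cell_sizes))) {
    missing <- setdiff(types, names(cell_sizes))
    if (length(missing))
      stop("cell sizes missing for type(s): ", paste(missing, collapse = ", "))
    cell_sizes <- cell_sizes[types]
  } else if (length(cell_sizes) != length(types)) {
    stop("cell sizes must have one value per cell type")
  }
  stats::setNames(as.numeric(cell_sizes), types)
}

#' Convert transcript (RNA) fractions to cell fractions
#'
#' The EM fractions describe the share of transcripts per cell type; cell
#' types with larger cells contribute more transcripts per cell. Dividing
#' by the cell-size vector S and renormalizing gives the share of cells:
#' `theta_k^cell = (theta_k / S_k) / sum_k'(theta_k' / S_k')`. The formula
#' is invariant to rescaling S.
#'
#' @param theta Fraction vector on the simplex.
#' @param S Strictly positive cell-size vector, one value per cell type.
#' @return Cell-fraction vector on the simplex.
#' @examples
#' adjust_cell_size(c(0.5, 0.5), c(2, 1))   # c(1/3, 2/3)
#' @export
adjust_cell_size <- function(theta, S) {
  if (length(S) != length(theta))
    stop("cell-size vector length must match theta")
  if (any(S <= 0)) stop("cell sizes must be strictly positive")
  .check_theta(theta, length(theta))
  w <- theta / S
  w / sum(w)
}

#' Derive a cell-size vector from per-type library sizes
#'
#' Cell size is the average transcript yield of one cell of each type,
#' estimated by the average library size observed for that type. The values
#' are rescaled to mean one; the scale cancels in [adjust_cell_size()], so
#' only the ratios matter.
#'
#' @param ref_library_sizes Positive vector, one average library size per
#'   cell type (names kept if present).
#' @return Cell-size vector with mean 1.
#' @export
estimate_cell_sizes <- function(ref_library_sizes) {
  if (any(ref_library_sizes <= 0) || any(!is.finite(ref_library_sizes)))
    stop("library sizes must be strictly positive and finite")
  ref_library_sizes / mean(ref_library_sizes)
}
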