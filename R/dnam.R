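## EM deconvolution of bulk DNA methylation.
##
## Generative model, per sample: each DNA molecule covering locus g picks a
## cell type from theta (multinomial), then a methylation status from that
## type's Bernoulli probability pi[g, k]. Sequencing data observe methylated
## / total molecule counts per locus; arrays observe the methylated fraction
## (beta value), which plugs into the same M-step under a large constant
## coverage.

#' Clip a methylation signature away from 0 and 1
#'
#' The E-step divides by mixtures of `pi` and `1 - pi`; reference
#' signatures routinely contain exact 0s and 1s, which would make those
#' denominators vanish for boundary fraction vectors. Entries are moved
#' into `[eps, 1 - eps]`.
#'
#' @param pi Matrix of methylation probabilities in `[0, 1]`, loci x cell
#'   types, with locus rownames and cell-type colnames.
#' @param eps Clipping bound (default 1e-6).
#' @return Clipped signature matrix.
#' @export
clip_signature <- function(pi, eps = 1e-6) {
  pi <- as.matrix(pi)
  storage.mode(pi) <- "double"
  if (is.null(rownames(pi)) || is.null(colnames(pi)))
    stop("signature needs locus rownames and cell-type colnames")
  if (anyDuplicated(rownames(pi)))
    stop("duplicate locus identifiers in signature")
  drop <- !stats::complete.cases(pi)
  if (any(drop)) {
    emixed_log("WARN", sum(drop), " signature row(s) with missing values dropped")
    pi <- pi[!drop, , drop = FALSE]
  }
  if (any(pi < 0 | pi > 1))
    stop("signature value outside [0,1] at ",
         .first_bad_cell(pi, pi < 0 | pi > 1))
  stopifnot(eps > 0, eps < 0.5)
  pmin(pmax(pi, eps), 1 - eps)
}

#' E-step of the methylation model for one sample
#'
#' For a methylated molecule at locus g, the posterior cell-type weights
#' are `psi1[g, k] = theta_k * pi[g, k] / sum_i theta_i * pi[g, i]`; for an
#' unmethylated molecule the same with `1 - pi`. Each row of `psi1` and
#' `psi0` is a probability vector over cell types.
#'
#' @param pi Clipped signature matrix (loci x cell types).
#' @param theta Current fraction vector on the simplex.
#' @return List with matrices `psi1` and `psi0` (loci x cell types).
#' @export
dnam_e_step <- function(pi, theta) {
  .check_theta(theta, ncol(pi))
  w1 <- sweep(pi, 2L, theta, "*")
  w0 <- sweep(1 - pi, 2L, theta, "*")
  d1 <- rowSums(w1)
  d0 <- rowSums(w0)
  if (any(d1 <= 0) || any(d0 <= 0))
    stop("degenerate E-step denominator; clip the signature first")
  list(psi1 = w1 / d1, psi0 = w0 / d0)
}

#' M-step of the methylation model, sequencing data
#'
#' New fractions proportional to the expected number of molecules assigned
#' to each cell type: `sum_g psi1[g, k] * meth_g + psi0[g, k] *
#' (cov_g - meth_g)`, normalized over cell types.
#'
#' @param psi Output of [dnam_e_step()].
#' @param meth Methylated molecule counts per locus.
#' @param cov Total coverage per locus.
#' @return Fraction vector on the simplex.
#' @export
dnam_m_step_seq <- function(psi, meth, cov) {
  if (any(cov < 0) || any(meth < 0) || any(meth > cov))
    stop("need 0 <= meth <= cov")
  if (sum(cov) <= 0) stop("all loci have zero coverage")
  num <- drop(crossprod(psi$psi1, meth) + crossprod(psi$psi0, cov - meth))
  num / sum(num)
}

#' M-step of the methylation model, array beta values
#'
#' Identical to [dnam_m_step_seq()] with the beta value standing in for the
#' methylated fraction under a large constant coverage: `theta_k
#' proportional to sum_g psi1[g, k] * beta_g + psi0[g, k] * (1 - beta_g)`.
#'
#' @param psi Output of [dnam_e_step()].
#' @param beta Beta values in `[0, 1]` per locus.
#' @return Fraction vector on the simplex.
#' @export
dnam_m_step_array <- function(psi, beta) {
  if (any(beta < 0 | beta > 1)) stop("beta values must lie in [0,1]")
  num <- drop(crossprod(psi$psi1, beta) + crossprod(psi$psi0, 1 - beta))
  num / sum(num)
}

#' Observed-data log-likelihood of the methylation model
#'
#' `sum_g meth_g * log(sum_k theta_k pi[g,k]) + (cov_g - meth_g) *
#' log(sum_k theta_k (1 - pi[g,k]))`. For array data, `beta` and `1 - beta`
#' replace the count weights (the likelihood per unit coverage). Used for
#' convergence diagnostics and monotonicity checks.
#'
#' @param meth Methylated counts per locus, or beta values when `cov` is
#'   `NULL`.
#' @param pi Clipped signature matrix.
#' @param theta Fraction vector on the simplex.
#' @param cov Total coverage per locus; `NULL` for array (beta) input.
#' @return Scalar log-likelihood (theta-dependent part).
#' @export
dnam_log_likelihood <- function(meth, pi, theta, cov = NULL) {
  .check_theta(theta, ncol(pi))
  if (is.null(cov)) {
    if (any(meth < 0 | meth > 1)) stop("beta values must lie in [0,1]")
    w1 <- meth; w0 <- 1 - meth
  } else {
    if (any(meth < 0) || any(meth > cov)) stop("need 0 <= meth <= cov")
    w1 <- meth; w0 <- cov - meth
  }
  p1 <- drop(pi %*% theta)
  p0 <- drop((1 - pi) %*% theta)
  sum(w1 * log(p1) + w0 * log(p0))
}

#' Joint quantile normalization of signature and bulk methylation
#'
#' Pools the cell-type columns of the signature with the sample columns of
#' the bulk matrix and quantile-normalizes all columns together: every
#' column's values are replaced by the mean of the order statistics across
#' the pooled columns at matching ranks, tied values receiving the mean of
#' their spanned quantiles. Afterwards all columns share the same sorted
#' values. Outputs are re-clipped to `[0, 1]`.
#'
#' @param ref Signature matrix (loci x cell types), values in `[0, 1]`.
#' @param bulk Bulk beta matrix (loci x samples), same loci in the same
#'   order, values in `[0, 1]`.
#' @return List with the normalized `ref` and `bulk` matrices.
#' @export
joint_quantile_normalize <- function(ref, bulk) {
  ref <- as.matrix(ref); bulk <- as.matrix(bulk)
  if (!identical(rownames(ref), rownames(bulk)))
    stop("signature and bulk must share identical loci in identical order")
  if (any(ref < 0 | ref > 1) || any(bulk < 0 | bulk > 1))
    stop("quantile normalization expects values in [0,1]")
  pooled <- cbind(ref, bulk)
  qn <- limma::normalizeQuantiles(pooled, ties = TRUE)
  qn <- pmin(pmax(qn, 0), 1)
  dimnames(qn) <- dimnames(pooled)
  list(ref = qn[, seq_len(ncol(ref)), drop = FALSE],
       bulk = qn[, ncol(ref) + seq_len(ncol(bulk)), drop = FALSE])
}

## one sample, sequencing or array; E and M collapsed (multiplicative form),
## algebraically identical to dnam_m_step_*(dnam_e_step(...))
.fit_dnam_sample <- function(m, u, pi, control) {
  K <- ncol(pi)
  keep <- (m + u) > 0            # zero-coverage loci carry no information
  m <- m[keep]; u <- u[keep]
  pi <- pi[keep, , drop = FALSE]
  if (!length(m)) stop("all loci have zero coverage in a sample")
  theta <- rep(1 / K, K)
  total <- sum(m + u)
  ll <- numeric(0)
  converged <- FALSE
  iter <- 0L
  one_minus_pi <- 1 - pi
  repeat {
    iter <- iter + 1L
    p1 <- drop(pi %*% theta)
    p0 <- drop(one_minus_pi %*% theta)
    ll <- c(ll, sum(m * log(p1) + u * log(p0)))
    num <- theta * drop(crossprod(pi, m / p1) + crossprod(one_minus_pi, u / p0))
    theta_new <- num / total
    theta_new <- theta_new / sum(theta_new)
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    if (delta < control$tol) { converged <- TRUE; break }
    if (iter >= control$max_iter) break
  }
  names(theta) <- colnames(pi)
  list(theta = theta, iterations = iter, loglik = ll, converged = converged)
}

#' Fit cell-type fractions from bulk DNA methylation
#'
#' Runs the closed-form EM for each sample independently, with the
#' modality-appropriate M-step: molecule counts for sequencing data, beta
#' values for arrays. For array data the signature and bulk are jointly
#' quantile-normalized first (default on; disable via
#' `emixed_control(quantile_norm = FALSE)`). Loci with zero coverage in a
#' sample are skipped for that sample. No cell-size correction applies:
#' every cell contributes approximately the same number of DNA copies, so
#' molecule fractions are cell fractions.
#'
#' @param bulk An `"emixed_bulk"` object with modality `"dnam_beta"` or
#'   `"dnam_counts"`, or a loci x samples matrix (beta values unless
#'   `coverage` is given, then methylated counts).
#' @param signature Methylation probability matrix (loci x cell types) in
#'   `[0, 1]`; clipped internally with [clip_signature()].
#' @param coverage Optional total-coverage matrix matching `bulk` when
#'   passing plain matrices of counts.
#' @param control An [emixed_control()] object.
#' @return An `"emixed_fit"` list (see [fit_rna()]); `cell_fractions` is
#'   the same matrix as `fractions` since no size correction applies.
#' @examples
#' sim <- simulate_dataset(sim_config(n_samples = 4, n_loci = 120,
#'                                    coverage = 200, seed = 7))
#' fit <- fit_dnam(sim$dnam$beta, sim$dnam$signature)
#' round(fit$fractions, 2)
#' @export
fit_dnam <- function(bulk, signature, coverage = NULL,
                     control = emixed_control()) {
  if (!inherits(bulk, "emixed_bulk")) {
    bulk <- if (is.null(coverage)) bulk_matrix(bulk, "dnam_beta")
            else bulk_matrix(bulk, "dnam_counts", coverage = coverage)
  }
  if (!bulk$modality %in% c("dnam_beta", "dnam_counts"))
    stop("fit_dnam needs a methylation modality, got '", bulk$modality, "'")
  signature <- clip_signature(signature, eps = control$epsilon)
  aln <- align_features(rownames(signature), bulk)
  pi <- signature[aln$ref_index, , drop = FALSE]
  vals <- bulk$values[aln$bulk_index, , drop = FALSE]
  if (bulk$modality == "dnam_beta") {
    if (control$quantile_norm) {
      qn <- joint_quantile_normalize(pi, vals)
      pi <- clip_signature(qn$ref, eps = control$epsilon)
      vals <- qn$bulk
    }
    fits <- lapply(seq_len(ncol(vals)), function(j)
      .fit_dnam_sample(vals[, j], 1 - vals[, j], pi, control))
  } else {
    cov <- bulk$coverage[aln$bulk_index, , drop = FALSE]
    fits <- lapply(seq_len(ncol(vals)), function(j)
      .fit_dnam_sample(vals[, j], cov[, j] - vals[, j], pi, control))
  }
  out <- .collect_fits(fits, colnames(vals), colnames(pi))
  out$cell_fractions <- out$fractions
  out$modality <- bulk$modality
  out$report <- aln$report
  out
}
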