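## Matched multi-omics pseudobulk simulator.
##
## Data are drawn from the same allocation models the estimators fit: RNA
## reads pick a cell type, then a gene; DNA molecules pick a cell type,
## then a Bernoulli methylation status. Marginalizing the per-read /
## per-molecule latents gives a multinomial over genes and a binomial per
## locus, which is how the fast default path samples; a molecule-by-molecule
## path is kept as a slow reference implementation.

#' Simulation configuration
#'
#' Bundles every knob of the matched multi-omics simulator, with defaults
#' describing a moderately hard blood-like mixture: a handful of cell
#' types, block marker structure in the RNA reference, bimodal CpG
#' methylation probabilities, and realistic sequencing depth and coverage.
#'
#' @param n_types Number of cell types K.
#' @param n_genes Number of genes I in the RNA reference.
#' @param n_loci Number of CpG loci G in the methylation signature.
#' @param n_samples Number of bulk samples N.
#' @param alpha Dirichlet concentration for the true fractions; `alpha = 1`
#'   is uniform on the simplex, large `alpha` concentrates near equal
#'   fractions.
#' @param marker_strength Fold elevation of a cell type's marker genes over
#'   the shared baseline in the RNA reference; 1 means no signal.
#' @param beta_a,beta_b Beta-distribution parameters for the methylation
#'   probability of a type's marker loci; the default `Beta(0.3, 0.3)` is
#'   bimodal near 0 and 1, as CpG methylation is.
#' @param depth Sequencing depth R_n per RNA sample (scalar or length-N).
#' @param coverage Read coverage D per methylation locus (scalar or
#'   length-G); see `coverage_dist`.
#' @param coverage_dist `"constant"` (every locus gets `coverage`) or
#'   `"poisson"` (per-locus, per-sample Poisson with mean `coverage`), the
#'   latter to stress the constant-coverage assumption behind the array
#'   M-step.
#' @param cell_sizes Average transcripts per cell of each type (length
#'   `n_types`); default all ones. Non-uniform sizes make transcript
#'   fractions differ from cell fractions, exercising the size correction.
#' @param noise_rna,noise_dnam Reference-mismatch noise: standard deviation
#'   of a truncated Gaussian perturbation applied to the reference handed
#'   to the estimator (the bulk data are still generated from the clean
#'   reference). For RNA the sd is relative to the mean reference entry;
#'   for DNAm it is on the probability scale. 0 disables.
#' @param seed Integer seed; recorded in the config and every simulated
#'   dataset.
#' @return A list of class `"emixed_sim_config"`.
#' @export
sim_config <- function(n_types = 3L, n_genes = 200L, n_loci = 500L,
                       n_samples = 50L, alpha = 1, marker_strength = 20,
                       beta_a = 0.3, beta_b = 0.3, depth = 1e5,
                       coverage = 1000, coverage_dist = c("constant", "poisson"),
                       cell_sizes = NULL, noise_rna = 0, noise_dnam = 0,
                       seed = 1L) {
  coverage_dist <- match.arg(coverage_dist)
  stopifnot(n_types >= 1, n_genes >= n_types, n_loci >= n_types,
            n_samples >= 1, alpha > 0, marker_strength >= 1,
            beta_a > 0, beta_b > 0, all(depth > 0), all(coverage >= 0),
            noise_rna >= 0, noise_dnam >= 0)
  if (is.null(cell_sizes)) cell_sizes <- rep(1, n_types)
  stopifnot(length(cell_sizes) == n_types, all(cell_sizes > 0))
  structure(list(n_types = as.integer(n_types), n_genes = as.integer(n_genes),
                 n_loci = as.integer(n_loci), n_samples = as.integer(n_samples),
                 alpha = alpha, marker_strength = marker_strength,
                 beta_a = beta_a, beta_b = beta_b, depth = depth,
                 coverage = coverage, coverage_dist = coverage_dist,
                 cell_sizes = cell_sizes, noise_rna = noise_rna,
                 noise_dnam = noise_dnam, seed = as.integer(seed)),
            class = "emixed_sim_config")
}

.type_names <- function(K) paste0("ct", seq_len(K))
.sample_names <- function(N) paste0("sample", seq_len(N))

.maybe_seed <- function(seed) if (!is.null(seed)) set.seed(seed)

#' Draw ground-truth cell fractions
#'
#' One fraction vector per sample from a symmetric Dirichlet with
#' concentration `cfg$alpha` (sampled via normalized Gamma draws).
#'
#' @param cfg An [sim_config()] object.
#' @param seed Optional seed; `NULL` continues the current random stream.
#' @return Samples x cell-types matrix with rows on the simplex.
#' @export
simulate_fractions <- function(cfg, seed = cfg$seed) {
  .maybe_seed(seed)
  g <- matrix(stats::rgamma(cfg$n_samples * cfg$n_types, shape = cfg$alpha),
              cfg$n_samples, cfg$n_types)
  theta <- g / rowSums(g)
  dimnames(theta) <- list(.sample_names(cfg$n_samples),
                          .type_names(cfg$n_types))
  theta
}

#' Simulate an RNA reference with block marker structure
#'
#' Each gene receives a shared baseline expression level (Gamma-distributed
#' across genes); the genes are split into K equal blocks and the block for
#' cell type k is elevated `marker_strength`-fold in that type's column.
#' With `marker_strength = 1` all columns are identical (a degenerate,
#' uninformative reference for negative controls). Per-type library sizes
#' proportional to the configured cell sizes are emitted alongside, for
#' [estimate_cell_sizes()].
#'
#' @inheritParams simulate_fractions
#' @return List with `reference` (raw genes x cell-types matrix) and
#'   `library_sizes` (named per-type vector).
#' @export
simulate_reference_rna <- function(cfg, seed = cfg$seed) {
  .maybe_seed(seed)
  K <- cfg$n_types; I <- cfg$n_genes
  baseline <- stats::rgamma(I, shape = 2, rate = 2) + 0.05
  ref <- matrix(baseline, I, K)
  block <- rep(seq_len(K), each = ceiling(I / K))[seq_len(I)]
  for (k in seq_len(K)) ref[block == k, k] <- ref[block == k, k] * cfg$marker_strength
  dimnames(ref) <- list(paste0("gene", seq_len(I)), .type_names(K))
  lib <- stats::setNames(cfg$cell_sizes * 1e4, .type_names(K))
  list(reference = ref, library_sizes = lib)
}

#' Simulate bulk RNA-seq counts from fractions and a reference
#'
#' Per sample, the transcript-level fractions are the cell fractions scaled
#' by cell size, `theta_k S_k / sum(theta S)` (the inverse of
#' [adjust_cell_size()]); gene counts are then multinomial with
#' probabilities `A %*% transcript_fractions`, `A` the column-normalized
#' reference. `method = "read"` instead draws every read's cell type and
#' gene explicitly — the literal generative process — as a slow
#' cross-check of the marginalization.
#'
#' @param theta Samples x cell-types matrix of true cell fractions.
#' @param reference Raw RNA reference (genes x cell types).
#' @param cell_sizes Positive per-type vector S; default all ones.
#' @param depth Total reads per sample (scalar or length-N).
#' @param seed Optional seed; `NULL` continues the current stream.
#' @param method `"multinomial"` (exact marginal, default) or `"read"`.
#' @return An `"emixed_bulk"` object with modality `"rna_counts"`.
#' @export
simulate_bulk_rna <- function(theta, reference, cell_sizes = NULL,
                              depth = 1e5, seed = NULL,
                              method = c("multinomial", "read")) {
  method <- match.arg(method)
  .maybe_seed(seed)
  A <- normalize_profile(reference)
  K <- ncol(A); N <- nrow(theta)
  if (is.null(cell_sizes)) cell_sizes <- rep(1, K)
  stopifnot(ncol(theta) == K, all(cell_sizes > 0))
  depth <- rep(depth, length.out = N)
  counts <- matrix(0, nrow(A), N,
                   dimnames = list(rownames(A), rownames(theta)))
  for (n in seq_len(N)) {
    tt <- theta[n, ] * cell_sizes
    tt <- tt / sum(tt)                       # transcript fractions
    if (method == "multinomial") {
      counts[, n] <- stats::rmultinom(1, depth[n], drop(A %*% tt))
    } else {
      z <- sample.int(K, depth[n], replace = TRUE, prob = tt)
      for (k in seq_len(K)) {
        nk <- sum(z == k)
        if (nk) counts[, n] <- counts[, n] + drop(stats::rmultinom(1, nk, A[, k]))
      }
    }
  }
  bulk_matrix(counts, "rna_counts")
}

#' Simulate a methylation signature with per-type marker loci
#'
#' Loci are split into K equal blocks. At a locus in cell type k's block,
#' type k's methylation probability is drawn from `Beta(beta_a, beta_b)`
#' (bimodal near 0/1 by default, i.e. informative), while all other types
#' share a common baseline probability near 0.5 (`Beta(5, 5)`), so each
#' locus discriminates exactly one type from the rest.
#'
#' @inheritParams simulate_fractions
#' @return Loci x cell-types matrix of methylation probabilities.
#' @export
simulate_reference_dnam <- function(cfg, seed = cfg$seed) {
  .maybe_seed(seed)
  K <- cfg$n_types; G <- cfg$n_loci
  baseline <- stats::rbeta(G, 5, 5)
  pi <- matrix(baseline, G, K)
  block <- rep(seq_len(K), each = ceiling(G / K))[seq_len(G)]
  for (k in seq_len(K))
    pi[block == k, k] <- stats::rbeta(sum(block == k), cfg$beta_a, cfg$beta_b)
  dimnames(pi) <- list(paste0("cpg", seq_len(G)), .type_names(K))
  pi
}

#' Simulate bulk DNA methylation counts and beta values
#'
#' Per locus and sample, the methylated count is binomial with size
#' `coverage` and success probability `sum_k theta_k pi[g, k]` — the exact
#' marginal of drawing each molecule's cell type from theta and then its
#' methylation status from that type's Bernoulli probability. `method =
#' "molecule"` performs those per-molecule draws explicitly as a slow
#' reference implementation. Beta values are methylated / coverage where
#' coverage is positive.
#'
#' @param theta Samples x cell-types matrix of true fractions.
#' @param pi Methylation signature (loci x cell types), values in `[0, 1]`.
#' @param coverage Scalar, length-G vector, or G x N matrix of total
#'   molecule counts.
#' @param seed Optional seed; `NULL` continues the current stream.
#' @param method `"binomial"` (default) or `"molecule"`.
#' @return List with `counts` (an `"emixed_bulk"`, modality
#'   `"dnam_counts"`) and `beta` (an `"emixed_bulk"`, modality
#'   `"dnam_beta"`; zero-coverage cells get beta 0).
#' @export
simulate_bulk_dnam <- function(theta, pi, coverage = 100, seed = NULL,
                               method = c("binomial", "molecule")) {
  method <- match.arg(method)
  .maybe_seed(seed)
  G <- nrow(pi); K <- ncol(pi); N <- nrow(theta)
  stopifnot(ncol(theta) == K)
  cov <- if (is.matrix(coverage)) coverage
         else matrix(rep(coverage, length.out = G), G, N)
  dimnames(cov) <- list(rownames(pi), rownames(theta))
  meth <- matrix(0, G, N, dimnames = dimnames(cov))
  for (n in seq_len(N)) {
    if (method == "binomial") {
      p <- drop(pi %*% theta[n, ])
      meth[, n] <- stats::rbinom(G, cov[, n], p)
    } else {
      for (g in seq_len(G)) {
        D <- cov[g, n]
        if (D > 0) {
          z <- sample.int(K, D, replace = TRUE, prob = theta[n, ])
          meth[g, n] <- sum(stats::rbinom(D, 1L, pi[g, z]))
        }
      }
    }
  }
  beta <- ifelse(cov > 0, meth / cov, 0)
  list(counts = bulk_matrix(meth, "dnam_counts", coverage = cov),
       beta = bulk_matrix(beta, "dnam_beta"))
}

#' Perturb an RNA reference with truncated Gaussian noise
#'
#' Adds independent Gaussian noise with standard deviation `sd_rel` times
#' the mean reference entry, truncating at zero, to emulate a mismatched
#' reference (e.g. built from a different cohort or platform).
#'
#' @param reference Raw RNA reference matrix.
#' @param sd_rel Noise sd relative to the mean entry.
#' @param seed Optional seed.
#' @return Perturbed non-negative reference matrix.
#' @export
perturb_reference_rna <- function(reference, sd_rel, seed = NULL) {
  .maybe_seed(seed)
  if (sd_rel <= 0) return(reference)
  noise <- stats::rnorm(length(reference), 0, sd_rel * mean(reference))
  pmax(reference + noise, 0)
}

#' Perturb a methylation signature with truncated Gaussian noise
#'
#' Adds independent Gaussian noise with standard deviation `sd` on the
#' probability scale, clamped back to `[0, 1]`.
#'
#' @param pi Methylation signature matrix.
#' @param sd Noise sd on the probability scale.
#' @param seed Optional seed.
#' @return Perturbed signature in `[0, 1]`.
#' @export
perturb_signature_dnam <- function(pi, sd, seed = NULL) {
  .maybe_seed(seed)
  if (sd <= 0) return(pi)
  pmin(pmax(pi + stats::rnorm(length(pi), 0, sd), 0), 1)
}

#' Simulate a complete matched multi-omics dataset
#'
#' Seeds the random stream once from the config, then draws true
#' fractions, both references, and matched bulk RNA and DNAm data for the
#' same samples. When `noise_rna` / `noise_dnam` are positive, the bulk
#' data come from the clean references while additionally perturbed copies
#' (`reference_noisy`, `signature_noisy`) are emitted for the estimator —
#' the reference-mismatch stress scenario.
#'
#' @param cfg An [sim_config()] object.
#' @return List with `theta` (true fractions), `rna` (list: `reference`,
#'   `reference_noisy` or `NULL`, `library_sizes`, `bulk`), `dnam` (list:
#'   `signature`, `signature_noisy` or `NULL`, `counts`, `coverage`,
#'   `beta`) and `config` (the input config, seed included).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "emixed_sim_config"))
  set.seed(cfg$seed)
  theta <- simulate_fractions(cfg, seed = NULL)
  rna_ref <- simulate_reference_rna(cfg, seed = NULL)
  pi <- simulate_reference_dnam(cfg, seed = NULL)
  bulk_rna <- simulate_bulk_rna(theta, rna_ref$reference,
                                cell_sizes = cfg$cell_sizes,
                                depth = cfg$depth, seed = NULL)
  cov <- switch(cfg$coverage_dist,
                constant = cfg$coverage,
                poisson = matrix(stats::rpois(cfg$n_loci * cfg$n_samples,
                                              rep(cfg$coverage,
                                                  length.out = cfg$n_loci)),
                                 cfg$n_loci, cfg$n_samples))
  bulk_dnam <- simulate_bulk_dnam(theta, pi, coverage = cov, seed = NULL)
  ref_noisy <- if (cfg$noise_rna > 0)
    perturb_reference_rna(rna_ref$reference, cfg$noise_rna) else NULL
  sig_noisy <- if (cfg$noise_dnam > 0)
    perturb_signature_dnam(pi, cfg$noise_dnam) else NULL
  list(theta = theta,
       rna = list(reference = rna_ref$reference,
                  reference_noisy = ref_noisy,
                  library_sizes = rna_ref$library_sizes,
                  bulk = bulk_rna),
       dnam = list(signature = pi, signature_noisy = sig_noisy,
                   counts = bulk_dnam$counts, beta = bulk_dnam$beta),
       config = cfg)
}
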