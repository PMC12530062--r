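# Small builders shared across test files. Log lines go through message(),
# so data-driven constructors are wrapped in suppressMessages where the
# message is not the thing under test.

toy_profile <- function(values, genes = NULL, types = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- types %||% paste0("ct", seq_len(ncol(m)))
  m
}

toy_bulk_rna <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  suppressMessages(bulk_matrix(m, "rna_counts"))
}

toy_signature <- function(values, loci = NULL, types = NULL) {
  m <- as.matrix(values)
  rownames(m) <- loci %||% paste0("cpg", seq_len(nrow(m)))
  colnames(m) <- types %||% paste0("ct", seq_len(ncol(m)))
  m
}

toy_fractions <- function(values, samples = NULL, types = NULL) {
  m <- as.matrix(values)
  rownames(m) <- samples %||% paste0("s", seq_len(nrow(m)))
  colnames(m) <- types %||% paste0("ct", seq_len(ncol(m)))
  m
}

# dense 1-D grid maximizer of a two-type log-likelihood; the independent
# oracle the EM fits are checked against
grid_argmax_theta1 <- function(loglik_of_theta1, step = 1e-4) {
  grid <- seq(step, 1 - step, by = step)
  grid[which.max(vapply(grid, loglik_of_theta1, numeric(1)))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

quiet_fit_rna <- function(...) suppressMessages(fit_rna(...))
quiet_fit_dnam <- function(...) suppressMessages(fit_dnam(...))
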