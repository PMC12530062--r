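#' @export
print.emixed_fit <- function(x, ...) {
  cat("EM deconvolution fit (", x$modality, ")\n", sep = "")
  cat("  samples:    ", nrow(x$fractions), "\n", sep = "")
  cat("  cell types: ", ncol(x$fractions), " (",
      paste(utils::head(colnames(x$fractions), 6), collapse = ", "),
      if (ncol(x$fractions) > 6) ", ..." else "", ")\n", sep = "")
  cat("  converged:  ", sum(x$converged), "/", length(x$converged),
      " samples (median ", stats::median(x$iterations), " iterations)\n",
      sep = "")
  if (!is.null(x$cell_fractions) &&
      !identical(x$cell_fractions, x$fractions))
    cat("  cell-size-adjusted fractions available in $cell_fractions\n")
  cat("  head of $fractions:\n")
  print(utils::head(round(x$fractions, 4), 4))
  invisible(x)
}

#' @export
print.emixed_bulk <- function(x, ...) {
  cat("Bulk matrix (", x$modality, "): ", nrow(x$values), " features x ",
      ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' @export
print.emixed_multi <- function(x, ...) {
  cat("Integrated multi-omics cell fractions\n")
  cat("  samples: ", nrow(x$integrated), " (",
      sum(x$availability$rna & x$availability$dnam), " with both modalities)\n",
      sep = "")
  cat("  RNA weight: ", x$weight, "\n", sep = "")
  cat("  head of $integrated:\n")
  print(utils::head(round(x$integrated, 4), 4))
  invisible(x)
}

#' @export
print.emixed_sim_config <- function(x, ...) {
  cat("Simulation config: K=", x$n_types, ", I=", x$n_genes, " genes, G=",
      x$n_loci, " loci, N=", x$n_samples, " samples, seed=", x$seed, "\n",
      sep = "")
  invisible(x)
}
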