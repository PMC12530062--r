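## Multi-omics integration and agreement metrics.
##
## Both omics layers of a tissue sample share one true cell composition, so
## the modality-specific estimates are two noisy reads of the same quantity;
## their unweighted average is the integrated estimate.

.as_fraction_matrix <- function(x, prefer_cell = TRUE) {
  if (inherits(x, "emixed_fit")) {
    if (prefer_cell && !is.null(x$cell_fractions)) return(x$cell_fractions)
    return(x$fractions)
  }
  m <- as.matrix(x)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("fraction matrix needs sample rownames and cell-type colnames")
  m
}

#' Integrate RNA- and DNAm-derived cell fractions
#'
#' For every sample present in both inputs, takes the unweighted mean of
#' the two modality estimates over the shared cell types, then renormalizes
#' to the simplex (a no-op when both inputs cover the same type set).
#' Samples present in only one modality carry that modality's estimate and
#' are flagged in `availability`.
#'
#' When a fit object from [fit_rna()] carries cell-size-adjusted fractions,
#' those are used (set `use_cell_fractions = FALSE` to average raw
#' transcript fractions instead); DNAm fractions need no adjustment.
#'
#' @param rna RNA-derived fractions: samples x cell-types matrix or an
#'   `"emixed_fit"` from [fit_rna()].
#' @param dnam DNAm-derived fractions: matrix or an `"emixed_fit"` from
#'   [fit_dnam()].
#' @param weight Weight on the RNA estimate, in `[0, 1]`; the DNAm estimate
#'   receives `1 - weight`. Default 0.5 (plain average).
#' @param use_cell_fractions Use the cell-size-adjusted RNA fractions when
#'   available (default `TRUE`).
#' @return A list of class `"emixed_multi"`: `integrated` (samples x shared
#'   cell types, rows on the simplex), `rna` and `dnam` (the aligned
#'   inputs), and `availability` (data frame flagging which modalities
#'   informed each sample).
#' @examples
#' rna <- matrix(c(0.7, 0.2, 0.1), 1, dimnames = list("s1", c("A", "B", "C")))
#' dnam <- matrix(c(0.5, 0.3, 0.2), 1, dimnames = list("s1", c("A", "B", "C")))
#' integrate_fractions(rna, dnam)$integrated
#' @export
integrate_fractions <- function(rna, dnam, weight = 0.5,
                                use_cell_fractions = TRUE) {
  stopifnot(is.numeric(weight), length(weight) == 1L, weight >= 0, weight <= 1)
  r <- .as_fraction_matrix(rna, prefer_cell = use_cell_fractions)
  d <- .as_fraction_matrix(dnam, prefer_cell = use_cell_fractions)
  types <- intersect(colnames(r), colnames(d))
  if (!length(types))
    stop("no shared cell types between modalities (RNA: ",
         paste(utils::head(colnames(r), 3), collapse = ", "), "; DNAm: ",
         paste(utils::head(colnames(d), 3), collapse = ", "), ")")
  samples <- union(rownames(r), rownames(d))
  both <- intersect(rownames(r), rownames(d))
  if (!length(both))
    stop("no shared samples between modalities")
  renorm <- function(m) m / rowSums(m)
  r2 <- renorm(r[intersect(samples, rownames(r)), types, drop = FALSE])
  d2 <- renorm(d[intersect(samples, rownames(d)), types, drop = FALSE])
  integrated <- matrix(NA_real_, length(samples), length(types),
                       dimnames = list(samples, types))
  integrated[rownames(r2), ] <- weight * r2
  only_d <- setdiff(rownames(d2), rownames(r2))
  integrated[only_d, ] <- d2[only_d, , drop = FALSE]
  integrated[both, ] <- integrated[both, , drop = FALSE] +
    (1 - weight) * d2[both, , drop = FALSE]
  only_r <- setdiff(rownames(r2), rownames(d2))
  integrated[only_r, ] <- r2[only_r, , drop = FALSE]
  integrated <- renorm(integrated)
  availability <- data.frame(sample = samples,
                             rna = samples %in% rownames(r),
                             dnam = samples %in% rownames(d))
  if (any(!availability$rna | !availability$dnam))
    emixed_log("INFO", sum(!availability$rna | !availability$dnam),
               " sample(s) present in only one modality")
  structure(list(integrated = integrated, rna = r2, dnam = d2,
                 weight = weight, availability = availability),
            class = "emixed_multi")
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between two vectors: `2 * cov(x, y) / (var(x) + var(y) +
#' (mean(x) - mean(y))^2)`, with population (1/n) moments as in Lin's
#' original definition. Unlike Pearson correlation it penalizes location
#' and scale shifts, so `ccc(x, x + c) < 1` for any `c != 0`.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @param na_undefined If both inputs are constant the coefficient is
#'   undefined; return `NaN` with a warning (default) or raise an error.
#' @return Scalar in `[-1, 1]`.
#' @examples
#' ccc(c(1, 2, 3), c(2, 3, 4))   # 4/7
#' @export
ccc <- function(x, y, na_undefined = TRUE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) {
    if (!na_undefined) stop("ccc undefined: both inputs are constant and equal")
    warning("ccc undefined for constant inputs; returning NaN")
    return(NaN)
  }
  2 * sxy / denom
}

#' Mean absolute error
#'
#' @param x,y Numeric vectors of equal length.
#' @return Non-negative scalar `mean(|x - y|)`.
#' @export
mae <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  mean(abs(x - y))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive their average rank);
#' a thin named wrapper over [stats::cor()] so the metric set is uniform.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Scalar in `[-1, 1]`, or `NA` with a warning when an input is
#'   constant.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("spearman correlation undefined for constant input; returning NA")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Score estimated fractions against ground truth
#'
#' Aligns the two matrices on shared samples and cell types, then computes
#' Lin's CCC, MAE and Spearman correlation per cell type across samples,
#' plus the unweighted mean over cell types.
#'
#' @param estimates Samples x cell-types matrix (or `"emixed_fit"`).
#' @param truth Samples x cell-types matrix of true fractions.
#' @return Data frame with one row per shared cell type and a final
#'   `"mean"` row; columns `cell_type`, `ccc`, `mae`, `spearman`, `n`.
#' @export
evaluate_fractions <- function(estimates, truth) {
  est <- .as_fraction_matrix(estimates)
  tru <- .as_fraction_matrix(truth)
  types <- intersect(colnames(est), colnames(tru))
  samples <- intersect(rownames(est), rownames(tru))
  if (!length(types)) stop("no shared cell types between estimates and truth")
  if (length(samples) < 2L)
    stop("need at least 2 shared samples for correlation metrics")
  est <- est[samples, types, drop = FALSE]
  tru <- tru[samples, types, drop = FALSE]
  per_type <- lapply(types, function(ct) {
    e <- est[, ct]; t <- tru[, ct]
    data.frame(cell_type = ct,
               ccc = suppressWarnings(ccc(e, t)),
               mae = mae(e, t),
               spearman = suppressWarnings(spearman_cor(e, t)),
               n = length(samples))
  })
  res <- do.call(rbind, per_type)
  rbind(res, data.frame(cell_type = "mean",
                        ccc = mean(res$ccc), mae = mean(res$mae),
                        spearman = mean(res$spearman), n = length(samples)))
}

#' Write an evaluation report to TSV
#'
#' @param report Data frame from [evaluate_fractions()].
#' @param path Output path.
#' @export
write_evaluation <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
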