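#' Fitting options for EM deconvolution
#'
#' Collects the tuning parameters shared by [fit_rna()] and [fit_dnam()].
#' Every argument has a default, so a control object is optional everywhere
#' one is accepted.
#'
#' @param tol Convergence tolerance: iteration stops when the max-norm change
#'   in the fraction vector between successive iterations falls below `tol`.
#' @param max_iter Maximum number of EM iterations per sample. Reaching it
#'   without meeting `tol` is flagged, not an error.
#' @param epsilon Clipping bound applied to methylation signature entries,
#'   which are moved into `[epsilon, 1 - epsilon]` so the E-step denominators
#'   stay positive.
#' @param quantile_norm Logical; jointly quantile-normalize the methylation
#'   signature and array beta values before fitting (array mode only).
#' @param seed Optional integer seed recorded in results for provenance.
#'   Fitting itself is deterministic; the seed matters only for simulation.
#'
#' @return A list of class `"emixed_control"`.
#' @examples
#' ctl <- emixed_control(tol = 1e-8)
#' ctl$max_iter
#' @export
emixed_control <- function(tol = 1e-6, max_iter = 1000L, epsilon = 1e-6,
                           quantile_norm = TRUE, seed = NULL) {
  stopifnot(is.numeric(tol), length(tol) == 1L, tol > 0)
  stopifnot(is.numeric(max_iter), length(max_iter) == 1L, max_iter >= 1)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L,
            epsilon > 0, epsilon < 0.5)
  stopifnot(is.logical(quantile_norm), length(quantile_norm) == 1L)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 epsilon = epsilon, quantile_norm = quantile_norm,
                 seed = seed),
            class = "emixed_control")
}

#' Read fitting options from a flat key-value file
#'
#' Parses a plain-text configuration file with one `key = value` (or
#' `key: value`) pair per line; `#` starts a comment. Recognized keys are
#' the arguments of [emixed_control()]; unknown keys raise an error. Any
#' key may be omitted, in which case its default applies.
#'
#' @param path Path to the configuration file.
#' @return An `"emixed_control"` object.
#' @export
read_control_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  opts <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*[:=]\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L)
      stop("cannot parse config line: '", ln, "'")
    opts[[m[2]]] <- m[3]
  }
  known <- c("tol", "max_iter", "epsilon", "quantile_norm", "seed")
  bad <- setdiff(names(opts), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  args <- list()
  for (key in c("tol", "epsilon")) {
    if (!is.null(opts[[key]])) args[[key]] <- as.numeric(opts[[key]])
  }
  for (key in c("max_iter", "seed")) {
    if (!is.null(opts[[key]])) args[[key]] <- as.integer(opts[[key]])
  }
  if (!is.null(opts[["quantile_norm"]])) {
    val <- toupper(opts[["quantile_norm"]])
    if (!val %in% c("TRUE", "FALSE", "ON", "OFF", "YES", "NO", "1", "0"))
      stop("quantile_norm must be a logical value, got '",
           opts[["quantile_norm"]], "'")
    args[["quantile_norm"]] <- val %in% c("TRUE", "ON", "YES", "1")
  }
  do.call(emixed_control, args)
}

## shared logging helper: level-prefixed lines on stderr
emixed_log <- function(level, ...) {
  message("[", level, "] ", ...)
}
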