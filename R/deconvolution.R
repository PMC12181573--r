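#' Construct a cell-type methylation reference matrix
#'
#' Mean beta per probe (rows) per purified cell type (columns), the reference
#' panel for constrained-projection deconvolution of mixed-tissue samples.
#'
#' @param values Numeric matrix in `[0, 1]` with unique probe rownames and
#'   at least two cell-type colnames.
#' @return The matrix with class `"cell_reference_matrix"` prepended.
#' @export
cell_reference_matrix <- function(values) {
  values <- validate_axes(values, what = "cell reference matrix")
  if (ncol(values) < 2) stop("cell reference needs at least 2 cell types", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0 | values > 1)) {
    stop("cell reference values must be finite and in [0,1]", call. = FALSE)
  }
  structure(values, class = c("cell_reference_matrix", class(matrix())))
}

#' Load a cell reference from wide CSV (probes x cell types)
#'
#' @param path CSV path; first column probe ids, remaining columns one per
#'   cell type.
#' @return A [cell_reference_matrix()].
#' @export
load_cell_reference <- function(path) {
  cell_reference_matrix(read_wide_matrix(path, "plain", what = "cell reference matrix"))
}

#' Estimate cell-type fractions by constrained projection
#'
#' For each sample, solves the non-negative least-squares problem
#' `min || R f - beta_s ||^2, f >= 0` over the probes shared between the
#' beta matrix and the reference `R`, then renormalizes `f` to the unit
#' simplex (Houseman-style constrained projection). The pre-normalization
#' sum is retained for diagnostics: values far from 1 flag samples poorly
#' explained by the panel.
#'
#' @param beta A [beta_matrix()].
#' @param ref A [cell_reference_matrix()].
#' @return Sample-by-cell-type matrix of fractions (rows sum to 1), with
#'   attribute `raw_sum` holding the per-sample pre-normalization sums.
#' @export
deconvolve_cell_fractions <- function(beta, ref) {
  stopifnot(inherits(ref, "cell_reference_matrix"))
  shared <- intersect(rownames(beta), rownames(ref))
  if (length(shared) < ncol(ref)) {
    stop(sprintf(
      "deconvolution needs at least %d shared probes (one per cell type); found %d",
      ncol(ref), length(shared)), call. = FALSE)
  }
  R <- unclass(ref)[shared, , drop = FALSE]
  B <- unclass(beta)[shared, , drop = FALSE]
  n <- ncol(B)
  out <- matrix(NA_real_, n, ncol(R),
                dimnames = list(colnames(B), colnames(R)))
  raw_sum <- stats::setNames(numeric(n), colnames(B))
  for (s in seq_len(n)) {
    y <- B[, s]
    ok <- is.finite(y)
    if (sum(ok) < ncol(R)) {
      stop(sprintf("sample '%s': too few non-missing shared probes for deconvolution",
                   colnames(B)[s]), call. = FALSE)
    }
    f <- pracma::lsqnonneg(R[ok, , drop = FALSE], y[ok])$x
    raw_sum[s] <- sum(f)
    if (raw_sum[s] <= 0) {
      stop(sprintf("sample '%s': all-zero deconvolution solution", colnames(B)[s]),
           call. = FALSE)
    }
    out[s, ] <- f / raw_sum[s]
  }
  attr(out, "raw_sum") <- raw_sum
  out
}
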