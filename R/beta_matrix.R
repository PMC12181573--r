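#' Construct a validated beta-value matrix
#'
#' A beta matrix holds methylation fractions (ratio of methylated to total
#' signal, in `[0, 1]`) for CpG probes (rows) by samples (columns). Missing
#' values are allowed; out-of-range values are an error, never clamped —
#' silent clamping would hide upstream processing faults.
#'
#' @param values Numeric matrix with unique, non-empty rownames (probe ids)
#'   and colnames (sample ids).
#' @return The matrix, with class `"beta_matrix"` prepended.
#' @examples
#' m <- matrix(c(0.1, 0.9, 0.5, 0.4), 2, 2,
#'             dimnames = list(c("cg01", "cg02"), c("s1", "s2")))
#' b <- beta_matrix(m)
#' @export
beta_matrix <- function(values) {
  values <- validate_axes(values, what = "beta matrix")
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "beta value out of [0,1]: %.6g at probe '%s', sample '%s'",
      values[bad[1, 1], bad[1, 2]],
      rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]
    ), call. = FALSE)
  }
  structure(values, class = c("beta_matrix", class(matrix())))
}

#' Construct a validated detection p-value matrix
#'
#' Same axes semantics as [beta_matrix()]; values are per-probe, per-sample
#' detection p-values in `[0, 1]`.
#'
#' @param values Numeric matrix with unique probe rownames and sample colnames.
#' @return The matrix with class `"detp_matrix"` prepended.
#' @export
detp_matrix <- function(values) {
  values <- validate_axes(values, what = "detection p-value matrix")
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "detection p-value out of [0,1]: %.6g at probe '%s', sample '%s'",
      values[bad[1, 1], bad[1, 2]],
      rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]
    ), call. = FALSE)
  }
  structure(values, class = c("detp_matrix", class(matrix())))
}

# Shared axis validation: numeric storage, unique non-empty dimnames.
validate_axes <- function(values, what) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop(sprintf("%s must be a numeric matrix", what), call. = FALSE)
  }
  pn <- rownames(values)
  sn <- colnames(values)
  if (is.null(pn) || is.null(sn) || any(!nzchar(pn)) || any(!nzchar(sn))) {
    stop(sprintf("%s needs non-empty probe rownames and sample colnames", what),
         call. = FALSE)
  }
  if (anyDuplicated(pn)) {
    stop(sprintf("duplicate probe id in %s: '%s'", what, pn[duplicated(pn)][1]),
         call. = FALSE)
  }
  if (anyDuplicated(sn)) {
    stop(sprintf("duplicate sample id in %s: '%s'", what, sn[duplicated(sn)][1]),
         call. = FALSE)
  }
  storage.mode(values) <- "double"
  values
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples; %d missing cells\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' @export
print.detp_matrix <- function(x, ...) {
  cat(sprintf("detp_matrix: %d probes x %d samples\n", nrow(x), ncol(x)))
  invisible(x)
}

# Read a wide probe-by-sample numeric table from TSV/CSV. The
# "series" dialect tolerates GEO series-matrix-style metadata lines
# prefixed with "!", which are stripped before parsing.
read_wide_matrix <- function(path, dialect = c("plain", "series"), what) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (dialect == "series") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "!")]
    dt <- data.table::fread(text = lines, header = TRUE, data.table = TRUE)
  } else {
    dt <- data.table::fread(path, header = TRUE, data.table = TRUE)
  }
  if (ncol(dt) < 2) stop(sprintf("%s has no sample columns: %s", what, path), call. = FALSE)
  ids <- as.character(dt[[1]])
  samples <- colnames(dt)[-1]
  vals <- as.list(as.data.frame(dt)[, -1, drop = FALSE])
  for (k in seq_along(vals)) {
    v <- vals[[k]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & nzchar(trimws(v)) &
                     !toupper(trimws(v)) %in% c("NA", "NAN"))
      if (length(bad) > 0) {
        stop(sprintf(
          "non-numeric cell '%s' in %s at probe '%s', sample '%s'",
          v[bad[1]], what, ids[bad[1]], samples[k]
        ), call. = FALSE)
      }
      vals[[k]] <- vn
    }
  }
  m <- do.call(cbind, vals)
  rownames(m) <- ids
  colnames(m) <- samples
  m
}

#' Load a beta-value matrix from a wide TSV/CSV file
#'
#' The first column holds probe ids and the header row holds sample ids.
#' The `"series"` dialect additionally tolerates metadata/comment lines
#' prefixed with `"!"` (the GEO series-matrix convention); on an identical
#' payload the two dialects parse to the same matrix.
#'
#' @param path Path to a TSV or CSV file (the delimiter is sniffed).
#' @param dialect `"plain"` (default) or `"series"`.
#' @return A [beta_matrix()]. Duplicate ids, non-numeric cells and values
#'   outside `[0, 1]` are hard errors naming the offending entry.
#' @export
load_beta_matrix <- function(path, dialect = c("plain", "series")) {
  beta_matrix(read_wide_matrix(path, dialect, what = "beta matrix"))
}

#' Load a detection p-value matrix
#'
#' Companion to [load_beta_matrix()]; same file layout and dialects.
#'
#' @inheritParams load_beta_matrix
#' @param beta Optional [beta_matrix()]; when supplied, the detection matrix
#'   must share its probe and sample axes exactly.
#' @return A [detp_matrix()].
#' @export
load_detp_matrix <- function(path, dialect = c("plain", "series"), beta = NULL) {
  d <- detp_matrix(read_wide_matrix(path, dialect, what = "detection p-value matrix"))
  if (!is.null(beta)) check_axes_match(beta, d)
  d
}

check_axes_match <- function(beta, detp) {
  if (!identical(rownames(beta), rownames(detp)) ||
      !identical(colnames(beta), colnames(detp))) {
    stop("beta and detection p-value matrices must share identical probe and sample axes",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a beta matrix to a wide TSV file
#'
#' Values are written with 10 decimal places so that a load/write/load cycle
#' reproduces the matrix exactly at that precision.
#'
#' @param beta A [beta_matrix()] (or numeric matrix with dimnames).
#' @param path Output file path (TSV).
#' @param digits Decimal places written; default 10.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path, digits = 10) {
  dt <- data.table::data.table(probe_id = rownames(beta))
  for (s in colnames(beta)) {
    dt[[s]] <- round(unname(beta[, s]), digits)
  }
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
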