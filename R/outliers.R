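#' Tukey fences of a numeric vector
#'
#' Lower fence `Q1 - 1.5 * IQR`, upper fence `Q3 + 1.5 * IQR`, with quartiles
#' computed by linear interpolation between the closest order statistics
#' (the type-7 convention, fixed and documented because different quantile
#' definitions move the fences). Values strictly outside the fences are
#' outliers; values on a fence are not.
#'
#' @param values Numeric vector; at least 4 non-missing values (quartiles of
#'   fewer are unstable).
#' @param k Fence multiplier; default 1.5.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
tukey_fences <- function(values, k = 1.5) {
  v <- values[!is.na(values)]
  if (length(v) < 4) {
    stop("tukey_fences needs at least 4 non-missing values", call. = FALSE)
  }
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
}

#' Remove Tukey-fence outliers from a biomarker table
#'
#' For each biomarker, fences are computed over all samples pooled (set
#' `per_group = TRUE` and supply `sheet` to fence within phenotype groups
#' instead). Flagged entries are set to missing for that biomarker only; the
#' sample is retained for every other biomarker. Exactly one pass is made:
#' re-fencing the trimmed values could flag further points, so the operation
#' is deliberately not iterated to convergence.
#'
#' @param table A [biomarker_table()].
#' @param per_group Fence within groups instead of pooled; default `FALSE`.
#' @param sheet A [sample_sheet()], required when `per_group = TRUE`.
#' @param k Fence multiplier passed to [tukey_fences()].
#' @return List with `table` (the masked [biomarker_table()]) and `log`, a
#'   data frame of removals (`sample_id`, `biomarker`, `value`, `lower`,
#'   `upper`).
#' @export
remove_outliers <- function(table, per_group = FALSE, sheet = NULL, k = 1.5) {
  stopifnot(is.matrix(table), nrow(table) > 0, ncol(table) > 0)
  if (per_group && is.null(sheet)) {
    stop("per_group fencing requires a sample sheet", call. = FALSE)
  }
  log_rows <- list()
  out <- unclass(table)
  strata <- if (per_group) {
    split(seq_len(nrow(table)),
          sheet$group[match(rownames(table), sheet$sample_id)])
  } else {
    list(all = seq_len(nrow(table)))
  }
  for (bm in colnames(table)) {
    for (rows in strata) {
      v <- out[rows, bm]
      if (sum(!is.na(v)) < 4) next
      fences <- tukey_fences(v, k = k)
      flagged <- which(!is.na(v) & (v < fences["lower"] | v > fences["upper"]))
      if (length(flagged) == 0) next
      log_rows[[length(log_rows) + 1]] <- data.frame(
        sample_id = rownames(table)[rows[flagged]],
        biomarker = bm,
        value = unname(v[flagged]),
        lower = unname(fences["lower"]),
        upper = unname(fences["upper"]),
        stringsAsFactors = FALSE
      )
      out[rows[flagged], bm] <- NA_real_
    }
  }
  log <- if (length(log_rows) > 0) {
    do.call(rbind, log_rows)
  } else {
    data.frame(sample_id = character(), biomarker = character(),
               value = numeric(), lower = numeric(), upper = numeric(),
               stringsAsFactors = FALSE)
  }
  list(table = biomarker_table(out), log = log)
}
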