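#' Detection p-value quality control of a beta matrix
#'
#' Applies the two standard array-QC rules, in a fixed order:
#' \enumerate{
#'   \item samples whose \emph{mean} probe detection p-value exceeds
#'     `sample_mean_thresh` (strict `>`) are removed;
#'   \item probes whose detection p-value exceeds `probe_fail_thresh`
#'     (strict `>`) in at least one of the \emph{remaining} samples are removed.
#' }
#' The order matters and is part of the contract: a probe that fails only in
#' a sample already excluded at step 1 is kept. With `detp = NULL` the filter
#' is skipped with a warning (QC is assumed to have happened upstream, as for
#' deposited processed matrices).
#'
#' @param beta A [beta_matrix()].
#' @param detp A [detp_matrix()] sharing `beta`'s axes, or `NULL`.
#' @param sample_mean_thresh Sample-level threshold on the mean detection
#'   p-value; default 0.05.
#' @param probe_fail_thresh Probe-level per-sample threshold; default 0.01.
#' @return A list with elements `beta` (the filtered [beta_matrix()]) and
#'   `report`, itself a list with data frames `removed_samples`
#'   (`sample_id`, `mean_detp`) and `removed_probes` (`probe_id`, `n_failed`,
#'   `max_detp`), plus the thresholds used.
#' @export
qc_filter <- function(beta, detp, sample_mean_thresh = 0.05,
                      probe_fail_thresh = 0.01) {
  stopifnot(inherits(beta, "beta_matrix"))
  if (is.null(detp)) {
    warning("no detection p-value matrix supplied; QC filter skipped",
            call. = FALSE)
    report <- list(
      skipped = TRUE,
      removed_samples = data.frame(sample_id = character(), mean_detp = numeric()),
      removed_probes = data.frame(probe_id = character(), n_failed = integer(),
                                  max_detp = numeric()),
      sample_mean_thresh = sample_mean_thresh,
      probe_fail_thresh = probe_fail_thresh
    )
    return(list(beta = beta, report = report))
  }
  check_axes_match(beta, detp)

  sample_means <- colMeans(detp, na.rm = TRUE)
  bad_samples <- which(sample_means > sample_mean_thresh)
  removed_samples <- data.frame(
    sample_id = colnames(detp)[bad_samples],
    mean_detp = unname(sample_means[bad_samples]),
    stringsAsFactors = FALSE
  )
  if (length(bad_samples) == ncol(beta)) {
    stop("QC removed every sample (all mean detection p-values above threshold)",
         call. = FALSE)
  }
  keep_s <- setdiff(seq_len(ncol(beta)), bad_samples)
  detp_kept <- detp[, keep_s, drop = FALSE]

  fail <- detp_kept > probe_fail_thresh
  fail[is.na(fail)] <- FALSE
  n_failed <- rowSums(fail)
  bad_probes <- which(n_failed >= 1)
  removed_probes <- data.frame(
    probe_id = rownames(detp)[bad_probes],
    n_failed = as.integer(n_failed[bad_probes]),
    max_detp = apply(detp_kept[bad_probes, , drop = FALSE], 1, max, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  rownames(removed_probes) <- NULL
  if (length(bad_probes) == nrow(beta)) {
    stop("QC removed every probe (all probes fail in at least one retained sample)",
         call. = FALSE)
  }
  keep_p <- setdiff(seq_len(nrow(beta)), bad_probes)

  out <- beta_matrix(unclass(beta)[keep_p, keep_s, drop = FALSE])
  report <- list(
    skipped = FALSE,
    removed_samples = removed_samples,
    removed_probes = removed_probes,
    sample_mean_thresh = sample_mean_thresh,
    probe_fail_thresh = probe_fail_thresh
  )
  list(beta = out, report = report)
}
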