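#' Load and validate a pipeline configuration
#'
#' The configuration is a YAML file naming the inputs and the analysis
#' settings. Recognised keys:
#' \describe{
#'   \item{beta, detp, sample_sheet}{input file paths (`detp` optional;
#'     without it QC is skipped with a warning).}
#'   \item{clocks}{list of clock-weight CSV paths (JSON sidecars alongside).}
#'   \item{composite_clocks}{list of composite-clock JSON paths (optional).}
#'   \item{cell_reference}{cell-reference CSV path (optional).}
#'   \item{reference_group}{group label fitted in stage one.}
#'   \item{contrasts}{list of two-element group-label pairs.}
#'   \item{alpha}{significance level, default 0.05.}
#'   \item{qc}{`sample_mean_thresh` (0.05) and `probe_fail_thresh` (0.01).}
#'   \item{flags}{`welch`, `per_group_fences`, `bh` (all default false).}
#'   \item{out_dir}{output directory.}
#' }
#' Validation errors (missing files, unknown reference group or contrast
#' labels, alpha outside (0,1)) are raised before any computation.
#'
#' @param path YAML file path.
#' @return A list of class `"pipeline_config"`.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  pipeline_config(raw, base_dir = dirname(path))
}

#' @rdname load_pipeline_config
#' @param cfg Named list with the keys above (paths relative to `base_dir`).
#' @param base_dir Directory against which relative paths are resolved.
#' @export
pipeline_config <- function(cfg, base_dir = ".") {
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(startsWith(p, "/"), p, file.path(base_dir, p))
  }
  out <- list(
    beta = resolve(cfg$beta),
    detp = resolve(cfg$detp),
    sample_sheet = resolve(cfg$sample_sheet),
    clocks = vapply(cfg$clocks %||% list(), resolve, character(1)),
    composite_clocks = vapply(cfg$composite_clocks %||% list(), resolve, character(1)),
    cell_reference = resolve(cfg$cell_reference),
    reference_group = cfg$reference_group,
    contrasts = lapply(cfg$contrasts %||% list(), unlist),
    alpha = cfg$alpha %||% 0.05,
    qc = list(
      sample_mean_thresh = cfg$qc$sample_mean_thresh %||% 0.05,
      probe_fail_thresh = cfg$qc$probe_fail_thresh %||% 0.01
    ),
    flags = list(
      welch = isTRUE(cfg$flags$welch),
      per_group_fences = isTRUE(cfg$flags$per_group_fences),
      bh = isTRUE(cfg$flags$bh)
    ),
    out_dir = resolve(cfg$out_dir) %||% "."
  )
  if (is.null(out$beta) || is.null(out$sample_sheet)) {
    stop("config must name 'beta' and 'sample_sheet' inputs", call. = FALSE)
  }
  if (length(out$clocks) == 0 && is.null(out$cell_reference)) {
    stop("config must name at least one clock or a cell reference", call. = FALSE)
  }
  if (is.null(out$reference_group)) {
    stop("config must name a reference_group", call. = FALSE)
  }
  if (length(out$contrasts) == 0) stop("config must list at least one contrast", call. = FALSE)
  if (any(vapply(out$contrasts, length, 0L) != 2)) {
    stop("each contrast must be a pair of group labels", call. = FALSE)
  }
  if (out$alpha <= 0 || out$alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  for (p in c(out$beta, out$detp, out$sample_sheet, out$clocks,
              out$composite_clocks, out$cell_reference)) {
    if (!file.exists(p)) stop(sprintf("config input not found: %s", p), call. = FALSE)
  }
  # group labels are validated against the sheet before compute
  sheet <- load_sample_sheet(out$sample_sheet)
  labels <- unique(sheet$group)
  if (!out$reference_group %in% labels) {
    stop(sprintf("reference group '%s' absent from the sample sheet", out$reference_group),
         call. = FALSE)
  }
  for (pair in out$contrasts) {
    missing_g <- setdiff(pair, labels)
    if (length(missing_g) > 0) {
      stop(sprintf("contrast group '%s' absent from the sample sheet", missing_g[1]),
           call. = FALSE)
    }
  }
  structure(out, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stage order is fixed: QC of the beta matrix, biomarker computation,
#' Tukey-fence outlier removal, reference-group model fitting, residual
#' computation, group contrasts, and Pearson correlations among the
#' biomarkers significant in the first contrast. Outlier removal strictly
#' precedes the reference fit. Each stage is logged with its removal
#' counts; any stage error aborts the run naming the stage, and partial
#' outputs are deleted.
#'
#' Outputs written to `cfg$out_dir`: `biomarkers.csv`, `qc_samples.csv`,
#' `qc_probes.csv`, `outlier_log.csv`, `reference_models.csv`,
#' `residuals.csv`, `contrasts.csv`, `correlations.csv` and
#' `manifest.json` (config hash, package version, cohort descriptives).
#'
#' @param cfg A `pipeline_config` (or path to a YAML config).
#' @param quiet Suppress stage messages.
#' @return Invisible list with all in-memory results (`qc`, `biomarkers`,
#'   `outliers`, `models`, `residuals`, `contrasts`, `correlations`,
#'   `manifest`).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- load_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(df, name) {
    p <- file.path(cfg$out_dir, name)
    data.table::fwrite(df, p)
    written <<- c(written, p)
    p
  }
  stage <- "load"
  res <- tryCatch({
    sheet <- load_sample_sheet(cfg$sample_sheet)
    beta <- load_beta_matrix(cfg$beta)
    detp <- if (!is.null(cfg$detp)) load_detp_matrix(cfg$detp, beta = beta) else NULL
    clocks <- lapply(cfg$clocks, load_clock_definition)
    composites <- lapply(cfg$composite_clocks, load_composite_clock)
    cellref <- if (!is.null(cfg$cell_reference)) load_cell_reference(cfg$cell_reference) else NULL

    stage <- "qc"
    qc <- qc_filter(beta, detp,
                    sample_mean_thresh = cfg$qc$sample_mean_thresh,
                    probe_fail_thresh = cfg$qc$probe_fail_thresh)
    say("qc: removed %d samples, %d probes (kept %d x %d)",
        nrow(qc$report$removed_samples), nrow(qc$report$removed_probes),
        nrow(qc$beta), ncol(qc$beta))
    emit(qc$report$removed_samples, "qc_samples.csv")
    emit(qc$report$removed_probes, "qc_probes.csv")
    sheet_kept <- sheet[sheet$sample_id %in% colnames(qc$beta), , drop = FALSE]
    class(sheet_kept) <- class(sheet)

    stage <- "biomarkers"
    bm <- compute_biomarkers(qc$beta, sheet_kept, clocks, composites, cellref)
    say("biomarkers: %d samples x %d biomarkers", nrow(bm), ncol(bm))
    emit(data.frame(sample_id = rownames(bm), as.data.frame(unclass(bm)),
                    check.names = FALSE), "biomarkers.csv")

    stage <- "outlier-removal"
    ol <- remove_outliers(bm, per_group = cfg$flags$per_group_fences,
                          sheet = sheet_kept)
    say("outliers: masked %d cells", nrow(ol$log))
    emit(ol$log, "outlier_log.csv")

    stage <- "reference-fit"
    ts <- two_stage_residuals(ol$table, sheet_kept, cfg$reference_group)
    coefs <- do.call(rbind, lapply(ts$models, function(m) data.frame(
      biomarker = m$biomarker, reference_group = m$reference_group,
      intercept = m$coefficients["intercept"], age = m$coefficients["age"],
      sex = m$coefficients["sex"], n_fit = m$n_fit,
      residual_sd = m$residual_sd, sex_dropped = m$sex_dropped,
      row.names = NULL)))
    emit(coefs, "reference_models.csv")
    say("reference fit on '%s' for %d biomarkers", cfg$reference_group, ncol(bm))

    stage <- "residuals"
    emit(data.frame(sample_id = rownames(ts$residuals),
                    as.data.frame(ts$residuals), check.names = FALSE),
         "residuals.csv")

    stage <- "contrasts"
    ct <- contrast_table(ts$residuals, sheet_kept, cfg$contrasts,
                         alpha = cfg$alpha, welch = cfg$flags$welch,
                         bh = cfg$flags$bh)
    emit(ct, "contrasts.csv")
    say("contrasts: %d rows, %d significant at alpha=%g",
        nrow(ct), sum(ct$significant), cfg$alpha)

    stage <- "correlations"
    prim <- cfg$contrasts[[1]]
    sig <- unique(ct$biomarker[ct$significant &
                                 ct$group_a == prim[1] & ct$group_b == prim[2]])
    cor_rows <- list()
    if (length(sig) >= 2) {
      pairs <- utils::combn(sig, 2)
      for (k in seq_len(ncol(pairs))) {
        pc <- pearson_correlation(ts$residuals[, pairs[1, k]],
                                  ts$residuals[, pairs[2, k]])
        cor_rows[[k]] <- data.frame(biomarker_a = pairs[1, k],
                                    biomarker_b = pairs[2, k],
                                    r = pc$r, n = pc$n, p = pc$p)
      }
    }
    cors <- if (length(cor_rows) > 0) do.call(rbind, cor_rows) else
      data.frame(biomarker_a = character(), biomarker_b = character(),
                 r = numeric(), n = integer(), p = numeric())
    emit(cors, "correlations.csv")

    stage <- "manifest"
    descr <- stats::aggregate(age ~ group, data = as.data.frame(sheet_kept), FUN = mean)
    manifest <- list(
      package_version = as.character(utils::packageVersion("epiaccel")),
      config = unclass(cfg)[c("reference_group", "alpha", "qc", "flags")],
      config_hash = config_hash(cfg),
      inputs = list(beta = cfg$beta, detp = cfg$detp, sample_sheet = cfg$sample_sheet),
      cohort = list(
        n_total = nrow(sheet_kept),
        n_per_group = as.list(table(sheet_kept$group)),
        mean_age_per_group = stats::setNames(as.list(round(descr$age, 4)), descr$group)
      ),
      qc = list(samples_removed = nrow(qc$report$removed_samples),
                probes_removed = nrow(qc$report$removed_probes)),
      outliers_masked = nrow(ol$log)
    )
    mp <- file.path(cfg$out_dir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, mp)

    list(qc = qc, biomarkers = bm, outliers = ol, models = ts$models,
         residuals = ts$residuals, contrasts = ct, correlations = cors,
         manifest = manifest)
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(res)
}

# Stable hash of the analysis-relevant configuration fields.
config_hash <- function(cfg) {
  key <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  # djb2 string hash; cheap, dependency-free, stable across sessions
  h <- 5381
  for (ch in utf8ToInt(key)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", as.integer(h))
}
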