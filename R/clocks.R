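#' Inverse of the Horvath age calibration
#'
#' Horvath-family clocks are trained on a log-calibrated age scale that is
#' logarithmic below an "adult age" knot and linear above it. This maps the
#' calibrated scale back to years:
#' `x < 0 -> (1 + adult_age) * exp(x) - 1`;
#' `x >= 0 -> (1 + adult_age) * x + adult_age`.
#' The map is strictly increasing and continuous at 0 (both branches give
#' `adult_age` there).
#'
#' @param x Numeric vector on the calibrated scale; must be finite.
#' @param adult_age Knot in years; > 0 (conventionally 20).
#' @return Age in years.
#' @export
horvath_inverse <- function(x, adult_age = 20) {
  stopifnot(adult_age > 0)
  if (any(!is.finite(x))) stop("non-finite value passed to horvath_inverse", call. = FALSE)
  ifelse(x < 0, (1 + adult_age) * exp(x) - 1, (1 + adult_age) * x + adult_age)
}

#' Apply a linear clock to a beta matrix
#'
#' Computes, per sample, `transform(intercept + sum_j weight_j * beta_j)`
#' over the clock's CpGs. CpGs absent from the matrix are dropped from the
#' sum (their count is recorded); CpGs present but missing (NA) in some
#' samples are handled per `missing_policy`: `"impute-cohort-mean"`
#' (default) substitutes the probe's cohort mean, `"error"` aborts.
#'
#' @param beta A [beta_matrix()].
#' @param clock A [clock_definition()].
#' @param missing_policy `"impute-cohort-mean"` or `"error"`.
#' @return Named numeric vector of per-sample values, with attributes
#'   `n_matched` (CpGs found), `n_missing_cpg` (clock CpGs absent from the
#'   matrix) and `n_imputed` (NA cells imputed).
#' @export
apply_linear_clock <- function(beta, clock,
                               missing_policy = c("impute-cohort-mean", "error")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(clock, "clock_definition"))
  cpgs <- names(clock$weights)
  present <- cpgs[cpgs %in% rownames(beta)]
  if (length(present) == 0) {
    stop(sprintf("clock '%s': none of its %d CpGs are present in the beta matrix",
                 clock$name, length(cpgs)), call. = FALSE)
  }
  sub <- unclass(beta)[present, , drop = FALSE]
  n_imputed <- 0L
  if (anyNA(sub)) {
    if (missing_policy == "error") {
      bad <- which(is.na(sub), arr.ind = TRUE)[1, ]
      stop(sprintf("clock '%s': missing beta at probe '%s', sample '%s' (missing_policy = 'error')",
                   clock$name, rownames(sub)[bad[1]], colnames(sub)[bad[2]]),
           call. = FALSE)
    }
    for (i in which(rowSums(is.na(sub)) > 0)) {
      mu <- mean(sub[i, ], na.rm = TRUE)
      if (!is.finite(mu)) {
        stop(sprintf("clock '%s': probe '%s' is missing in every sample, cannot impute",
                     clock$name, rownames(sub)[i]), call. = FALSE)
      }
      n_imputed <- n_imputed + sum(is.na(sub[i, ]))
      sub[i, is.na(sub[i, ])] <- mu
    }
  }
  lin <- clock$intercept + drop(crossprod(sub, clock$weights[present]))
  out <- switch(clock$transform,
                "identity" = lin,
                "horvath-inverse" = horvath_inverse(lin, clock$adult_age))
  if (any(!is.finite(out))) {
    stop(sprintf("clock '%s' produced a non-finite value", clock$name), call. = FALSE)
  }
  names(out) <- colnames(beta)
  attr(out, "n_matched") <- length(present)
  attr(out, "n_missing_cpg") <- length(cpgs) - length(present)
  attr(out, "n_imputed") <- n_imputed
  out
}

#' Apply a composite clock to a biomarker table
#'
#' `intercept + sum_k w_k * biomarker_k + age_weight * age + sex_weight * sex`,
#' per sample. Samples missing any referenced component get a missing output;
#' a component name absent from the table altogether is a hard error.
#'
#' @param table Sample-by-biomarker numeric matrix (see [biomarker_table()]).
#' @param sheet A [sample_sheet()] covering the table's samples.
#' @param comp A [composite_clock_definition()].
#' @return Named numeric vector (one value per table row), NA where a
#'   component is missing.
#' @export
apply_composite_clock <- function(table, sheet, comp) {
  stopifnot(inherits(comp, "composite_clock_definition"))
  comps <- names(comp$component_weights)
  unknown <- setdiff(comps, colnames(table))
  if (length(unknown) > 0) {
    stop(sprintf("composite clock '%s' references unknown biomarker '%s'",
                 comp$name, unknown[1]), call. = FALSE)
  }
  idx <- match(rownames(table), sheet$sample_id)
  if (anyNA(idx)) {
    stop("biomarker table contains samples absent from the sample sheet", call. = FALSE)
  }
  base <- comp$intercept + comp$age_weight * sheet$age[idx] +
    comp$sex_weight * sheet$sex[idx]
  if (length(comps) > 0) {
    contrib <- table[, comps, drop = FALSE] %*% comp$component_weights
    base <- base + drop(contrib) # NA propagates for missing components
  }
  stats::setNames(base, rownames(table))
}

#' Flatten a PC clock into a single linear clock
#'
#' A principal-component clock scores `intercept + v' (P' beta + c)` where
#' `P` projects CpGs onto components. Since the composition of two linear
#' maps is linear, it collapses to one [clock_definition()] with weights
#' `P v` and intercept `intercept + v'c` — avoiding a second coefficient
#' format for PC clocks.
#'
#' @param name Name for the flattened clock.
#' @param projection CpG-by-component numeric matrix `P` (rownames = CpGs).
#' @param center Optional per-component offset `c` added after projection.
#' @param score_weights Component weight vector `v`.
#' @param score_intercept Scalar intercept of the component-level score.
#' @param transform,adult_age,units Passed to [clock_definition()].
#' @return A [clock_definition()] equivalent to the two-step computation.
#' @export
flatten_pc_clock <- function(name, projection, score_weights, score_intercept = 0,
                             center = NULL, transform = "identity",
                             adult_age = 20, units = "years") {
  stopifnot(is.matrix(projection), !is.null(rownames(projection)),
            ncol(projection) == length(score_weights))
  w <- drop(projection %*% score_weights)
  b0 <- score_intercept
  if (!is.null(center)) b0 <- b0 + sum(center * score_weights)
  clock_definition(name, stats::setNames(w, rownames(projection)),
                   intercept = b0, transform = transform,
                   adult_age = adult_age, units = units)
}

#' Assemble a sample-by-biomarker table
#'
#' Runs every linear clock, then cell-fraction deconvolution (if a reference
#' is given), then every composite clock (which may reference earlier
#' columns), and binds the results into one matrix with samples as rows.
#'
#' @param beta A [beta_matrix()].
#' @param sheet A [sample_sheet()] covering the beta matrix's samples.
#' @param clocks List of [clock_definition()] objects.
#' @param composites List of [composite_clock_definition()] objects.
#' @param cell_reference Optional [cell_reference_matrix()]; adds one
#'   biomarker column per cell type (fractions).
#' @param missing_policy Passed to [apply_linear_clock()].
#' @return A [biomarker_table()] matrix.
#' @export
compute_biomarkers <- function(beta, sheet, clocks, composites = list(),
                               cell_reference = NULL,
                               missing_policy = "impute-cohort-mean") {
  cols <- list()
  for (ck in clocks) {
    v <- apply_linear_clock(beta, ck, missing_policy = missing_policy)
    cols[[ck$name]] <- as.numeric(v)
  }
  if (!is.null(cell_reference)) {
    fr <- deconvolve_cell_fractions(beta, cell_reference)
    for (ct in colnames(fr)) cols[[ct]] <- unname(fr[, ct])
  }
  tab <- do.call(cbind, cols)
  rownames(tab) <- colnames(beta)
  for (cc in composites) {
    tab <- cbind(tab, apply_composite_clock(tab, sheet, cc))
    colnames(tab)[ncol(tab)] <- cc$name
  }
  biomarker_table(tab)
}

#' Construct a validated biomarker table
#'
#' Samples as rows, biomarkers as columns; values finite or missing
#' (missingness arises from outlier removal or composite clocks with
#' missing components).
#'
#' @param values Numeric matrix with unique sample rownames and biomarker
#'   colnames.
#' @return The matrix with class `"biomarker_table"` prepended.
#' @export
biomarker_table <- function(values) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("biomarker table needs sample rownames and biomarker colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicate sample id in biomarker table", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicate biomarker name in biomarker table", call. = FALSE)
  if (any(is.infinite(values))) stop("biomarker table contains infinite values", call. = FALSE)
  structure(values, class = c("biomarker_table", class(matrix())))
}

#' @export
print.biomarker_table <- function(x, ...) {
  cat(sprintf("biomarker_table: %d samples x %d biomarkers (%s)\n",
              nrow(x), ncol(x), paste(colnames(x), collapse = ", ")))
  invisible(x)
}
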