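#' Fit the reference-group regression of a biomarker on age and sex
#'
#' Stage one of the two-stage residual-outcome procedure: ordinary least
#' squares of the biomarker on chronological age and sex, using only samples
#' from the designated reference group. Sex stays in the model even when its
#' coefficient is non-significant; it is dropped (with a warning) only when
#' the reference group is single-sex and the column is therefore rank
#' deficient. Constant age in the reference group is an error — the age
#' slope is the point of the model.
#'
#' @param table A [biomarker_table()].
#' @param sheet A [sample_sheet()].
#' @param biomarker Biomarker (column) name.
#' @param reference_group Group label whose samples are used for the fit.
#' @return An object of class `"reference_model"`: list with `biomarker`,
#'   `reference_group`, `coefficients` (`intercept`, `age`, `sex`), `n_fit`,
#'   `residual_sd`, `sex_dropped`.
#' @export
fit_reference_model <- function(table, sheet, biomarker, reference_group) {
  if (!biomarker %in% colnames(table)) {
    stop(sprintf("unknown biomarker '%s'", biomarker), call. = FALSE)
  }
  idx <- match(sheet$sample_id, rownames(table))
  ref <- which(sheet$group == reference_group & !is.na(idx))
  if (length(ref) == 0) {
    stop(sprintf("reference group '%s' not found in sample sheet", reference_group),
         call. = FALSE)
  }
  y <- table[idx[ref], biomarker]
  age <- sheet$age[ref]
  sex <- sheet$sex[ref]
  ok <- !is.na(y) & is.finite(age) & !is.na(sex)
  y <- y[ok]; age <- age[ok]; sex <- sex[ok]
  if (length(y) < 3) {
    stop(sprintf("biomarker '%s': fewer than 3 usable reference samples", biomarker),
         call. = FALSE)
  }
  if (stats::var(age) == 0) {
    stop(sprintf("biomarker '%s': constant age in reference group (column 'age' degenerate)",
                 biomarker), call. = FALSE)
  }
  sex_dropped <- length(unique(sex)) < 2
  if (sex_dropped) {
    warning(sprintf("biomarker '%s': single-sex reference group; sex dropped from the model",
                    biomarker), call. = FALSE)
    fit <- stats::lm(y ~ age)
    co <- c(intercept = unname(stats::coef(fit)[1]),
            age = unname(stats::coef(fit)[2]), sex = 0)
  } else {
    fit <- stats::lm(y ~ age + sex)
    co <- c(intercept = unname(stats::coef(fit)[1]),
            age = unname(stats::coef(fit)[2]),
            sex = unname(stats::coef(fit)[3]))
  }
  if (any(!is.finite(co))) {
    stop(sprintf("biomarker '%s': non-finite reference model coefficients", biomarker),
         call. = FALSE)
  }
  structure(
    list(biomarker = biomarker, reference_group = reference_group,
         coefficients = co, n_fit = length(y),
         residual_sd = stats::sigma(fit), sex_dropped = sex_dropped),
    class = "reference_model"
  )
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf(
    "reference_model '%s' (ref '%s', n=%d): intercept %.4g, age %.4g/yr, sex %.4g, sd %.4g\n",
    x$biomarker, x$reference_group, x$n_fit,
    x$coefficients["intercept"], x$coefficients["age"], x$coefficients["sex"],
    x$residual_sd))
  invisible(x)
}

#' Residuals of every sample from a reference model
#'
#' Stage two: the fitted reference line predicts the biomarker for every
#' sample — including the reference group itself — and the residual
#' (observed minus predicted) is the age- and sex-adjusted value carried
#' into the group contrasts. Samples lacking age or sex get a missing
#' residual.
#'
#' @param model A `reference_model` from [fit_reference_model()].
#' @param table A [biomarker_table()].
#' @param sheet A [sample_sheet()].
#' @return Named numeric vector of residuals over the table's samples.
#' @export
compute_residuals <- function(model, table, sheet) {
  stopifnot(inherits(model, "reference_model"))
  idx <- match(rownames(table), sheet$sample_id)
  if (anyNA(idx)) {
    stop("biomarker table contains samples absent from the sample sheet", call. = FALSE)
  }
  co <- model$coefficients
  pred <- co["intercept"] + co["age"] * sheet$age[idx] + co["sex"] * sheet$sex[idx]
  res <- table[, model$biomarker] - pred
  stats::setNames(unname(res), rownames(table))
}

#' Two-stage residuals for every biomarker
#'
#' Convenience wrapper fitting one reference model per biomarker and
#' assembling the residuals into a sample-by-biomarker matrix.
#'
#' @inheritParams fit_reference_model
#' @return List with `residuals` (matrix, samples x biomarkers) and
#'   `models` (named list of `reference_model`s).
#' @export
two_stage_residuals <- function(table, sheet, reference_group) {
  models <- lapply(colnames(table), function(bm) {
    fit_reference_model(table, sheet, bm, reference_group)
  })
  names(models) <- colnames(table)
  res <- vapply(models, compute_residuals, numeric(nrow(table)),
                table = table, sheet = sheet)
  if (nrow(table) == 1) res <- matrix(res, 1, dimnames = list(rownames(table), colnames(table)))
  rownames(res) <- rownames(table)
  list(residuals = res, models = models)
}

#' Compare two groups on adjusted residuals
#'
#' Two-sided Student's t-test on the residuals of `group_a` versus
#' `group_b`, pooled-variance by default (`welch = TRUE` switches to the
#' Welch unequal-variance form). With zero pooled variance, equal means give
#' `t = 0, p = 1`; unequal means are an error (the statistic is undefined).
#'
#' @param residuals Named residual vector (from [compute_residuals()]) or a
#'   residual matrix with a `biomarker` argument.
#' @param sheet A [sample_sheet()].
#' @param group_a,group_b Group labels to contrast (difference is a minus b).
#' @param alpha Significance level for the flag; default 0.05.
#' @param welch Use the Welch test instead of pooled variance.
#' @param biomarker Label recorded in the result (mandatory when `residuals`
#'   is a matrix).
#' @return One-row data frame: `biomarker`, `group_a`, `group_b`, `n_a`,
#'   `n_b`, `mean_a`, `mean_b`, `mean_diff`, `t`, `df`, `p`, `significant`.
#' @export
contrast_groups <- function(residuals, sheet, group_a, group_b, alpha = 0.05,
                            welch = FALSE, biomarker = NULL) {
  if (is.matrix(residuals)) {
    if (is.null(biomarker)) stop("biomarker must be named for a residual matrix", call. = FALSE)
    residuals <- stats::setNames(residuals[, biomarker], rownames(residuals))
  }
  if (is.null(biomarker)) biomarker <- NA_character_
  grp <- sheet$group[match(names(residuals), sheet$sample_id)]
  a <- residuals[!is.na(residuals) & grp == group_a & !is.na(grp)]
  b <- residuals[!is.na(residuals) & grp == group_b & !is.na(grp)]
  if (length(a) < 2 || length(b) < 2) {
    stop(sprintf("contrast %s vs %s: need at least 2 non-missing residuals per group",
                 group_a, group_b), call. = FALSE)
  }
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  if (!welch && pooled_var == 0) {
    if (mean(a) == mean(b)) {
      tt <- list(statistic = 0, parameter = length(a) + length(b) - 2, p.value = 1)
    } else {
      stop(sprintf("contrast %s vs %s: zero pooled variance with unequal means",
                   group_a, group_b), call. = FALSE)
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = !welch)
    tt <- list(statistic = unname(ht$statistic), parameter = unname(ht$parameter),
               p.value = ht$p.value)
  }
  data.frame(
    biomarker = biomarker, group_a = group_a, group_b = group_b,
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), mean_b = mean(b), mean_diff = mean(a) - mean(b),
    t = tt$statistic, df = tt$parameter, p = tt$p.value,
    significant = tt$p.value < alpha,
    stringsAsFactors = FALSE
  )
}

#' All group contrasts for all biomarkers
#'
#' Runs [contrast_groups()] for every biomarker and every requested group
#' pair, returning one tidy row per (biomarker, contrast). Optionally
#' appends Benjamini-Hochberg adjusted q-values per contrast pair (the raw
#' `p` and `significant` columns are unchanged — no correction is the
#' default, matching a raw 0.05 threshold).
#'
#' @param residuals Residual matrix from [two_stage_residuals()].
#' @param sheet A [sample_sheet()].
#' @param contrasts List of 2-element character vectors `c(group_a, group_b)`.
#' @param alpha,welch Passed to [contrast_groups()].
#' @param bh Add a `q` column of BH-adjusted p-values (within each pair).
#' @return Data frame, one row per biomarker x contrast.
#' @export
contrast_table <- function(residuals, sheet, contrasts, alpha = 0.05,
                           welch = FALSE, bh = FALSE) {
  rows <- list()
  for (pair in contrasts) {
    for (bm in colnames(residuals)) {
      rows[[length(rows) + 1]] <- contrast_groups(
        residuals, sheet, pair[1], pair[2],
        alpha = alpha, welch = welch, biomarker = bm)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (bh) {
    out$q <- NA_real_
    for (pair in contrasts) {
      sel <- out$group_a == pair[1] & out$group_b == pair[2]
      out$q[sel] <- stats::p.adjust(out$p[sel], method = "BH")
    }
  }
  out
}

#' One-way fixed-effects ANOVA of a sample-sheet variable across groups
#'
#' Classic (equal-variance) one-way ANOVA, typically used to check that
#' phenotype groups do not differ in mean chronological age before
#' interpreting age-adjusted contrasts.
#'
#' @param sheet A [sample_sheet()].
#' @param variable Column to test; default `"age"`.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
anova_oneway <- function(sheet, variable = "age") {
  if (!variable %in% colnames(sheet)) {
    stop(sprintf("unknown variable '%s'", variable), call. = FALSE)
  }
  v <- sheet[[variable]]
  g <- factor(sheet$group)
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]; g <- droplevels(g[ok])
  sizes <- table(g)
  if (length(sizes) < 2) stop("ANOVA needs at least 2 groups", call. = FALSE)
  if (any(sizes < 2)) {
    stop(sprintf("group '%s' has fewer than 2 samples", names(sizes)[sizes < 2][1]),
         call. = FALSE)
  }
  ht <- stats::oneway.test(v ~ g, var.equal = TRUE)
  list(F = unname(ht$statistic), df1 = unname(ht$parameter[1]),
       df2 = unname(ht$parameter[2]), p = ht$p.value)
}

#' Pearson correlation between two biomarker vectors
#'
#' Sample Pearson r over pairwise-complete observations, with the usual
#' two-sided p-value from the t transformation `t = r sqrt((n-2)/(1-r^2))`.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `r`, `n`, `p`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("pearson_correlation needs at least 3 paired values", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("pearson_correlation: zero variance input", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), n = length(x), p = ht$p.value)
}
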