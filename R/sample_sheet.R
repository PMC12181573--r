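#' Construct a validated sample sheet
#'
#' A sample sheet carries, per sample, the phenotype group label, the
#' chronological age in years and a binary sex indicator; any further numeric
#' columns are preserved as covariates (e.g. diabetes duration in years).
#'
#' @param df Data frame with columns `sample_id`, `group`, `age`, `sex`
#'   (already coded 0/1).
#' @return The data frame with class `"sample_sheet"` prepended.
#' @export
sample_sheet <- function(df) {
  required <- c("sample_id", "group", "age", "sex")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("sample sheet is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  if (anyDuplicated(df$sample_id)) {
    stop(sprintf("duplicate sample_id in sample sheet: '%s'",
                 df$sample_id[duplicated(df$sample_id)][1]), call. = FALSE)
  }
  if (any(!nzchar(df$group) | is.na(df$group))) {
    stop("empty group label in sample sheet", call. = FALSE)
  }
  if (!is.numeric(df$age) || any(!is.finite(df$age)) || any(df$age <= 0)) {
    stop("age must be finite and positive for every sample", call. = FALSE)
  }
  if (!all(df$sex %in% c(0, 1))) {
    stop("sex must be coded 0/1 (see sex_map in load_sample_sheet)", call. = FALSE)
  }
  df$sex <- as.numeric(df$sex)
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Load a sample sheet from CSV
#'
#' Required columns: `sample_id`, `group`, `age`, `sex`. Sex may be given as
#' 0/1 or as labels mapped through `sex_map` (default `F -> 0`, `M -> 1`;
#' the coding is a convention of this package, surfaced so other codings can
#' be declared rather than guessed). Unknown columns are kept as covariates.
#'
#' @param path CSV file path.
#' @param sex_map Named numeric vector mapping sex labels to 0/1.
#' @return A [sample_sheet()].
#' @export
load_sample_sheet <- function(path, sex_map = c("F" = 0, "M" = 1)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  if (!"sex" %in% colnames(df)) {
    stop("sample sheet is missing required column(s): sex", call. = FALSE)
  }
  sx <- df$sex
  if (!is.numeric(sx) || !all(sx %in% c(0, 1))) {
    sx <- as.character(sx)
    mapped <- unname(sex_map[sx])
    bad <- which(is.na(mapped))
    if (length(bad) > 0) {
      stop(sprintf("unmappable sex value '%s' for sample '%s'",
                   sx[bad[1]], as.character(df$sample_id)[bad[1]]), call. = FALSE)
    }
    df$sex <- mapped
  }
  sample_sheet(df)
}

#' @export
print.sample_sheet <- function(x, ...) {
  tab <- table(x$group)
  cat(sprintf("sample_sheet: %d samples in %d groups (%s)\n",
              nrow(x), length(tab),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Names of the covariate columns of a sample sheet
#'
#' Everything beyond the required `sample_id`, `group`, `age`, `sex`.
#'
#' @param sheet A [sample_sheet()].
#' @return Character vector of covariate column names.
#' @export
covariate_names <- function(sheet) {
  setdiff(colnames(sheet), c("sample_id", "group", "age", "sex"))
}
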