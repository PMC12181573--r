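#' Define a linear epigenetic clock
#'
#' A linear clock maps beta values to a surrogate score as
#' `transform(intercept + sum_j weight_j * beta_j)`. This structural form
#' covers classic age predictors (Hannum, Horvath skin-blood, PhenoAge),
#' methylation-based telomere length, EpiScores and pace-of-aging measures;
#' principal-component "bolstered" clocks are also representable because a
#' CpG-to-component projection followed by a linear score is itself one
#' linear map (see [flatten_pc_clock()]).
#'
#' @param name Clock name (used as the biomarker column name).
#' @param weights Named numeric vector, CpG id -> coefficient.
#' @param intercept Intercept on the output scale.
#' @param transform `"identity"` or `"horvath-inverse"` (the anti-log
#'   calibration used by Horvath-family age clocks; see [horvath_inverse()]).
#' @param adult_age Adult-age knot of the Horvath calibration, years; > 0.
#' @param units Free-text units of the output (e.g. `"years"`, `"kb"`).
#' @return An object of class `"clock_definition"`.
#' @export
clock_definition <- function(name, weights, intercept = 0,
                             transform = c("identity", "horvath-inverse"),
                             adult_age = 20, units = "years") {
  transform <- match.arg(transform)
  if (length(weights) == 0) stop("clock weights must be non-empty", call. = FALSE)
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("clock weights must be named by CpG id", call. = FALSE)
  }
  if (anyDuplicated(names(weights))) {
    stop(sprintf("duplicate CpG id in clock '%s': '%s'", name,
                 names(weights)[duplicated(names(weights))][1]), call. = FALSE)
  }
  stopifnot(is.numeric(weights), all(is.finite(weights)),
            is.numeric(intercept), length(intercept) == 1, is.finite(intercept),
            adult_age > 0)
  structure(
    list(name = as.character(name), weights = weights,
         intercept = as.numeric(intercept), transform = transform,
         adult_age = as.numeric(adult_age), units = as.character(units)),
    class = "clock_definition"
  )
}

#' @export
print.clock_definition <- function(x, ...) {
  cat(sprintf("clock_definition '%s': %d CpGs, intercept %.4g, transform %s [%s]\n",
              x$name, length(x$weights), x$intercept, x$transform, x$units))
  invisible(x)
}

#' Load a clock definition from a CSV of weights plus a JSON sidecar
#'
#' The CSV must have columns `cpg` and `weight`; the sidecar (by default the
#' same path with extension `.json`) holds
#' `{name, intercept, transform, adult_age, units}`. Absent sidecar fields
#' fall back to the [clock_definition()] defaults.
#'
#' @param csv_path Path to the weight CSV.
#' @param json_path Path to the JSON sidecar; default derived from `csv_path`.
#' @return A [clock_definition()].
#' @export
load_clock_definition <- function(csv_path,
                                  json_path = paste0(tools::file_path_sans_ext(csv_path), ".json")) {
  if (!file.exists(csv_path)) stop(sprintf("file not found: %s", csv_path), call. = FALSE)
  w <- as.data.frame(data.table::fread(csv_path, header = TRUE))
  if (!all(c("cpg", "weight") %in% colnames(w))) {
    stop("clock CSV must have columns 'cpg' and 'weight'", call. = FALSE)
  }
  meta <- list()
  if (file.exists(json_path)) meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  weights <- stats::setNames(as.numeric(w$weight), as.character(w$cpg))
  clock_definition(
    name = meta$name %||% tools::file_path_sans_ext(basename(csv_path)),
    weights = weights,
    intercept = meta$intercept %||% 0,
    transform = meta$transform %||% "identity",
    adult_age = meta$adult_age %||% 20,
    units = meta$units %||% "years"
  )
}

#' Write a clock definition as CSV + JSON sidecar
#'
#' Inverse of [load_clock_definition()].
#'
#' @param clock A [clock_definition()].
#' @param csv_path Output CSV path; the sidecar is written next to it.
#' @return `csv_path`, invisibly.
#' @export
write_clock_definition <- function(clock, csv_path) {
  data.table::fwrite(
    data.table::data.table(cpg = names(clock$weights), weight = unname(clock$weights)),
    csv_path
  )
  jsonlite::write_json(
    list(name = clock$name, intercept = clock$intercept,
         transform = clock$transform, adult_age = clock$adult_age,
         units = clock$units),
    paste0(tools::file_path_sans_ext(csv_path), ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(csv_path)
}

#' Define a composite clock
#'
#' Composite clocks of the GrimAge family are linear combinations of
#' previously computed sub-biomarkers plus chronological age and sex:
#' `intercept + sum_k w_k * biomarker_k + age_weight * age + sex_weight * sex`.
#'
#' @param name Composite clock name.
#' @param component_weights Named numeric vector, biomarker name -> weight.
#' @param intercept,age_weight,sex_weight Scalars.
#' @param units Output units.
#' @return An object of class `"composite_clock_definition"`.
#' @export
composite_clock_definition <- function(name, component_weights, intercept = 0,
                                       age_weight = 0, sex_weight = 0,
                                       units = "years") {
  if (length(component_weights) > 0 &&
      (is.null(names(component_weights)) || any(!nzchar(names(component_weights))))) {
    stop("component weights must be named by biomarker", call. = FALSE)
  }
  stopifnot(is.numeric(intercept), is.numeric(age_weight), is.numeric(sex_weight))
  structure(
    list(name = as.character(name),
         component_weights = component_weights,
         intercept = as.numeric(intercept),
         age_weight = as.numeric(age_weight),
         sex_weight = as.numeric(sex_weight),
         units = as.character(units)),
    class = "composite_clock_definition"
  )
}

#' Load a composite clock definition from JSON
#'
#' Expected fields: `name`, `intercept`, `component_weights` (object mapping
#' biomarker name to weight), `age_weight`, `sex_weight`, `units`.
#'
#' @param path JSON file path.
#' @return A [composite_clock_definition()].
#' @export
load_composite_clock <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  composite_clock_definition(
    name = j$name %||% tools::file_path_sans_ext(basename(path)),
    component_weights = unlist(j$component_weights %||% list()),
    intercept = j$intercept %||% 0,
    age_weight = j$age_weight %||% 0,
    sex_weight = j$sex_weight %||% 0,
    units = j$units %||% "years"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
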