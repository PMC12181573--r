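#' Configuration for the synthetic methylation cohort generator
#'
#' Defaults mirror the structure of a three-group diabetic-neuropathy
#' methylation study: group sizes 99/132/84 (painful DN, painless DN,
#' healthy controls), ages uniform on 41-84 years, and an injected
#' epigenetic acceleration of +3 years in PDN and -2 years in CTRL relative
#' to the PLDN reference. Betas drift linearly with (accelerated) age;
#' see [generate_cohort()] for the generative model.
#'
#' @param n_per_group Named integer vector, group label -> sample count.
#' @param age_range Chronological age bounds in years (uniform draw).
#' @param sex_ratio Probability that `sex == 1` (default 0.5).
#' @param m Number of CpG probes; at least 4.
#' @param b0 Baseline beta at age 0, scalar or length-`m` (default 0.2).
#' @param s Beta drift per year of effective age, scalar or length-`m`
#'   (default 0.005/yr).
#' @param sex_effect Additive beta shift for `sex == 1`, scalar or
#'   length-`m` (default 0.01).
#' @param accel Named numeric vector, group -> mean acceleration in years
#'   (default `c(PDN = 3, PLDN = 0, CTRL = -2)`).
#' @param accel_sd Between-individual sd of acceleration, years (default 3).
#' @param noise_sd Probe-level Gaussian noise sd in beta units (default 0.01).
#' @param detp_fail_rate Per-cell probability of an injected detection
#'   failure (default 1e-4). Because probe QC removes a probe failing in any
#'   single sample, the per-probe removal probability is
#'   `1 - (1 - rate)^n`; the default loses a few percent of probes in a
#'   cohort of ~300, matching a well-behaved processed array study.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_per_group = c(PDN = 99, PLDN = 132, CTRL = 84),
                              age_range = c(41, 84), sex_ratio = 0.5,
                              m = 50, b0 = 0.2, s = 0.005, sex_effect = 0.01,
                              accel = c(PDN = 3, PLDN = 0, CTRL = -2),
                              accel_sd = 3, noise_sd = 0.01,
                              detp_fail_rate = 1e-4, seed = 1L) {
  stopifnot(length(n_per_group) >= 1, all(n_per_group > 0),
            !is.null(names(n_per_group)), all(nzchar(names(n_per_group))),
            length(age_range) == 2, age_range[1] > 0, age_range[2] >= age_range[1],
            sex_ratio >= 0, sex_ratio <= 1,
            m >= 4,
            length(b0) %in% c(1, m), length(s) %in% c(1, m),
            length(sex_effect) %in% c(1, m),
            accel_sd >= 0, noise_sd >= 0,
            detp_fail_rate >= 0, detp_fail_rate <= 1)
  missing_acc <- setdiff(names(n_per_group), names(accel))
  if (length(missing_acc) > 0) {
    stop(sprintf("no acceleration specified for group(s): %s",
                 paste(missing_acc, collapse = ", ")), call. = FALSE)
  }
  structure(
    list(n_per_group = n_per_group, age_range = age_range,
         sex_ratio = sex_ratio, m = as.integer(m),
         b0 = rep_len(b0, m), s = rep_len(s, m),
         sex_effect = rep_len(sex_effect, m),
         accel = accel, accel_sd = accel_sd, noise_sd = noise_sd,
         detp_fail_rate = detp_fail_rate, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Deterministic per-sample sub-stream seed, kept below 2^31 so outputs are
# invariant to how many probes earlier samples consumed.
sample_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}

#' Generate a synthetic methylation cohort with known acceleration
#'
#' Generative model, per sample `i` of group `g`:
#' \itemize{
#'   \item acceleration `accel_i ~ N(accel[g], accel_sd)`, effective age
#'     `a_i = age_i + accel_i`;
#'   \item beta for probe `j`: `clip_[0,1](b0_j + s_j * a_i +
#'     sex_effect_j * sex_i + eps)`, `eps ~ N(0, noise_sd)`;
#'   \item detection p-values are tiny (uniform below 0.005) except for
#'     injected failures (rate `detp_fail_rate`) drawn uniform on
#'     (0.011, 0.2), i.e. clearly above the 0.01 probe threshold.
#' }
#' A single generator is seeded once for the sample-level draws; each
#' sample's probe-level noise uses its own deterministic sub-stream, so the
#' cohort is fully reproducible and per-sample values do not depend on probe
#' ordering elsewhere. A configuration whose noise-free betas leave
#' [0.05, 0.95] triggers a warning (clipping bends the linear model).
#'
#' @param cfg A [simulation_config()].
#' @return List with `beta` ([beta_matrix()]), `detp` ([detp_matrix()]),
#'   `sheet` ([sample_sheet()]) and `truth` (data frame of per-sample true
#'   acceleration plus attributes `accel` (the group means), `seed` and
#'   `clipped_fraction`).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  groups <- rep(names(cfg$n_per_group), cfg$n_per_group)
  n <- length(groups)
  ids <- sprintf("S%04d", seq_len(n))
  probes <- sprintf("cg%06d", seq_len(cfg$m))

  # expected (noise-free) beta range check, before any draw
  eff_lo <- cfg$age_range[1] + min(cfg$accel[groups]) - 2 * cfg$accel_sd
  eff_hi <- cfg$age_range[2] + max(cfg$accel[groups]) + 2 * cfg$accel_sd
  exp_lo <- min(cfg$b0 + cfg$s * eff_lo, cfg$b0 + cfg$s * eff_hi)
  exp_hi <- max(cfg$b0 + cfg$s * eff_lo + cfg$sex_effect,
                cfg$b0 + cfg$s * eff_hi + cfg$sex_effect)
  if (exp_lo < 0.05 || exp_hi > 0.95) {
    warning(sprintf(
      "expected beta range [%.3f, %.3f] leaves [0.05, 0.95]; clipping will distort linearity",
      exp_lo, exp_hi), call. = FALSE)
  }

  set.seed(cfg$seed)
  age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
  sex <- stats::rbinom(n, 1, cfg$sex_ratio)
  accel <- stats::rnorm(n, cfg$accel[groups], cfg$accel_sd)
  eff_age <- age + accel

  beta <- matrix(NA_real_, cfg$m, n, dimnames = list(probes, ids))
  detp <- matrix(NA_real_, cfg$m, n, dimnames = list(probes, ids))
  for (i in seq_len(n)) {
    set.seed(sample_seed(cfg$seed, i))
    eps <- stats::rnorm(cfg$m, 0, cfg$noise_sd)
    beta[, i] <- cfg$b0 + cfg$s * eff_age[i] + cfg$sex_effect * sex[i] + eps
    base_p <- stats::runif(cfg$m, 0, 0.005)
    fail <- stats::runif(cfg$m) < cfg$detp_fail_rate
    detp[, i] <- ifelse(fail, stats::runif(cfg$m, 0.011, 0.2), base_p)
  }
  clipped <- sum(beta < 0 | beta > 1)
  beta <- pmin(pmax(beta, 0), 1)

  sheet <- sample_sheet(data.frame(
    sample_id = ids, group = groups, age = age, sex = sex,
    stringsAsFactors = FALSE
  ))
  truth <- data.frame(sample_id = ids, group = groups,
                      true_acceleration = accel, effective_age = eff_age,
                      stringsAsFactors = FALSE)
  attr(truth, "accel") <- cfg$accel
  attr(truth, "seed") <- cfg$seed
  attr(truth, "clipped_fraction") <- clipped / length(beta)
  attr(truth, "generator_version") <- "epiaccel-sim-1"

  list(beta = beta_matrix(beta), detp = detp_matrix(detp),
       sheet = sheet, truth = truth)
}

#' Toy clock matched to a synthetic cohort
#'
#' For a configuration with uniform baseline `b0` and slope `s`, the clock
#' with weights `w_j = 1 / (m * s)` and intercept `-b0 / s` satisfies
#' `intercept + sum_j w_j * beta_j = effective age` exactly when probe noise
#' and sex effects are zero — so on noise-free data the clock's output minus
#' chronological age equals each sample's true injected acceleration.
#'
#' @param cfg A [simulation_config()] with uniform `b0` and `s`; `s` must be
#'   non-zero.
#' @param name Clock name; default `"ToyClock"`.
#' @return A [clock_definition()] with identity transform, units years.
#' @export
generate_toy_clock <- function(cfg, name = "ToyClock") {
  stopifnot(inherits(cfg, "simulation_config"))
  if (length(unique(cfg$b0)) != 1 || length(unique(cfg$s)) != 1) {
    stop("generate_toy_clock requires uniform b0 and s across probes", call. = FALSE)
  }
  s <- cfg$s[1]; b0 <- cfg$b0[1]
  if (s == 0) stop("toy clock undefined for zero age slope (s = 0)", call. = FALSE)
  probes <- sprintf("cg%06d", seq_len(cfg$m))
  clock_definition(
    name = name,
    weights = stats::setNames(rep(1 / (cfg$m * s), cfg$m), probes),
    intercept = -b0 / s,
    transform = "identity",
    units = "years"
  )
}

#' Write a synthetic cohort to disk in the formats the loaders read
#'
#' Emits `beta.tsv`, `detp.tsv`, `samples.csv` and `truth.csv` under `dir`,
#' round-trippable through [load_beta_matrix()], [load_detp_matrix()] and
#' [load_sample_sheet()].
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_beta_matrix(cohort$beta, file.path(dir, "beta.tsv"))
  write_beta_matrix(cohort$detp, file.path(dir, "detp.tsv"))
  sheet <- as.data.frame(cohort$sheet)
  data.table::fwrite(sheet, file.path(dir, "samples.csv"))
  data.table::fwrite(cohort$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
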