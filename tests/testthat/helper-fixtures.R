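# Shared in-code fixtures: small matrices and cohorts built fresh per test.

fixture_beta <- function(values = c(0.10, 0.20, 0.30, 0.40, 0.50, 0.60),
                         probes = c("cg01", "cg02", "cg03"),
                         samples = c("s1", "s2")) {
  beta_matrix(matrix(values, nrow = length(probes),
                     dimnames = list(probes, samples)))
}

fixture_sheet <- function(n = 6, groups = rep(c("PDN", "PLDN", "CTRL"), 2),
                          ages = seq(50, 75, length.out = n),
                          sex = rep(c(0, 1), length.out = n)) {
  sample_sheet(data.frame(
    sample_id = sprintf("s%d", seq_len(n)),
    group = groups, age = ages, sex = sex,
    stringsAsFactors = FALSE
  ))
}

# tiny deterministic cohort for fast end-to-end tests
small_cohort_config <- function(seed = 1, ...) {
  simulation_config(
    n_per_group = c(PDN = 8, PLDN = 9, CTRL = 8),
    m = 12, seed = seed, ...
  )
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
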