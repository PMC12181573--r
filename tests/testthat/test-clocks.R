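# forward Horvath calibration, written here as the independent oracle for
# the package's inverse: log-linear below the adult-age knot, linear above
horvath_forward_oracle <- function(age, adult_age = 20) {
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

test_that("linear clock arithmetic is exact on hand-computed cases", {
  b <- beta_matrix(matrix(c(0.5, 0.25), 2, 1,
                          dimnames = list(c("cg1", "cg2"), "s1")))
  ck <- clock_definition("toy", c(cg1 = 2, cg2 = -1), intercept = 10)
  expect_equal(as.numeric(apply_linear_clock(b, ck)), 10 + 1.0 - 0.25)

  ck0 <- clock_definition("flat", c(cg1 = 0, cg2 = 0), intercept = 7)
  expect_equal(as.numeric(apply_linear_clock(b, ck0)), 7)

  # zero linear part under the anti-log calibration returns the knot age
  ckh <- clock_definition("h", c(cg1 = 0, cg2 = 0), intercept = 0,
                          transform = "horvath-inverse", adult_age = 20)
  expect_equal(as.numeric(apply_linear_clock(b, ckh)), 20)
})

test_that("horvath_inverse matches its closed form and inverts the forward map", {
  expect_equal(horvath_inverse(0, 20), 20)
  expect_equal(horvath_inverse(1, 20), 41)
  grid <- seq(-3, 3, by = 0.05)
  ages <- horvath_inverse(grid, adult_age = 20)
  expect_equal(horvath_forward_oracle(ages, 20), grid, tolerance = 1e-10)
  # strictly increasing, continuous at the knot
  expect_true(all(diff(ages) > 0))
  expect_equal(horvath_inverse(-1e-12, 20), horvath_inverse(0, 20), tolerance = 1e-10)
  expect_error(horvath_inverse(NaN), "non-finite")
})

test_that("identity-transform clocks are linear in beta", {
  set.seed(3)
  probes <- sprintf("cg%d", 1:6)
  ck <- clock_definition("lin", setNames(rnorm(6), probes), intercept = 5)
  m1 <- matrix(runif(18, 0.1, 0.45), 6, dimnames = list(probes, sprintf("s%d", 1:3)))
  v1 <- apply_linear_clock(beta_matrix(m1), ck)
  v2 <- apply_linear_clock(beta_matrix(2 * m1), ck)
  expect_equal(unname(v2 - ck$intercept), unname(2 * (v1 - ck$intercept)),
               tolerance = 1e-12)
})

test_that("missing CpGs follow the declared policy", {
  m <- matrix(c(0.5, NA, 0.4, 0.2), 2, dimnames = list(c("cg1", "cg2"),
                                                       c("s1", "s2")))
  b <- beta_matrix(m)
  ck <- clock_definition("t", c(cg1 = 1, cg2 = 1, cg9 = 5))
  expect_error(apply_linear_clock(b, ck, missing_policy = "error"), "cg2.*s1")
  v <- apply_linear_clock(b, ck, missing_policy = "impute-cohort-mean")
  # cg9 absent -> dropped; cg2 NA in s1 -> imputed with its cohort mean (0.2)
  expect_equal(as.numeric(v), c(0.5 + 0.2, 0.4 + 0.2))
  expect_equal(attr(v, "n_matched"), 2L)
  expect_equal(attr(v, "n_missing_cpg"), 1L)
  expect_equal(attr(v, "n_imputed"), 1L)

  ck_none <- clock_definition("none", c(cgX = 1))
  expect_error(apply_linear_clock(b, ck_none), "none of its")
})

test_that("a flattened PC clock equals the explicit two-step computation", {
  set.seed(8)
  probes <- sprintf("cg%d", 1:20)
  P <- matrix(rnorm(20 * 4), 20, 4, dimnames = list(probes, NULL))
  v <- rnorm(4); b0 <- 1.7; ctr <- rnorm(4)
  B <- matrix(runif(20 * 5, 0.05, 0.95), 20, dimnames = list(probes, sprintf("s%d", 1:5)))

  two_step <- b0 + drop(crossprod(v, t(P) %*% B + ctr))
  flat <- flatten_pc_clock("pc", P, v, score_intercept = b0, center = ctr)
  expect_equal(as.numeric(apply_linear_clock(beta_matrix(B), flat)),
               unname(two_step), tolerance = 1e-10)
})

test_that("composite clocks combine components, age and sex as declared", {
  sheet <- fixture_sheet(3, groups = c("PDN", "PLDN", "CTRL"),
                         ages = c(60, 70, 65), sex = c(0, 1, 0))
  tab <- biomarker_table(matrix(c(1, 2, 3, 10, 20, 30), 3,
                                dimnames = list(sheet$sample_id, c("A", "B"))))

  c0 <- composite_clock_definition("c0", numeric(), intercept = 5)
  expect_equal(unname(apply_composite_clock(tab, sheet, c0)), rep(5, 3))

  c1 <- composite_clock_definition("c1", c(A = 1))
  expect_equal(unname(apply_composite_clock(tab, sheet, c1)), c(1, 2, 3))

  # spreadsheet-style manual sum for a full two-component case
  c2 <- composite_clock_definition("c2", c(A = 0.5, B = -0.1), intercept = 2,
                                   age_weight = 0.3, sex_weight = -1)
  manual <- 2 + 0.5 * c(1, 2, 3) - 0.1 * c(10, 20, 30) +
    0.3 * c(60, 70, 65) - 1 * c(0, 1, 0)
  expect_equal(unname(apply_composite_clock(tab, sheet, c2)), manual)

  bad <- composite_clock_definition("bad", c(Z = 1))
  expect_error(apply_composite_clock(tab, sheet, bad), "unknown biomarker 'Z'")

  tab_na <- tab; tab_na[2, "A"] <- NA
  v <- apply_composite_clock(biomarker_table(tab_na), sheet, c2)
  expect_true(is.na(v[2]) && !anyNA(v[-2]))
})

test_that("biomarker values are invariant under probe and sample reordering", {
  cfg <- small_cohort_config(seed = 5)
  co <- generate_cohort(cfg)
  ck <- generate_toy_clock(cfg)
  v <- apply_linear_clock(co$beta, ck)

  perm_p <- sample(nrow(co$beta))
  perm_s <- sample(ncol(co$beta))
  shuffled <- beta_matrix(unclass(co$beta)[perm_p, perm_s])
  v2 <- apply_linear_clock(shuffled, ck)
  expect_equal(as.numeric(v2[names(v)]), as.numeric(v), tolerance = 1e-12)
})
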