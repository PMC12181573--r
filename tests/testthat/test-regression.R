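# closed-form OLS oracle via the normal equations
ols_oracle <- function(X, y) drop(solve(crossprod(X), crossprod(X, y)))

# textbook pooled-variance t oracle
pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

make_table <- function(values, sheet, name = "bm") {
  biomarker_table(matrix(values, length(values),
                         dimnames = list(sheet$sample_id, name)))
}

test_that("an exact plane is interpolated by the reference fit", {
  sheet <- fixture_sheet(8, groups = rep("PLDN", 8),
                         ages = c(50, 55, 60, 65, 70, 75, 62, 58),
                         sex = c(0, 1, 0, 1, 0, 1, 1, 0))
  tab <- make_table(2 + 0.5 * sheet$age + 0 * sheet$sex, sheet)
  m <- fit_reference_model(tab, sheet, "bm", "PLDN")
  expect_equal(unname(m$coefficients), c(2, 0.5, 0), tolerance = 1e-10)
  expect_equal(m$n_fit, 8L)
})

test_that("the reference fit equals the normal-equations solution", {
  set.seed(21)
  sheet <- fixture_sheet(10, groups = rep("PLDN", 10),
                         ages = runif(10, 45, 80), sex = rbinom(10, 1, 0.5))
  y <- rnorm(10, 50, 5)
  tab <- make_table(y, sheet)
  m <- fit_reference_model(tab, sheet, "bm", "PLDN")
  X <- cbind(1, sheet$age, sheet$sex)
  expect_equal(unname(m$coefficients), ols_oracle(X, y), tolerance = 1e-10)
})

test_that("rank-deficient designs are handled: sex dropped, constant age fatal", {
  sheet <- fixture_sheet(6, groups = rep("PLDN", 6),
                         ages = c(50, 55, 60, 65, 70, 75), sex = rep(1, 6))
  tab <- make_table(rnorm(6, 40, 2), sheet)
  expect_warning(m <- fit_reference_model(tab, sheet, "bm", "PLDN"),
                 "single-sex")
  expect_equal(unname(m$coefficients["sex"]), 0)
  expect_true(m$sex_dropped)

  sheet2 <- fixture_sheet(6, groups = rep("PLDN", 6), ages = rep(60, 6),
                          sex = rep(c(0, 1), 3))
  tab2 <- make_table(rnorm(6), sheet2)
  expect_error(fit_reference_model(tab2, sheet2, "bm", "PLDN"), "age")
})

test_that("residuals behave like OLS residuals and extend to all groups", {
  set.seed(31)
  sheet <- fixture_sheet(12, groups = rep(c("PLDN", "PDN", "CTRL"), 4),
                         ages = runif(12, 45, 80), sex = rbinom(12, 1, 0.5))
  y <- 10 + 0.3 * sheet$age + 2 * sheet$sex + rnorm(12)
  tab <- make_table(y, sheet)
  m <- fit_reference_model(tab, sheet, "bm", "PLDN")
  res <- compute_residuals(m, tab, sheet)

  # reference-group residuals sum to zero (OLS with intercept)
  expect_equal(sum(res[sheet$group == "PLDN"]), 0, tolerance = 1e-10)

  # n=8 random case against a direct predict-and-subtract oracle
  co <- m$coefficients
  pred <- co["intercept"] + co["age"] * sheet$age + co["sex"] * sheet$sex
  expect_equal(unname(res), unname(y - pred), tolerance = 1e-12)

  # a sample lying exactly on the fitted plane has residual zero
  tab2 <- tab
  tab2[4, "bm"] <- co["intercept"] + co["age"] * sheet$age[4] + co["sex"] * sheet$sex[4]
  res2 <- compute_residuals(m, biomarker_table(tab2), sheet)
  expect_equal(unname(res2[4]), 0, tolerance = 1e-12)
})

test_that("group contrasts reproduce the textbook pooled t-test", {
  sheet <- fixture_sheet(6, groups = rep(c("A", "B"), each = 3),
                         ages = 51:56)
  res <- setNames(c(1, 2, 3, 4, 5, 6), sheet$sample_id)

  ct <- contrast_groups(res, sheet, "A", "B")
  oracle <- pooled_t_oracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ct$mean_diff, -3)
  expect_equal(ct$t, oracle$t, tolerance = 1e-10)
  expect_equal(ct$t, -3 / sqrt(2 / 3), tolerance = 1e-10) # pooled sd 1
  expect_equal(ct$df, 4)
  expect_equal(ct$p, oracle$p, tolerance = 1e-10)
  expect_true(ct$p > 0.021 && ct$p < 0.022)
  expect_true(ct$significant)

  # antisymmetry in the group order
  ct_rev <- contrast_groups(res, sheet, "B", "A")
  expect_equal(ct_rev$t, -ct$t)
  expect_equal(ct_rev$p, ct$p)
})

test_that("degenerate contrasts follow the declared conventions", {
  sheet <- fixture_sheet(6, groups = rep(c("A", "B"), each = 3), ages = 51:56)
  same <- setNames(c(1, 2, 3, 1, 2, 3), sheet$sample_id)
  ct <- contrast_groups(same, sheet, "A", "B")
  expect_equal(ct$t, 0)
  expect_equal(ct$p, 1)

  flat_eq <- setNames(rep(5, 6), sheet$sample_id)
  ct2 <- contrast_groups(flat_eq, sheet, "A", "B")
  expect_equal(c(ct2$t, ct2$p), c(0, 1))

  flat_ne <- setNames(rep(c(1, 2), each = 3), sheet$sample_id)
  expect_error(contrast_groups(flat_ne, sheet, "A", "B"), "zero pooled variance")

  expect_error(contrast_groups(same[1:4], sheet, "A", "B"), "at least 2")
})

test_that("one-way ANOVA matches the sum-of-squares decomposition", {
  sheet <- fixture_sheet(9, groups = rep(c("A", "B", "C"), each = 3),
                         ages = rep(c(1, 2, 3), 3))
  a0 <- anova_oneway(sheet)
  expect_equal(a0$F, 0)
  expect_equal(a0$p, 1)

  set.seed(13)
  ages <- rnorm(9, 60, 8)
  sheet2 <- fixture_sheet(9, groups = rep(c("A", "B", "C"), each = 3), ages = ages)
  a1 <- anova_oneway(sheet2)
  # SS-decomposition oracle
  gm <- mean(ages)
  grp <- rep(c("A", "B", "C"), each = 3)
  ssb <- sum(tapply(ages, grp, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(ages, grp, function(v) sum((v - mean(v))^2)))
  Fo <- (ssb / 2) / (ssw / 6)
  expect_equal(a1$F, Fo, tolerance = 1e-10)
  expect_equal(a1$p, stats::pf(Fo, 2, 6, lower.tail = FALSE), tolerance = 1e-12)

  # two groups: F equals the square of the pooled t statistic
  sheet3 <- fixture_sheet(8, groups = rep(c("A", "B"), each = 4),
                          ages = c(50, 55, 60, 65, 58, 63, 68, 73))
  a2 <- anova_oneway(sheet3)
  t2 <- pooled_t_oracle(sheet3$age[1:4], sheet3$age[5:8])$t^2
  expect_equal(a2$F, t2, tolerance = 1e-10)

  sheet4 <- fixture_sheet(3, groups = c("A", "A", "B"), ages = c(50, 60, 70))
  expect_error(anova_oneway(sheet4), "fewer than 2")
})

test_that("Pearson correlation matches the covariance-formula oracle", {
  expect_equal(pearson_correlation(1:10, 1:10)$r, 1)
  expect_equal(pearson_correlation(1:10, -2 * (1:10) + 7)$r, -1)

  set.seed(17)
  x <- rnorm(10); y <- 0.5 * x + rnorm(10)
  pc <- pearson_correlation(x, y)
  r_o <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_o <- r_o * sqrt(8 / (1 - r_o^2))
  expect_equal(pc$r, r_o, tolerance = 1e-12)
  expect_equal(pc$p, 2 * stats::pt(-abs(t_o), 8), tolerance = 1e-12)

  expect_error(pearson_correlation(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})
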