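test_that("sex-difference tests reduce to closed forms", {
  d <- data.frame(sex = factor(rep(c("F", "M"), each = 3),
                               levels = c("F", "M")),
                  v = c(1, 2, 3, 4, 5, 6),
                  same = rep(c(2, 4, 6), 2))
  tab <- sex_difference_table(d, continuous = c("v", "same"),
                              categorical = character())
  # {1,2,3} vs {4,5,6}: pooled SD 1, SE sqrt(2/3), t = -3.674
  tstat <- (mean(1:3) - mean(4:6)) / sqrt(2 / 3)
  expect_equal(tstat, -3.674, tolerance = 1e-3)
  expect_equal(tab$p[tab$variable == "v"],
               2 * pt(abs(tstat), 4, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(tab$p[tab$variable == "same"], 1)
})

test_that("sex differences in the generated cohort are detected", {
  d <- tiny_derived(n = 1439, seed = 61)
  tab <- sex_difference_table(d)
  expect_lt(tab$p[tab$variable == "adiponectin"], 0.05)
  expect_lt(tab$p[tab$variable == "hdl"], 0.05)
  expect_true(all(tab$p >= 0 & tab$p <= 1, na.rm = TRUE))
})

test_that("adjusted correlations equal partial correlations", {
  set.seed(62)
  n <- 200
  d <- data.frame(a = rnorm(n), b = rnorm(n), z1 = rnorm(n),
                  z2 = rnorm(n))
  d$x <- d$z1 + 0.5 * d$z2 + d$a
  d$y <- -d$z1 + 0.3 * d$z2 + 0.4 * d$a + rnorm(n)
  res <- adjusted_pearson(d, "x", "y", adjusters = c("z1", "z2"))
  # oracle: partial correlation from the inverse correlation matrix
  R <- solve(cor(d[, c("x", "y", "z1", "z2")]))
  r_oracle <- -R[1, 2] / sqrt(R[1, 1] * R[2, 2])
  expect_equal(res$r, r_oracle, tolerance = 1e-10)

  # zero adjusters: plain Pearson, exactly
  res0 <- adjusted_pearson(d, "x", "y", adjusters = character())
  expect_equal(res0$r, cor(d$x, d$y), tolerance = 1e-14)

  # identity: y == x with independent adjusters
  d$yy <- d$x
  expect_equal(adjusted_pearson(d, "x", "yy", c("z1"))$r, 1)
})

test_that("adjusted correlations are null-calibrated under conditional independence", {
  set.seed(63)
  n <- 10000
  z <- rnorm(n)
  d <- data.frame(z = z, x = z + rnorm(n), y = -z + rnorm(n))
  res <- adjusted_pearson(d, "x", "y", adjusters = "z")
  expect_lt(abs(res$r), 0.03)
})

test_that("correlation table reproduces the expected sign structure", {
  d <- tiny_derived(n = 1439, seed = 64)
  tab <- correlation_table(d)
  r_of <- function(v) tab$r[tab$var_x == "log_adiponectin" &
                              tab$var_y == v]
  expect_lt(r_of("homa_ir"), 0)
  expect_gt(r_of("hdl"), 0)
  expect_gt(r_of("pea"), 0)
})

test_that("the interaction LRT behaves like a nested-model deviance test", {
  d <- tiny_derived(n = 600, seed = 65)
  res <- interaction_lrt(d, "log_adiponectin", "pea", "obese",
                         covariates = c("age", "sex"))
  expect_gte(res$lrt_stat, 0)
  expect_equal(res$df, 1L)

  # affine rescaling of covariates leaves the statistic unchanged
  d2 <- d
  d2$age <- 10 * d2$age - 300
  res2 <- interaction_lrt(d2, "log_adiponectin", "pea", "obese",
                          covariates = c("age", "sex"))
  expect_equal(res$lrt_stat, res2$lrt_stat, tolerance = 1e-8)

  # a constant modifier is rejected
  d3 <- d; d3$obese <- TRUE
  expect_error(interaction_lrt(d3, "log_adiponectin", "pea", "obese"),
               "constant")

  # collinear interaction column is reported by name
  d4 <- d; d4$dup <- d4$pea
  expect_error(interaction_lrt(d4, "log_adiponectin", "pea", "dup"),
               "collinear")
})

test_that("the LRT statistic equals twice the log-likelihood gain", {
  set.seed(66)
  n <- 100
  d <- data.frame(x = rnorm(n), z = rnorm(n),
                  m = factor(rep(c("a", "b"), n / 2)))
  d$y <- 0.4 * d$x + 0.2 * d$z + rnorm(n)
  r <- interaction_lrt(d, "y", "x", "m", covariates = "z")
  # oracle: Gaussian ML log-likelihoods from stats::logLik
  m0 <- lm(y ~ x + m + z, data = d)
  m1 <- lm(y ~ x + m + z + x:m, data = d)
  expect_equal(r$lrt_stat,
               as.numeric(2 * (logLik(m1) - logLik(m0))),
               tolerance = 1e-8)
})

test_that("forward selection adds strong predictors and respects the threshold", {
  set.seed(67)
  n <- 700
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                  pea = rnorm(n))
  d$y <- 0.9 * d$x1 + 0.02 * d$x2 + rnorm(n)
  fit <- stepwise_forward(d, "y", candidates = c("x3", "x2", "x1", "pea"))
  expect_equal(fit$selected[1], "x1")  # dominant partial R^2 enters first
  expect_false("pea" %in% fit$selected)
  rep <- fit$report
  expect_true(all(is.na(rep$beta[!rep$selected])))
  expect_true(all(rep$p[!rep$selected] > fit$alpha_enter, na.rm = TRUE))

  # empty candidate set: intercept-only model
  fit0 <- stepwise_forward(d, "y", candidates = character(),
                           forced = "pea")
  expect_equal(length(fit0$selected), 0L)
  expect_equal(names(coef(fit0$model)), c("(Intercept)", "pea"))
})

test_that("selection is invariant to candidate order up to ties", {
  set.seed(68)
  n <- 500
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  d$y <- 0.5 * d$a - 0.4 * d$b + rnorm(n)
  f1 <- stepwise_forward(d, "y", candidates = c("a", "b", "c"))
  f2 <- stepwise_forward(d, "y", candidates = c("c", "b", "a"))
  expect_setequal(f1$selected, f2$selected)
  expect_equal(sort(coef(f1$model)), sort(coef(f2$model)),
               tolerance = 1e-12)
})

test_that("stratified analysis reports the exposure in every stratum", {
  d <- tiny_derived(n = 800, seed = 69)
  res <- stratified_analysis(d, strata = c("obesity", "ir"))
  expect_setequal(res$stratum, c("non_obese", "obese", "non_ir", "ir"))
  expect_true(all(is.finite(res$pea_beta)))
  expect_true(all(is.finite(res$pea_se)))
  expect_true(all(res$r2 >= 0 & res$r2 <= 1))
  # the stratifier itself is never a candidate within its strata
  fits <- attr(res, "fits")
  expect_false("bmi" %in% fits$non_obese$selected)
  expect_false("homa_ir" %in% fits$ir$selected)
})

test_that("strata below the size floor are skipped", {
  d <- tiny_derived(n = 400, seed = 70)
  expect_message(res <- stratified_analysis(d, strata = "obesity",
                                            min_n = 200),
                 "skipped")
  expect_lt(nrow(res), 2L)
  expect_error(suppressMessages(
    stratified_analysis(d[1:4, ], strata = "obesity")),
    "floor")
})

test_that("the diabetes-free sensitivity stratum runs", {
  d <- tiny_derived(n = 800, seed = 71)
  res <- stratified_analysis(d, strata = "no_diabetes")
  expect_equal(res$stratum, "no_diabetes")
  expect_lt(res$n, 800)
})
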