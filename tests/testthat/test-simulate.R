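test_that("simulated panels are seeded and hit the target differential", {
  p1 <- simulate_panel(3, 0.4, seed = 21)
  p2 <- simulate_panel(3, 0.4, seed = 21)
  expect_identical(p1, p2)

  big <- simulate_panel(1000, 0.4, seed = 22)
  expect_gt(mean(big$delta), 0.35)
  expect_lt(mean(big$delta), 0.45)
  expect_error(simulate_panel(10, 0.95), "delta_mean")
})

test_that("true ancestry draws match the calibrated quantiles", {
  s <- simulate_true_pea(100000, seed = 23)
  expect_lt(abs(median(s) - 0.158), 0.01)
  expect_lt(abs(IQR(s) - 0.093), 0.01)
  u <- simulate_true_pea(50000, beta_a = 1, beta_b = 1, seed = 24)
  expect_lt(abs(median(u) - 0.5), 0.02)
  expect_identical(simulate_true_pea(10, seed = 3),
                   simulate_true_pea(10, seed = 3))
})

test_that("quantile matching recovers shapes for other targets", {
  sh <- match_pea_beta(median = 0.3, iqr = 0.2)
  expect_lt(abs(qbeta(0.5, sh["a"], sh["b"]) - 0.3), 1e-4)
  expect_lt(abs(diff(qbeta(c(0.25, 0.75), sh["a"], sh["b"])) - 0.2), 1e-4)
})

test_that("genotype draws follow the binomial admixture model", {
  one <- aim_panel("m", 0.2, 0.9)
  gm <- simulate_genotypes(one, rep(1, 10000), seed = 25)
  expect_lt(abs(mean(gm) - 2 * 0.9), 0.02)  # E dosage = 2 p_eur at s = 1

  gm_na <- simulate_genotypes(one, rep(0.5, 50), missing_rate = 1,
                              seed = 26)
  expect_true(all(is.na(gm_na)))

  # at s = 0 genotype counts follow HWE at p_afr (chi-square oracle)
  p <- aim_panel("m", 0.4, 0.9)
  g <- simulate_genotypes(p, rep(0, 5000), seed = 27)
  obs <- table(factor(g, levels = 0:2))
  expected <- c((1 - 0.4)^2, 2 * 0.4 * 0.6, 0.4^2)
  chi <- chisq.test(obs, p = expected)
  expect_gt(chi$p.value, 0.01)
})

test_that("the generator and the likelihood share one model", {
  # average log-likelihood is maximized near the generating s
  panel <- simulate_panel(400, 0.4, seed = 28)
  for (s0 in c(0.1, 0.35, 0.7)) {
    gm <- simulate_genotypes(panel, rep(s0, 40), seed = 29)
    grid <- seq(0.01, 0.99, 0.01)
    mean_ll <- rowMeans(sapply(seq_len(nrow(gm)), function(i)
      ancestry_loglik(gm[i, ], panel, grid)))
    expect_lt(abs(grid[which.max(mean_ll)] - s0), 0.03)
  }
})

test_that("phenotype tables are reproducible and structurally sound", {
  s <- simulate_true_pea(500, seed = 30)
  cfg <- sim_config(n_individuals = 500, seed = 30)
  a <- simulate_phenotypes(s, cfg, seed = 31)
  b <- simulate_phenotypes(s, cfg, seed = 31)
  expect_identical(a, b)

  expect_true(all(a$adiponectin > 0))
  expect_true(all(a$age >= 21))
  expect_true(all(table(a$sex) > 0))
  frac_f <- mean(a$sex == "F")
  expect_gt(frac_f, 0.52); expect_lt(frac_f, 0.72)
  bmi <- compute_bmi(a$weight, a$height)
  expect_gt(mean(bmi >= 30), 0.40); expect_lt(mean(bmi >= 30), 0.70)
  expect_gt(mean(is.na(a$insulin)), 0.10)
  truth <- attr(a, "truth")
  expect_equal(length(truth$slope), 500L)
})

test_that("a null ancestry effect yields a null stratified slope", {
  cfg <- sim_config(n_individuals = 2000, beta_pea_nonobese = 0,
                    beta_pea_obese = 0, seed = 32)
  s <- simulate_true_pea(2000, seed = 32)
  ph <- simulate_phenotypes(s, cfg, seed = 33)
  truth <- attr(ph, "truth")
  d <- ph[!truth$obese_latent, ]
  fit <- lm(log(adiponectin) ~ s[!truth$obese_latent], data = d)
  ci <- confint(fit)[2, ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("the non-obese stratum recovers the generating slope", {
  # average slope estimate over replicates concentrates near 0.62
  est <- sapply(1:30, function(r) {
    s <- simulate_true_pea(1439, seed = 100 + r)
    ph <- simulate_phenotypes(s, sim_config(seed = 100 + r),
                              seed = 200 + r)
    truth <- attr(ph, "truth")
    keep <- !truth$obese_latent
    coef(lm(log(ph$adiponectin[keep]) ~ s[keep]))[2]
  })
  se_mc <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.62), 4 * se_mc + 0.02)
})

test_that("written cohorts round-trip through the readers", {
  cohort <- tiny_cohort(n = 40, m = 25, seed = 44)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_true(all(file.exists(file.path(dir,
    c("freqs.tsv", "genotypes.tsv", "phenotypes.csv", "truth.json")))))
  panel <- read_frequency_table(file.path(dir, "freqs.tsv"))
  gm <- read_genotypes(file.path(dir, "genotypes.tsv"), panel)
  expect_equal(dim(gm), dim(cohort$genotypes))
  expect_equal(unname(unclass(gm)), unname(unclass(cohort$genotypes)))
})
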