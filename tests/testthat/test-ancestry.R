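test_that("genotype probabilities follow Hardy-Weinberg at the admixed frequency", {
  # symmetric heterozygote: p(s) = 0.5 -> Pr(g=1) = 2 * 0.5 * 0.5
  expect_equal(genotype_prob(1, 0.1, 0.9, 0.5), 0.5)
  # s-invariant when the ancestral frequencies agree
  for (s in c(0, 0.3, 1))
    expect_equal(genotype_prob(2, 0.3, 0.3, s), 0.09)
  # direct HWE arithmetic: (1 - 0.9)^2
  expect_equal(genotype_prob(0, 0.1, 0.9, 1), 0.01)
  expect_error(genotype_prob(3, 0.1, 0.9, 0.5), "dosage")
  expect_error(genotype_prob(1, 0.1, 0.9, 1.5), "s must")
})

test_that("the three genotype probabilities sum to one for random inputs", {
  set.seed(1)
  for (i in 1:200) {
    p1 <- runif(1, 0.001, 0.999); p2 <- runif(1, 0.001, 0.999)
    s <- runif(1)
    tot <- sum(genotype_prob(0:2, p1, p2, s))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("the log-likelihood is additive over loci and flat for uninformative panels", {
  panel <- tiny_panel(2)
  g <- c(1, 2)
  l12 <- ancestry_loglik(g, panel, 0.4)
  l1 <- ancestry_loglik(c(1, NA), panel, 0.4)
  l2 <- ancestry_loglik(c(NA, 2), panel, 0.4)
  expect_equal(l12, l1 + l2, tolerance = 1e-12)

  flat <- aim_panel(c("a", "b"), c(0.3, 0.6), c(0.3, 0.6))
  lls <- ancestry_loglik(c(1, 2), flat, seq(0, 1, 0.1))
  expect_lt(diff(range(lls)), 1e-12)

  expect_error(ancestry_loglik(c(NA, NA), panel, 0.5), "non-missing")
})

test_that("log-likelihood matches an independent product-then-log computation", {
  panel <- tiny_panel(5)
  g <- c(0, 1, 2, 1, 0)
  s <- 0.3
  # oracle: per-locus probabilities multiplied, then logged
  prob <- 1
  for (i in 1:5) {
    p <- s * panel$p_eur[i] + (1 - s) * panel$p_afr[i]
    prob <- prob * dbinom(g[i], 2, p)
  }
  expect_equal(ancestry_loglik(g, panel, s), log(prob), tolerance = 1e-12)
  expect_true(all(ancestry_loglik(g, panel, c(0.1, 0.5, 0.9)) <= 0))
})

test_that("single-locus and boundary maxima are found analytically", {
  one <- aim_panel("m", 0.1, 0.9)
  est <- estimate_ancestry(1, one)
  expect_equal(est$s_hat, 0.5, tolerance = 1e-6)  # p(s)=0.5 maximizes 2p(1-p)

  eur <- aim_panel(paste0("m", 1:20), rep(0.01, 20), rep(0.99, 20))
  est2 <- estimate_ancestry(rep(2, 20), eur)
  expect_equal(est2$s_hat, 1.0)
  expect_equal(est2$flags, "boundary")
  expect_true(is.na(est2$se))
})

test_that("refined estimates agree with a dense grid argmax", {
  set.seed(5)
  panel <- simulate_panel(200, 0.4, seed = 5)
  s_true <- simulate_true_pea(30, seed = 6)
  gm <- simulate_genotypes(panel, s_true, seed = 7)
  grid <- seq(0, 1, length.out = 10000)
  for (i in seq_len(nrow(gm))) {
    est <- estimate_ancestry(gm[i, ], panel)
    llg <- ancestry_loglik(gm[i, ], panel, grid)
    expect_lt(abs(est$s_hat - grid[which.max(llg)]), 1e-4)
    expect_gte(est$loglik, max(llg) - 1e-6)
  }
})

test_that("swapping the ancestral populations maps s_hat to 1 - s_hat", {
  set.seed(8)
  panel <- simulate_panel(150, 0.4, seed = 8)
  swapped <- aim_panel(panel$marker_id, p_afr = panel$p_eur,
                       p_eur = panel$p_afr, eps = panel$eps)
  gm <- simulate_genotypes(panel, simulate_true_pea(10, seed = 9),
                           seed = 10)
  for (i in seq_len(nrow(gm))) {
    a <- estimate_ancestry(gm[i, ], panel)
    b <- estimate_ancestry(gm[i, ], swapped)
    expect_equal(a$s_hat, 1 - b$s_hat, tolerance = 1e-5)
  }
})

test_that("a flat likelihood returns 0.5 with a non-identifiability flag", {
  flat <- aim_panel(c("a", "b"), c(0.3, 0.6), c(0.3, 0.6))
  expect_warning(est <- estimate_ancestry(c(1, 2), flat), "flat")
  expect_equal(est$s_hat, 0.5)
  expect_equal(est$flags, "non_identifiable")
})

test_that("the posterior mean reduces to hand computations", {
  # flat likelihood -> mean of the uniform prior
  flat <- aim_panel(c("a", "b"), c(0.3, 0.6), c(0.3, 0.6))
  expect_equal(posterior_mean_ancestry(c(1, 2), flat), 0.5,
               tolerance = 1e-9)
  # 3-point toy grid with hand-set log-likelihoods
  s <- c(0, 0.5, 1)
  ll <- log(c(1, 2, 1))
  expect_equal(admixcor:::posterior_mean_from_loglik(s, ll),
               (0 * 1 + 0.5 * 2 + 1 * 1) / 4)
})

test_that("cohort estimation drops all-missing individuals and is deterministic", {
  panel <- tiny_panel(4)
  g <- rbind(c(1, 2, 0, 1), c(NA, NA, NA, NA), c(1, 2, 0, 1))
  gm <- genotype_matrix(g, paste0("i", 1:3), panel$marker_id)
  expect_message(est <- estimate_cohort(gm, panel, min_markers = 1),
                 "dropping 1")
  expect_equal(nrow(est), 2L)
  expect_equal(attr(est, "dropped")$individual_id, "i2")
  # duplicated genotypes give identical estimates
  expect_equal(est$s_hat[1], est$s_hat[2])
  expect_error(estimate_cohort(gm[0, , drop = FALSE], panel), "empty")
})

test_that("estimation error shrinks as the panel grows", {
  set.seed(12)
  s_true <- simulate_true_pea(60, seed = 12)
  rmse <- sapply(c(50, 200, 1000), function(m) {
    panel <- simulate_panel(m, 0.4, seed = 13)
    gm <- simulate_genotypes(panel, s_true, seed = 14)
    sh <- estimate_cohort(gm, panel)$s_hat
    sqrt(mean((sh - s_true)^2))
  })
  # monotone information, with slack for Monte-Carlo noise
  expect_lt(rmse[2], rmse[1] * 1.1)
  expect_lt(rmse[3], rmse[2] * 1.1)
  expect_lt(rmse[3], rmse[1])
})
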