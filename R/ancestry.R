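#' Genotype probability under the admixture Hardy-Weinberg model
#'
#' For an individual with European ancestry proportion `s`, the counted
#' allele at a marker has frequency `p(s) = s * p_eur + (1 - s) * p_afr`
#' and the genotype dosage is Binomial(2, p(s)) — Hardy-Weinberg
#' proportions at the individual's admixed allele frequency.  This is
#' the one-parameter genotype model behind classical maximum-likelihood
#' individual-admixture estimators.
#'
#' @param g dosage in `{0, 1, 2}` (`NA` propagates: the locus carries no
#'   likelihood contribution and callers skip it).
#' @param p_afr,p_eur clamped ancestral allele frequencies.
#' @param s ancestry proportion in `[0, 1]`.
#' @return `Pr(G = g | s)`; vectorized over all arguments.
#' @export
genotype_prob <- function(g, p_afr, p_eur, s) {
  if (any(s < 0 | s > 1, na.rm = TRUE)) stop("s must lie in [0, 1]")
  ok <- is.na(g) | g %in% c(0, 1, 2)
  if (!all(ok)) stop("dosage must be 0, 1, 2 or NA")
  p <- s * p_eur + (1 - s) * p_afr
  stats::dbinom(g, size = 2, prob = p)
}

# log-likelihood of one individual's dosages over a vector of s values.
# g, p_afr, p_eur: per-locus vectors (NA dosages already removed);
# returns length(s) vector. Uses the binomial kernel directly:
#   l(s) = sum_i [ g_i log p_i(s) + (2 - g_i) log(1 - p_i(s)) + log C(2, g_i) ]
loglik_grid <- function(g, p_afr, p_eur, s) {
  lchoose2 <- c(0, log(2), 0)[g + 1L]
  d <- p_eur - p_afr
  vapply(s, function(si) {
    p <- p_afr + si * d
    sum(g * log(p) + (2 - g) * log1p(-p)) + sum(lchoose2)
  }, numeric(1))
}

#' Admixture log-likelihood for one individual
#'
#' Sum over non-missing loci of the log genotype probability
#' [genotype_prob] at ancestry proportion `s`; missing loci are skipped
#' (the likelihood is a product over observed loci only).
#'
#' @param genotypes dosage vector aligned to `panel` (names, if present,
#'   must match the panel's marker ids).
#' @param panel an [aim_panel] (clamped).
#' @param s ancestry proportion(s) in `[0, 1]`; vectorized.
#' @return Natural-log likelihood, one value per element of `s`.
#' @export
ancestry_loglik <- function(genotypes, panel, s) {
  stopifnot(inherits(panel, "aim_panel"))
  if (length(genotypes) != panel$n_markers)
    stop("genotype vector length must match the panel")
  if (any(s < 0 | s > 1)) stop("s must lie in [0, 1]")
  obs <- !is.na(genotypes)
  if (!any(obs)) stop("no non-missing genotypes")
  g <- genotypes[obs]
  if (!all(g %in% c(0, 1, 2))) stop("dosage must be 0, 1, 2 or NA")
  loglik_grid(g, panel$p_afr[obs], panel$p_eur[obs], s)
}

#' Maximum-likelihood ancestry proportion for one individual
#'
#' Maximizes the admixture log-likelihood over `s` in `[0, 1]` by a
#' coarse grid scan followed by bounded derivative-free refinement
#' ([stats::optimize]); the boundaries are always evaluated explicitly
#' and ties are broken toward the smaller `s`.  The standard error comes
#' from the observed information (negative numerical second derivative)
#' at interior optima and is `NA` at the boundary.
#'
#' @param genotypes dosage vector aligned to `panel`.
#' @param panel an [aim_panel].
#' @param tol refinement tolerance for [stats::optimize].
#' @param grid_n number of points in the coarse scan.
#' @param individual_id optional identifier carried into the result.
#' @return An `ancestry_estimate`: list with `individual_id`, `s_hat`,
#'   `loglik`, `se`, `n_used` and `flags` (`""`, `"boundary"` or
#'   `"non_identifiable"`).
#' @export
estimate_ancestry <- function(genotypes, panel, tol = 1e-6, grid_n = 101L,
                              individual_id = NA_character_) {
  stopifnot(inherits(panel, "aim_panel"))
  obs <- !is.na(genotypes)
  if (!any(obs)) stop("no non-missing genotypes")
  g <- genotypes[obs]
  p1 <- panel$p_afr[obs]
  p2 <- panel$p_eur[obs]
  ll <- function(s) loglik_grid(g, p1, p2, s)
  grid <- seq(0, 1, length.out = max(grid_n, 5L))
  llg <- ll(grid)

  flags <- ""
  if (diff(range(llg)) < 1e-12) {
    # all p_afr == p_eur (or no information): likelihood flat in s
    s_hat <- 0.5
    flags <- "non_identifiable"
    warning("flat likelihood: ancestry not identifiable; s_hat set to 0.5")
    out <- list(individual_id = individual_id, s_hat = s_hat,
                loglik = ll(s_hat), se = NA_real_,
                n_used = sum(obs), flags = flags)
    class(out) <- "ancestry_estimate"
    return(out)
  }

  i0 <- which.max(llg)          # first max -> smaller s on ties
  h <- grid[2L] - grid[1L]
  lo <- max(0, grid[i0] - h)
  hi <- min(1, grid[i0] + h)
  opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = tol)
  # candidates: refined optimum, best grid point, both boundaries;
  # among candidates within tol of the best, take the smallest s
  cand_s <- c(0, opt$maximum, grid[i0], 1)
  cand_ll <- c(llg[1L], opt$objective, llg[i0], llg[length(grid)])
  near <- cand_ll >= max(cand_ll) - tol
  s_hat <- min(cand_s[near])
  ll_max <- ll(s_hat)

  se <- NA_real_
  dh <- 1e-4
  if (s_hat > dh && s_hat < 1 - dh) {
    d2 <- (ll(s_hat + dh) - 2 * ll_max + ll(s_hat - dh)) / dh^2
    if (is.finite(d2) && d2 < 0) se <- 1 / sqrt(-d2)
  } else {
    flags <- "boundary"
  }
  out <- list(individual_id = individual_id, s_hat = s_hat,
              loglik = ll_max, se = se, n_used = sum(obs), flags = flags)
  class(out) <- "ancestry_estimate"
  out
}

#' @export
print.ancestry_estimate <- function(x, ...) {
  cat(sprintf("ancestry estimate%s: s_hat = %.4f (se %s), loglik %.2f, %d markers%s\n",
              if (is.na(x$individual_id)) "" else paste0(" [", x$individual_id, "]"),
              x$s_hat, ifelse(is.na(x$se), "NA", sprintf("%.4f", x$se)),
              x$loglik, x$n_used,
              if (nzchar(x$flags)) paste0(" [", x$flags, "]") else ""))
  invisible(x)
}

#' Flat-prior posterior-mean ancestry proportion
#'
#' Alternate estimator used for cross-method agreement checks: the
#' posterior mean of `s` under a uniform prior on `[0, 1]`,
#' `E[s | G] = \int s L(s) ds / \int L(s) ds`, computed on a uniform
#' grid in log space with max-subtraction for numerical stability.
#'
#' @inheritParams estimate_ancestry
#' @param grid_n number of grid points.
#' @return The posterior-mean estimate in `[0, 1]`.
#' @export
posterior_mean_ancestry <- function(genotypes, panel, grid_n = 1001L) {
  ll <- ancestry_loglik(genotypes, panel,
                        s <- seq(0, 1, length.out = max(grid_n, 3L)))
  posterior_mean_from_loglik(s, ll)
}

# weighted mean of s under weights exp(ll), stabilized by max-subtraction
posterior_mean_from_loglik <- function(s, ll) {
  w <- exp(ll - max(ll))
  sum(s * w) / sum(w)
}

#' Estimate ancestry for every individual in a cohort
#'
#' Runs [estimate_ancestry] over the rows of a genotype matrix,
#' dropping individuals with fewer than `min_markers` non-missing
#' genotypes (dropped ids and reasons are recorded in the
#' `"dropped"` attribute) and attaching cohort summary statistics of
#' the estimates.
#'
#' @param gm a [genotype_matrix].
#' @param panel an [aim_panel]; the matrix columns must be a subset of
#'   its markers.
#' @param min_markers minimum non-missing markers per retained
#'   individual.
#' @inheritParams estimate_ancestry
#' @return A data.frame with columns `individual_id`, `s_hat`, `se`,
#'   `loglik`, `n_used`, `flags`; attributes `dropped` (data.frame) and
#'   `summary` (median, IQR, mean, SD of `s_hat`).
#' @export
estimate_cohort <- function(gm, panel, min_markers = 1L, tol = 1e-6,
                            grid_n = 101L) {
  if (nrow(gm) == 0L) stop("empty cohort")
  al <- align_to_panel(gm, panel)
  gm <- al$gm; panel <- al$panel
  n_used <- rowSums(!is.na(gm))
  keep <- n_used >= min_markers
  dropped <- data.frame(
    individual_id = rownames(gm)[!keep],
    reason = rep(sprintf("fewer than %d non-missing markers",
                         min_markers), sum(!keep)))
  if (nrow(dropped))
    message("dropping ", nrow(dropped), " individual(s) with < ",
            min_markers, " non-missing markers")
  if (!any(keep)) stop("no individuals with enough non-missing markers")
  est <- lapply(which(keep), function(i)
    estimate_ancestry(gm[i, ], panel, tol = tol, grid_n = grid_n,
                      individual_id = rownames(gm)[i]))
  out <- data.frame(
    individual_id = vapply(est, `[[`, character(1), "individual_id"),
    s_hat = vapply(est, `[[`, numeric(1), "s_hat"),
    se = vapply(est, `[[`, numeric(1), "se"),
    loglik = vapply(est, `[[`, numeric(1), "loglik"),
    n_used = vapply(est, `[[`, numeric(1), "n_used"),
    flags = vapply(est, `[[`, character(1), "flags"),
    stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  attr(out, "summary") <- c(median = stats::median(out$s_hat),
                            iqr = stats::IQR(out$s_hat),
                            mean = mean(out$s_hat),
                            sd = stats::sd(out$s_hat))
  out
}

#' Theoretical ancestry standard error from the expected information
#'
#' For the Binomial(2, p(s)) genotype model the per-locus expected
#' (Fisher) information at ancestry `s` is
#' `2 d^2 / (p(s) (1 - p(s)))` with `d = p_eur - p_afr`; summing over
#' the panel and inverting gives the asymptotic variance of the MLE.
#' Used as the oracle for parameter-recovery checks.
#'
#' @param panel an [aim_panel].
#' @param s true ancestry proportion(s); vectorized.
#' @return Theoretical standard error(s) `1 / sqrt(I(s))`.
#' @export
theoretical_ancestry_se <- function(panel, s) {
  stopifnot(inherits(panel, "aim_panel"))
  d <- panel$p_eur - panel$p_afr
  vapply(s, function(si) {
    p <- panel$p_afr + si * d
    1 / sqrt(sum(2 * d^2 / (p * (1 - p))))
  }, numeric(1))
}

#' Write cohort ancestry estimates to CSV
#' @param estimates data.frame from [estimate_cohort].
#' @param path output path.
#' @export
write_ancestry <- function(estimates, path) {
  utils::write.csv(estimates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
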