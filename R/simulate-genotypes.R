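#' Beta shape parameters calibrated to the study PEA distribution
#'
#' Quantile-matched so that Beta(a, b) has median 0.158 and
#' interquartile range 0.093 — the proportion-of-European-ancestry
#' distribution the cohort generator reproduces.  Obtained with
#' [match_pea_beta]; shipped as constants so simulations are stable.
#'
#' @format Named numeric vector with elements `a` and `b`.
#' @export
pea_beta_shapes <- c(a = 4.671091, b = 23.47476)

#' Quantile-match Beta shape parameters to a median and IQR
#'
#' Solves for `(a, b)` such that `qbeta(0.5, a, b) = median` and
#' `qbeta(0.75) - qbeta(0.25) = iqr`, by least squares on the two
#' quantile residuals.  This is the matching routine that produced
#' [pea_beta_shapes].
#'
#' @param median target median in (0, 1).
#' @param iqr target interquartile range.
#' @return Named vector `c(a = , b = )`.
#' @export
match_pea_beta <- function(median = 0.158, iqr = 0.093) {
  stopifnot(median > 0, median < 1, iqr > 0, iqr < 1)
  obj <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    (stats::qbeta(0.5, a, b) - median)^2 +
      ((stats::qbeta(0.75, a, b) - stats::qbeta(0.25, a, b)) - iqr)^2
  }
  o <- stats::optim(c(log(4), log(20)), obj,
                    control = list(reltol = 1e-14, maxit = 2000))
  c(a = exp(o$par[1]), b = exp(o$par[2]))
}

#' Simulate an AIM panel
#'
#' Draws African-reference frequencies uniformly on `[0.05, 0.95]` and
#' sets the European-reference frequency at a differential drawn around
#' `delta_mean` (Normal, SD 0.05, truncated to be positive) with random
#' sign; when the drawn direction would leave `[eps, 1 - eps]`, the
#' feasible direction is used instead, so the realized mean
#' differential stays close to `delta_mean`.
#'
#' @param n_markers number of markers.
#' @param delta_mean target mean `|p_afr - p_eur|`, in `(0, 0.9)`.
#' @param seed integer seed.
#' @param eps clamping bound.
#' @return An [aim_panel].
#' @export
simulate_panel <- function(n_markers, delta_mean = 0.4, seed = 1L,
                           eps = 0.001) {
  stopifnot(n_markers >= 1)
  if (delta_mean <= 0 || delta_mean >= 0.9)
    stop("delta_mean must lie in (0, 0.9)")
  set.seed(seed)
  p_afr <- stats::runif(n_markers, 0.05, 0.95)
  delta <- abs(stats::rnorm(n_markers, delta_mean, 0.05))
  delta <- pmin(delta, 0.9)
  sign <- ifelse(stats::runif(n_markers) < 0.5, 1, -1)
  up_ok <- p_afr + delta <= 1 - eps
  dn_ok <- p_afr - delta >= eps
  sign[sign > 0 & !up_ok & dn_ok] <- -1
  sign[sign < 0 & !dn_ok & up_ok] <- 1
  p_eur <- pmin(pmax(p_afr + sign * delta, eps), 1 - eps)
  aim_panel(sprintf("aim_%05d", seq_len(n_markers)), p_afr, p_eur,
            eps = eps)
}

#' Simulate true ancestry proportions
#'
#' I.i.d. Beta draws; the default shapes [pea_beta_shapes] reproduce a
#' European-ancestry distribution with median 0.158 and IQR 0.093.
#'
#' @param n number of individuals.
#' @param beta_a,beta_b Beta shape parameters (> 0).
#' @param seed integer seed.
#' @return Numeric vector of true proportions in `[0, 1]`.
#' @export
simulate_true_pea <- function(n, beta_a = pea_beta_shapes[["a"]],
                              beta_b = pea_beta_shapes[["b"]], seed = 1L) {
  stopifnot(n >= 1, beta_a > 0, beta_b > 0)
  set.seed(seed)
  stats::rbeta(n, beta_a, beta_b)
}

#' Simulate genotype dosages for admixed individuals
#'
#' The generative twin of the estimation model: each dosage is drawn
#' Binomial(2, p_i(s_j)) with `p_i(s) = s * p_eur_i + (1 - s) * p_afr_i`,
#' independently across loci, then masked missing with probability
#' `missing_rate`.
#'
#' @param panel an [aim_panel].
#' @param s_true vector of true ancestry proportions in `[0, 1]`.
#' @param missing_rate per-entry missingness probability.
#' @param seed integer seed.
#' @return A [genotype_matrix], `length(s_true)` rows.
#' @export
simulate_genotypes <- function(panel, s_true, missing_rate = 0, seed = 1L) {
  stopifnot(inherits(panel, "aim_panel"),
            all(s_true >= 0 & s_true <= 1),
            missing_rate >= 0, missing_rate <= 1)
  set.seed(seed)
  n <- length(s_true)
  m <- panel$n_markers
  # p is n x m: outer over individuals (rows) and loci (cols)
  p <- outer(s_true, panel$p_eur) + outer(1 - s_true, panel$p_afr)
  g <- matrix(stats::rbinom(n * m, size = 2, prob = p), nrow = n)
  if (missing_rate > 0)
    g[stats::runif(n * m) < missing_rate] <- NA
  genotype_matrix(g, sprintf("ind_%05d", seq_len(n)), panel$marker_id)
}
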