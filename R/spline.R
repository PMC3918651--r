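#' Penalized cubic-spline test of linearity for the ancestry effect
#'
#' Fits a Gaussian additive model
#' `log_adiponectin ~ covariates + s(pea)` with a penalized cubic
#' regression spline (basis dimension `k`, knots on quantiles,
#' smoothing parameter by generalized cross-validation) and compares
#' deviances against two nested models: the covariates-only model
#' (`p_deviance`: does ancestry carry signal at all?) and the model
#' with a linear ancestry term (`p_nonlinearity`: does the smooth add
#' anything beyond a straight line?).  Both comparisons use the
#' approximate F-test of [mgcv::anova.gam].  A relation is declared
#' non-linear only under the compound rule: significant non-linearity
#' **and** estimated degrees of freedom of the smooth greater than 3.
#'
#' @param data data.frame (typically a [derive_cohort] table or a
#'   stratum of one).
#' @param outcome outcome column, default `"log_adiponectin"`.
#' @param exposure smoothed exposure column, default `"pea"`.
#' @param covariates linear adjustment columns.
#' @param k spline basis dimension.
#' @param alpha significance level for the compound rule.
#' @param stratum label carried into the result.
#' @param min_n minimum observations.
#' @return A `spline_fit`: list with `stratum`, `n`, `edf`,
#'   `dev_with`, `dev_without`, `p_deviance`, `p_nonlinearity`,
#'   `nonlinear_flag` and the three fitted models.
#' @export
fit_pea_spline <- function(data, outcome = "log_adiponectin",
                           exposure = "pea",
                           covariates = c("age", "sex"), k = 10,
                           alpha = 0.05, stratum = "all", min_n = 50L) {
  vars <- c(outcome, exposure, covariates)
  stopifnot(all(vars %in% names(data)))
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars,
            drop = FALSE]
  if (nrow(d) < min_n)
    stop("stratum '", stratum, "': n = ", nrow(d), " < ", min_n)
  if (length(unique(d[[exposure]])) < 10L)
    stop("exposure needs at least 10 unique values")
  rhs0 <- if (length(covariates)) paste(covariates, collapse = " + ")
          else "1"
  f0 <- stats::as.formula(paste(outcome, "~", rhs0))
  flin <- stats::as.formula(paste(outcome, "~", rhs0, "+", exposure))
  fsm <- stats::as.formula(paste0(outcome, " ~ ", rhs0, " + s(",
                                  exposure, ", bs = \"cr\", k = ", k,
                                  ")"))
  m0 <- mgcv::gam(f0, data = d, method = "GCV.Cp")
  mlin <- mgcv::gam(flin, data = d, method = "GCV.Cp")
  msm <- mgcv::gam(fsm, data = d, method = "GCV.Cp")
  if (!msm$converged)
    stop("smoothing-parameter search did not converge (n = ", nrow(d),
         ", k = ", k, "); GCV/UBRE score ", format(msm$gcv.ubre))
  edf <- sum(summary(msm)$edf)
  dev_with <- stats::deviance(msm)
  dev_without <- stats::deviance(m0)
  p_dev <- anova_gam_p(m0, msm)
  p_nl <- anova_gam_p(mlin, msm)
  structure(list(
    stratum = stratum, n = nrow(d), edf = edf,
    dev_with = dev_with, dev_without = dev_without,
    p_deviance = p_dev, p_nonlinearity = p_nl,
    nonlinear_flag = isTRUE(p_nl <= alpha && edf > 3),
    alpha = alpha, k = k,
    model_null = m0, model_linear = mlin, model_smooth = msm,
    exposure = exposure, data = d), class = "spline_fit")
}

# approximate F-test p-value for nested gam models; a smooth that has
# collapsed onto the smaller model (no deviance or df gain) gives p = 1
anova_gam_p <- function(small, big) {
  a <- stats::anova(small, big, test = "F")
  ddev <- a[2L, "Deviance"]
  ddf <- a[2L, "Df"]
  if (is.na(ddev) || is.na(ddf) || ddev <= 0 || ddf < 0.01) return(1)
  p <- a[2L, "Pr(>F)"]
  if (is.na(p)) 1 else p
}

#' @export
print.spline_fit <- function(x, ...) {
  cat(sprintf("cubic-spline fit [%s]: n = %d, edf = %.2f\n",
              x$stratum, x$n, x$edf))
  cat(sprintf("  deviance %.2f (with) vs %.2f (without), p = %.4g\n",
              x$dev_with, x$dev_without, x$p_deviance))
  cat(sprintf("  non-linearity p = %.4g -> %s\n", x$p_nonlinearity,
              if (x$nonlinear_flag) "NON-LINEAR" else "linear"))
  invisible(x)
}

#' Spline linearity tests across cohort strata
#'
#' Runs [fit_pea_spline] in the four strata of the obesity and
#' insulin-resistance classifications.
#'
#' @param derived a [derive_cohort] table.
#' @param strata subset of `c("obesity", "ir")`.
#' @inheritParams fit_pea_spline
#' @return Named list of `spline_fit` objects (strata below `min_n`
#'   are skipped with a message).
#' @export
fit_pea_splines <- function(derived, strata = c("obesity", "ir"),
                            covariates = c("age", "sex"), k = 10,
                            alpha = 0.05, min_n = 50L) {
  subsets <- list()
  if ("obesity" %in% strata) {
    subsets$obese <- derived$obese
    subsets$non_obese <- !derived$obese
  }
  if ("ir" %in% strata) {
    subsets$ir <- derived$insulin_resistant
    subsets$non_ir <- !derived$insulin_resistant
  }
  fits <- list()
  for (nm in names(subsets)) {
    idx <- subsets[[nm]]
    idx[is.na(idx)] <- FALSE
    if (sum(idx) < min_n) {
      message("stratum '", nm, "' skipped: n = ", sum(idx))
      next
    }
    fits[[nm]] <- fit_pea_spline(derived[idx, , drop = FALSE],
                                 covariates = covariates, k = k,
                                 alpha = alpha, stratum = nm,
                                 min_n = min_n)
  }
  fits
}

#' Summarize spline fits as a table
#' @param fits list from [fit_pea_splines] (or a single `spline_fit`).
#' @return data.frame, one row per stratum.
#' @export
spline_table <- function(fits) {
  if (inherits(fits, "spline_fit")) fits <- list(fits)
  do.call(rbind, lapply(fits, function(f)
    data.frame(stratum = f$stratum, n = f$n, edf = f$edf,
               dev_with = f$dev_with, dev_without = f$dev_without,
               p_deviance = f$p_deviance,
               p_nonlinearity = f$p_nonlinearity,
               nonlinear_flag = f$nonlinear_flag)))
}

#' Plot fitted ancestry smooths
#'
#' One panel per stratum: the fitted smooth of the ancestry effect
#' with pointwise 95% band and a rug of observed ancestry values.
#'
#' @param fits list from [fit_pea_splines] or a single fit.
#' @param file optional PNG path; if `NULL`, plots to the current
#'   device.
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_pea_splines <- function(fits, file = NULL) {
  if (inherits(fits, "spline_fit")) fits <- list(fits)
  if (!is.null(file))
    grDevices::png(file, width = 1200,
                   height = 300 * ceiling(length(fits) / 2), res = 120)
  op <- graphics::par(mfrow = c(ceiling(length(fits) / 2),
                                min(2, length(fits))),
                      mar = c(4, 4, 2, 1))
  on.exit({
    graphics::par(op)
    if (!is.null(file)) grDevices::dev.off()
  })
  for (f in fits) {
    mgcv::plot.gam(f$model_smooth, select = 1, shade = TRUE,
                   rug = TRUE, main = f$stratum,
                   xlab = "proportion of European ancestry",
                   ylab = "partial effect on log adiponectin")
  }
  invisible(file)
}
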