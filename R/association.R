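#' Sex-difference descriptive table
#'
#' Per-variable comparison of women and men: continuous variables by
#' the classical (equal-variance) unpaired Student t-test, categorical
#' variables by the chi-square test (without continuity correction).
#' Output has the shape of a descriptive "Table 1": mean +/- SD or
#' percentage per sex with a p-value per row.
#'
#' @param data data.frame with a `sex` factor (`F`/`M`).
#' @param continuous names of continuous columns to test.
#' @param categorical names of categorical columns to test.
#' @param welch use the Welch (unequal-variance) t-test instead.
#' @return data.frame: `variable`, `women`, `men`, `n`, `p`, `test`.
#' @export
sex_difference_table <- function(data,
                                 continuous = c("age", "adiponectin",
                                                "pea", "bmi", "waist",
                                                "triglycerides", "hdl",
                                                "glucose", "homa_ir",
                                                "sbp", "dbp", "activity",
                                                "crp"),
                                 categorical = c("diabetic", "alcohol",
                                                 "education"),
                                 welch = FALSE) {
  stopifnot("sex" %in% names(data))
  f <- data$sex == "F"
  if (sum(f) == 0L || sum(!f) == 0L) stop("both sexes must be present")
  rows <- list()
  for (v in intersect(continuous, names(data))) {
    x <- data[[v]][f]; y <- data[[v]][!f]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) {
      rows[[v]] <- data.frame(variable = v, women = NA, men = NA,
                              n = length(x) + length(y), p = NA,
                              test = "untestable")
      next
    }
    p <- if (stats::sd(x) == 0 && stats::sd(y) == 0 &&
             mean(x) == mean(y)) 1
         else stats::t.test(x, y, var.equal = !welch)$p.value
    rows[[v]] <- data.frame(
      variable = v,
      women = sprintf("%.1f ± %.1f", mean(x), stats::sd(x)),
      men = sprintf("%.1f ± %.1f", mean(y), stats::sd(y)),
      n = length(x) + length(y), p = p, test = "t")
  }
  for (v in intersect(categorical, names(data))) {
    x <- data[[v]]
    ok <- !is.na(x)
    tab <- table(data$sex[ok], as.character(x[ok]))
    if (any(dim(tab) < 2L) || any(rowSums(tab) < 2L)) {
      rows[[v]] <- data.frame(variable = v, women = NA, men = NA,
                              n = sum(ok), p = NA, test = "untestable")
      next
    }
    lev <- colnames(tab)[ncol(tab)]
    pct <- prop.table(tab, 1)[, lev] * 100
    rows[[v]] <- data.frame(
      variable = v,
      women = sprintf("%.0f%% %s", pct[["F"]], lev),
      men = sprintf("%.0f%% %s", pct[["M"]], lev),
      n = sum(ok),
      p = suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value),
      test = "chisq")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Covariate-adjusted Pearson correlation
#'
#' Residualizes both variables on the adjusters by ordinary least
#' squares (with intercept) and returns the Pearson correlation of the
#' residuals, with `t = r sqrt((n - 2 - k) / (1 - r^2))` on
#' `n - 2 - k` degrees of freedom for the two-sided p-value (`k`
#' adjusters).  With no adjusters this is the plain Pearson
#' correlation.
#'
#' @param data data.frame.
#' @param x,y column names of the two variables.
#' @param adjusters character vector of adjuster column names (factors
#'   allowed), default age and sex.
#' @return data.frame row: `var_x`, `var_y`, `r`, `p`, `n`,
#'   `adjusters`.
#' @export
adjusted_pearson <- function(data, x, y, adjusters = c("age", "sex")) {
  vars <- c(x, y, adjusters)
  stopifnot(all(vars %in% names(data)))
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars,
            drop = FALSE]
  n <- nrow(d)
  k <- if (length(adjusters))
    ncol(stats::model.matrix(
      stats::reformulate(adjusters), data = d)) - 1L else 0L
  if (n <= k + 2L) stop("too few complete cases (", n, ") for ",
                        k, " adjuster column(s)")
  resid_on <- function(v) {
    if (length(adjusters) == 0L) return(d[[v]] - mean(d[[v]]))
    stats::residuals(stats::lm(stats::reformulate(adjusters, v), data = d))
  }
  rx <- resid_on(x); ry <- resid_on(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("constant residuals: correlation undefined")
    r <- NA_real_; p <- NA_real_
  } else {
    r <- stats::cor(rx, ry)
    df <- n - 2L - k
    tstat <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  }
  data.frame(var_x = x, var_y = y, r = r, p = p, n = n,
             adjusters = paste(adjusters, collapse = "+"))
}

#' Age- and sex-adjusted correlation table
#'
#' Adjusted correlations of each covariate with log-adiponectin and
#' with the ancestry proportion — the "Table 2" surface.
#'
#' @param derived a [derive_cohort] table.
#' @param vars covariates to correlate.
#' @param adjusters adjusters, default age and sex.
#' @return data.frame with one row per variable and correlation target.
#' @export
correlation_table <- function(derived,
                              vars = c("pea", "bmi", "waist",
                                       "triglycerides", "hdl", "glucose",
                                       "homa_ir", "sbp", "dbp",
                                       "activity", "crp"),
                              adjusters = c("age", "sex")) {
  vars <- intersect(vars, names(derived))
  out <- list()
  for (v in vars) {
    out[[paste0("adipo_", v)]] <-
      adjusted_pearson(derived, "log_adiponectin", v, adjusters)
    if (v != "pea")
      out[[paste0("pea_", v)]] <-
        adjusted_pearson(derived, "pea", v, adjusters)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Likelihood-ratio test of effect modification
#'
#' Fits nested Gaussian linear models with and without the
#' exposure-by-modifier interaction term(s) and compares maximized
#' log-likelihoods: `LRT = 2 (l1 - l0) = n log(RSS0 / RSS1)`, referred
#' to a chi-square with as many degrees of freedom as interaction
#' columns.  Negative statistics from numerical noise are clipped at 0.
#'
#' @param data data.frame.
#' @param outcome,exposure,modifier column names.
#' @param covariates further adjustment columns (main effects).
#' @return data.frame row: `modifier`, `lrt_stat`, `df`, `p`, `n`,
#'   `model_terms`.
#' @export
interaction_lrt <- function(data, outcome, exposure, modifier,
                            covariates = character()) {
  vars <- c(outcome, exposure, modifier, covariates)
  stopifnot(all(vars %in% names(data)))
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars,
            drop = FALSE]
  if (length(unique(d[[modifier]])) < 2L)
    stop("modifier '", modifier, "' is constant")
  main <- c(exposure, modifier, covariates)
  f0 <- stats::reformulate(main, outcome)
  f1 <- stats::reformulate(c(main, paste0(exposure, ":", modifier)),
                           outcome)
  m0 <- stats::lm(f0, data = d)
  m1 <- stats::lm(f1, data = d)
  b1 <- stats::coef(m1)
  if (any(is.na(b1)))
    stop("rank-deficient interaction model; collinear term(s): ",
         paste(names(b1)[is.na(b1)], collapse = ", "))
  df <- length(b1) - length(stats::coef(m0))
  if (df < 1L) stop("interaction added no parameters")
  n <- nrow(d)
  lrt <- max(0, n * log(sum(stats::residuals(m0)^2) /
                          sum(stats::residuals(m1)^2)))
  data.frame(modifier = modifier, lrt_stat = lrt, df = df,
             p = stats::pchisq(lrt, df, lower.tail = FALSE), n = n,
             model_terms = paste(main, collapse = "+"))
}

# ---- fast least-squares helpers for the stepwise scan -----------------

# residual sum of squares of y on columns X (with intercept already in X)
rss_fit <- function(X, y) {
  f <- stats::.lm.fit(X, y)
  sum(f$residuals^2)
}

#' Forward-stepwise linear regression
#'
#' Starts from intercept plus any `forced` terms and repeatedly adds
#' the candidate with the smallest partial-F p-value, as long as that
#' p-value is at most `alpha_enter`; no removal step.  Ties are broken
#' by candidate order.  Every candidate's final status is reported:
#' selected candidates with coefficient, SE and p-value from the final
#' model; unselected candidates with the p-value they would have had
#' if added to the final model (the "dash" convention of stepwise
#' regression tables).
#'
#' @param data data.frame; complete cases over all variables are used.
#' @param outcome outcome column name.
#' @param candidates character vector of candidate columns.
#' @param forced columns always kept in the model.
#' @param alpha_enter entry threshold, default 0.05.
#' @return A `stepwise_fit`: list with `model` (the final [stats::lm]),
#'   `selected` (in entry order), `report` (per-candidate data.frame),
#'   `r2`, `n`, `alpha_enter`.
#' @export
stepwise_forward <- function(data, outcome, candidates,
                             forced = character(), alpha_enter = 0.05) {
  stopifnot(length(candidates) >= 0, alpha_enter > 0, alpha_enter < 1)
  vars <- c(outcome, forced, candidates)
  stopifnot(all(vars %in% names(data)))
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars,
            drop = FALSE]
  n <- nrow(d)
  y <- d[[outcome]]
  # one numeric column per candidate/forced term (factors -> contrasts)
  col_of <- function(v) {
    x <- d[[v]]
    if (is.numeric(x)) matrix(x, ncol = 1L)
    else stats::model.matrix(~x)[, -1L, drop = FALSE]
  }
  cols <- lapply(stats::setNames(c(forced, candidates),
                                 c(forced, candidates)), col_of)
  X <- cbind(`(Intercept)` = rep(1, n),
             do.call(cbind, c(list(matrix(nrow = n, ncol = 0)),
                              cols[forced])))
  selected <- character()
  remaining <- candidates
  rss0 <- rss_fit(X, y)
  repeat {
    if (!length(remaining)) break
    p_terms <- ncol(X)
    if (n <= p_terms + 2L) {
      warning("too few observations to continue selection")
      break
    }
    pvals <- vapply(remaining, function(v) {
      Xc <- cbind(X, cols[[v]])
      df2 <- n - ncol(Xc)
      if (df2 < 1L) return(NA_real_)
      rss1 <- rss_fit(Xc, y)
      q <- ncol(cols[[v]])
      Fstat <- ((rss0 - rss1) / q) / (rss1 / df2)
      stats::pf(Fstat, q, df2, lower.tail = FALSE)
    }, numeric(1))
    if (all(is.na(pvals))) break
    best <- which(pvals == min(pvals, na.rm = TRUE))[1L]  # tie: order
    if (is.na(pvals[best]) || pvals[best] > alpha_enter) break
    v <- remaining[best]
    X <- cbind(X, cols[[v]])
    rss0 <- rss_fit(X, y)
    selected <- c(selected, v)
    remaining <- setdiff(remaining, v)
  }

  final_terms <- c(forced, selected)
  f <- if (length(final_terms)) stats::reformulate(final_terms, outcome)
       else stats::as.formula(paste(outcome, "~ 1"))
  model <- stats::lm(f, data = d)
  sm <- summary(model)$coefficients

  # per-candidate report; unselected: p-value when added to final model
  report <- do.call(rbind, lapply(candidates, function(v) {
    if (v %in% selected) {
      rn <- rownames(sm)[startsWith(rownames(sm), v)]
      data.frame(term = v, selected = TRUE,
                 step = match(v, selected),
                 beta = sm[rn[1L], 1L], se = sm[rn[1L], 2L],
                 p = sm[rn[1L], 4L])
    } else {
      Xc <- cbind(X, cols[[v]])
      q <- ncol(cols[[v]])
      df2 <- n - ncol(Xc)
      p_add <- if (df2 >= 1L) {
        rss1 <- rss_fit(Xc, y)
        Fs <- ((rss0 - rss1) / q) / (rss1 / df2)
        stats::pf(Fs, q, df2, lower.tail = FALSE)
      } else NA_real_
      data.frame(term = v, selected = FALSE, step = NA_integer_,
                 beta = NA_real_, se = NA_real_, p = p_add)
    }
  }))
  structure(list(model = model, selected = selected, report = report,
                 r2 = summary(model)$r.squared, n = n,
                 alpha_enter = alpha_enter, data = d, outcome = outcome,
                 forced = forced, cols = cols, X = X, y = y),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("forward-stepwise linear model:", x$outcome, "~",
      paste(c(x$forced, x$selected), collapse = " + "), "\n")
  cat(sprintf("  n = %d, R^2 = %.3f, alpha_enter = %g\n",
              x$n, x$r2, x$alpha_enter))
  print(x$report, row.names = FALSE, digits = 3)
  invisible(x)
}

# refit the final selected covariate set plus the exposure and return
# the exposure's coefficient, SE, p and 95% CI (defined whether or not
# the exposure was selected)
exposure_refit <- function(fit, exposure) {
  terms <- unique(c(fit$forced, fit$selected, exposure))
  f <- stats::reformulate(terms, fit$outcome)
  m <- stats::lm(f, data = fit$data)
  sm <- summary(m)$coefficients
  rn <- rownames(sm)[startsWith(rownames(sm), exposure)][1L]
  ci <- stats::confint(m, rn, level = 0.95)
  c(beta = sm[rn, 1L], se = sm[rn, 2L], p = sm[rn, 4L],
    ci_lo = ci[1L], ci_hi = ci[2L])
}

#' Stratified stepwise regression of adiponectin on ancestry
#'
#' Runs [stepwise_forward] for log-adiponectin with the ancestry
#' proportion as the main exposure within each stratum of the requested
#' classifications (obesity: non-obese/obese; insulin resistance:
#' non-IR/IR; `"no_diabetes"`: the diabetes-free sensitivity subset).
#' The exposure is selection-eligible like any candidate but is always
#' reported, with coefficient, SE, p-value and 95% CI from refitting
#' the selected covariate set plus the exposure.  The stratifying
#' variable itself (BMI for obesity strata, HOMA-IR for IR strata) is
#' removed from the candidate list.
#'
#' @param derived a [derive_cohort] table.
#' @param strata subset of `c("obesity", "ir", "no_diabetes")`.
#' @param candidates candidate covariate columns.
#' @param exposure exposure column, default `"pea"`.
#' @param alpha_enter stepwise entry threshold.
#' @param min_n minimum stratum size; smaller strata are skipped with a
#'   message.
#' @return data.frame, one row per stratum: `stratum`, `n`,
#'   `pea_selected`, `pea_beta`, `pea_se`, `pea_p`, `pea_ci_lo`,
#'   `pea_ci_hi`, `r2`, `selected`; the full `stepwise_fit` objects in
#'   the `"fits"` attribute.
#' @export
stratified_analysis <- function(derived,
                                strata = c("obesity", "ir"),
                                candidates = c("age", "sex", "waist",
                                               "bmi", "triglycerides",
                                               "hdl", "homa_ir", "sbp",
                                               "dbp", "activity",
                                               "alcohol", "crp",
                                               "education"),
                                exposure = "pea", alpha_enter = 0.05,
                                min_n = 50L) {
  stopifnot(all(strata %in% c("obesity", "ir", "no_diabetes")))
  subsets <- list()
  if ("obesity" %in% strata) {
    subsets[["non_obese"]] <- list(idx = !derived$obese,
                                   drop = "bmi")
    subsets[["obese"]] <- list(idx = derived$obese, drop = "bmi")
  }
  if ("ir" %in% strata) {
    subsets[["non_ir"]] <- list(idx = !derived$insulin_resistant,
                                drop = "homa_ir")
    subsets[["ir"]] <- list(idx = derived$insulin_resistant,
                            drop = "homa_ir")
  }
  if ("no_diabetes" %in% strata)
    subsets[["no_diabetes"]] <- list(idx = !derived$diabetic,
                                     drop = character())
  rows <- list(); fits <- list()
  for (nm in names(subsets)) {
    idx <- subsets[[nm]]$idx
    idx[is.na(idx)] <- FALSE
    d <- derived[idx, , drop = FALSE]
    if (nrow(d) < min_n) {
      message("stratum '", nm, "' skipped: n = ", nrow(d), " < ", min_n)
      next
    }
    cand <- setdiff(intersect(candidates, names(d)), subsets[[nm]]$drop)
    fit <- stepwise_forward(d, "log_adiponectin",
                            candidates = c(exposure, cand),
                            alpha_enter = alpha_enter)
    ex <- exposure_refit(fit, exposure)
    rows[[nm]] <- data.frame(
      stratum = nm, n = fit$n,
      pea_selected = exposure %in% fit$selected,
      pea_beta = ex[["beta"]], pea_se = ex[["se"]], pea_p = ex[["p"]],
      pea_ci_lo = ex[["ci_lo"]], pea_ci_hi = ex[["ci_hi"]],
      r2 = fit$r2,
      selected = paste(fit$selected, collapse = "+"))
    fits[[nm]] <- fit
  }
  if (!length(rows)) stop("all strata below the size floor")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
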