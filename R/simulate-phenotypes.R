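#' Simulation configuration for the synthetic cohort
#'
#' Bundles the generator's tunable parameters with defaults set to the
#' study conditions the package targets: 1439 individuals, up to 1447
#' AIMs with mean frequency differential 0.4, true European-ancestry
#' proportions Beta-distributed with median 0.158 / IQR 0.093, and a
#' log-adiponectin outcome whose association with ancestry is modified
#' by obesity (slope 0.62 among non-obese, 0 among obese) or by insulin
#' resistance (0.74 among insulin-sensitive, 0 among resistant),
#' depending on `pea_modifier`.
#'
#' The two modifier arms are alternatives, not a joint model: with
#' obesity and insulin-resistance prevalences near 53% and 25% the four
#' stratum slopes cannot all be marginal slopes of one outcome at once,
#' so the generator carries the effect through one classification at a
#' time (see the methods vignette).
#'
#' @param n_individuals cohort size.
#' @param n_markers AIM panel size.
#' @param delta_mean target mean allele-frequency differential.
#' @param pea_beta_a,pea_beta_b Beta shapes for true ancestry.
#' @param beta_pea_nonobese,beta_pea_obese log-adiponectin (natural log
#'   ug/mL) change per unit ancestry proportion in the obesity strata.
#' @param beta_pea_nonir,beta_pea_ir same for the insulin-resistance
#'   strata.
#' @param pea_modifier which classification modifies the ancestry
#'   effect: `"obesity"` or `"ir"`.
#' @param noise_sd residual SD of log-adiponectin.
#' @param missing_rate genotype missingness fraction.
#' @param insulin_missing_rate fraction with no fasting insulin (hence
#'   no HOMA-IR), default 249/1439.
#' @param seed integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 1439L, n_markers = 1447L,
                       delta_mean = 0.4,
                       pea_beta_a = pea_beta_shapes[["a"]],
                       pea_beta_b = pea_beta_shapes[["b"]],
                       beta_pea_nonobese = 0.62, beta_pea_obese = 0,
                       beta_pea_nonir = 0.74, beta_pea_ir = 0,
                       pea_modifier = c("obesity", "ir"),
                       noise_sd = 0.5, missing_rate = 0.02,
                       insulin_missing_rate = 249 / 1439, seed = 1L) {
  pea_modifier <- match.arg(pea_modifier)
  stopifnot(n_individuals >= 1, n_markers >= 1, noise_sd > 0,
            missing_rate >= 0, missing_rate <= 1,
            insulin_missing_rate >= 0, insulin_missing_rate <= 1,
            pea_beta_a > 0, pea_beta_b > 0)
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_markers = as.integer(n_markers), delta_mean = delta_mean,
    pea_beta_a = pea_beta_a, pea_beta_b = pea_beta_b,
    beta_pea_nonobese = beta_pea_nonobese,
    beta_pea_obese = beta_pea_obese,
    beta_pea_nonir = beta_pea_nonir, beta_pea_ir = beta_pea_ir,
    pea_modifier = pea_modifier, noise_sd = noise_sd,
    missing_rate = missing_rate,
    insulin_missing_rate = insulin_missing_rate,
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate a cardio-metabolic phenotype table
#'
#' Generates a cohort phenotype table with the marginal structure of an
#' African-American population sample (62% women, age 48 +/- 12 years
#' truncated at 21, sex-specific BMI giving roughly half the cohort
#' obese, log-normal fasting insulin and glucose, sex-specific HDL,
#' blood pressures rising with age, log-normal triglycerides and CRP)
#' and a log-adiponectin outcome built from a shared adiposity factor:
#'
#' `log(adiponectin) = b0 + slope_i * s_i - 0.28 male - 0.09 HOMA +
#'  0.012 (HDL - 50) - 0.006 (waist - 99) + 0.002 (age - 48) -
#'  0.012 (CRP - 5) + Normal(0, noise_sd)`
#'
#' where `slope_i` is the stratum-specific ancestry coefficient chosen
#' by `config$pea_modifier`.  The adiposity factor induces the expected
#' sign structure (adiponectin negatively related to HOMA-IR and
#' adiposity, positively to HDL).
#'
#' @param s_true vector of true ancestry proportions.
#' @param config a [sim_config].
#' @param seed integer seed (defaults to `config$seed + 2`).
#' @return A data.frame (cohort phenotype table) with attribute
#'   `"truth"` recording the generating parameters, per-individual
#'   slope, latent HOMA-IR and latent strata.
#' @export
simulate_phenotypes <- function(s_true, config = sim_config(),
                                seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"),
            all(s_true >= 0 & s_true <= 1))
  set.seed(seed)
  n <- length(s_true)
  female <- stats::runif(n) < 0.62
  age <- stats::rnorm(n, 48, 12)
  while (any(age < 21)) age[age < 21] <- stats::rnorm(sum(age < 21), 48, 12)

  adip <- stats::rnorm(n)                       # shared adiposity factor
  bmi <- ifelse(female, 33.0 + 7.4 * adip, 29.5 + 5.7 * adip)
  bmi <- pmax(bmi, 16)
  height <- ifelse(female, stats::rnorm(n, 1.62, 0.07),
                   stats::rnorm(n, 1.78, 0.08))
  weight <- bmi * height^2
  waist <- 42 + 1.8 * bmi + stats::rnorm(n, 0, 5)

  insulin <- exp(log(11) + 0.45 * adip + stats::rnorm(n, 0, 0.45))
  glucose <- exp(log(92) + 0.05 * adip + stats::rnorm(n, 0, 0.18)) # mg/dL
  homa_latent <- insulin * (glucose / 18.016) / 22.5
  diabetes_meds <- stats::runif(n) < 0.10

  hdl <- ifelse(female, 53.6, 45.5) - 3 * adip +
    stats::rnorm(n, 0, ifelse(female, 12, 10))
  hdl <- pmax(hdl, 20)
  triglycerides <- exp(log(90) + 0.10 * adip + stats::rnorm(n, 0, 0.5))
  sbp <- 105 + 0.35 * age + 2 * adip + stats::rnorm(n, 0, 13)
  dbp <- 72 + 0.15 * age + 1.5 * adip + stats::rnorm(n, 0, 9)
  activity <- pmin(pmax(stats::rnorm(n, 8.9, 2.4), 0), 24)
  alcohol <- stats::runif(n) < ifelse(female, 0.50, 0.66)
  crp <- exp(log(2.5) + 0.35 * adip + stats::rnorm(n, 0, 1))
  education <- stats::runif(n) < 0.37

  obese_latent <- bmi >= 30
  ir_latent <- rank(homa_latent, ties.method = "average") >
    0.75 * n                                    # latent upper quartile
  slope <- if (config$pea_modifier == "obesity") {
    ifelse(obese_latent, config$beta_pea_obese, config$beta_pea_nonobese)
  } else {
    ifelse(ir_latent, config$beta_pea_ir, config$beta_pea_nonir)
  }
  log_adipo <- 1.68 + slope * s_true - 0.28 * (!female) -
    0.09 * homa_latent + 0.012 * (hdl - 50) - 0.006 * (waist - 99) +
    0.002 * (age - 48) - 0.012 * (crp - 5) +
    stats::rnorm(n, 0, config$noise_sd)

  insulin[stats::runif(n) < config$insulin_missing_rate] <- NA

  out <- data.frame(
    individual_id = sprintf("ind_%05d", seq_len(n)),
    age = round(age, 1),
    sex = factor(ifelse(female, "F", "M"), levels = c("F", "M")),
    adiponectin = round(exp(log_adipo), 4),
    weight = round(weight, 1), height = round(height, 3),
    waist = round(waist, 1),
    triglycerides = round(triglycerides, 1), hdl = round(hdl, 1),
    glucose = round(glucose, 1), insulin = round(insulin, 2),
    sbp = round(sbp, 1), dbp = round(dbp, 1),
    activity = round(activity, 1),
    alcohol = factor(ifelse(alcohol, "yes", "no")),
    crp = round(crp, 2),
    education = factor(ifelse(education, ">HS", "<=HS")),
    diabetes_meds = factor(ifelse(diabetes_meds, "yes", "no")),
    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(
    s_true = s_true, slope = slope, obese_latent = obese_latent,
    ir_latent = ir_latent, homa_latent = homa_latent, config = config,
    seed = seed)
  out
}

#' Simulate a complete admixed cohort
#'
#' Drives the three generators with sub-seeds derived from
#' `config$seed`: AIM panel, true ancestry proportions, genotype
#' dosages and the phenotype table.
#'
#' @param config a [sim_config].
#' @return List with elements `panel`, `s_true`, `genotypes`,
#'   `phenotypes` and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  panel <- simulate_panel(config$n_markers, config$delta_mean,
                          seed = config$seed)
  s_true <- simulate_true_pea(config$n_individuals, config$pea_beta_a,
                              config$pea_beta_b, seed = config$seed + 1L)
  genotypes <- simulate_genotypes(panel, s_true, config$missing_rate,
                                  seed = config$seed + 3L)
  phenotypes <- simulate_phenotypes(s_true, config,
                                    seed = config$seed + 2L)
  list(panel = panel, s_true = s_true, genotypes = genotypes,
       phenotypes = phenotypes, config = config)
}

#' Write a simulated cohort to disk
#'
#' Writes `freqs.tsv`, `genotypes.tsv`, `phenotypes.csv` and
#' `truth.json` (generating parameters and the true ancestry vector)
#' into a directory.
#'
#' @param cohort list from [simulate_cohort].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_frequency_table(cohort$panel, file.path(dir, "freqs.tsv"))
  write_genotypes(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  utils::write.csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- attr(cohort$phenotypes, "truth")
  jsonlite::write_json(
    list(config = unclass(cohort$config), s_true = cohort$s_true,
         slope = truth$slope),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
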