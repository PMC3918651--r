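#' Body-mass index
#'
#' Weight in kilograms divided by height in meters squared.
#'
#' @param weight kg, > 0.
#' @param height m, > 0.
#' @return BMI in kg/m^2; vectorized, `NA` propagates.
#' @export
compute_bmi <- function(weight, height) {
  if (any(weight <= 0, na.rm = TRUE) || any(height <= 0, na.rm = TRUE))
    stop("weight and height must be positive")
  weight / height^2
}

#' Obesity classification
#'
#' Obese is BMI >= 30 kg/m^2 (inclusive boundary); `NA` stays `NA`.
#'
#' @param bmi kg/m^2.
#' @return Logical vector.
#' @export
classify_obesity <- function(bmi) bmi >= 30

#' Homeostasis-model assessment of insulin resistance (HOMA-IR)
#'
#' `fasting insulin (uU/mL) x fasting glucose (mmol/L) / 22.5`.
#' Glucose supplied in mg/dL is converted by dividing by 18.016.
#' Missing insulin gives missing HOMA-IR.
#'
#' @param glucose fasting glucose, > 0.
#' @param insulin fasting insulin in uU/mL, > 0 (may be `NA`).
#' @param glucose_unit `"mmol/L"` or `"mg/dL"`; no autodetection —
#'   silent unit inference is a correctness hazard, so the unit is
#'   always declared.
#' @return HOMA-IR, unitless.
#' @export
compute_homa_ir <- function(glucose, insulin,
                            glucose_unit = c("mmol/L", "mg/dL")) {
  glucose_unit <- match.arg(glucose_unit)
  if (any(glucose <= 0, na.rm = TRUE) || any(insulin <= 0, na.rm = TRUE))
    stop("glucose and insulin must be positive")
  if (glucose_unit == "mg/dL") glucose <- glucose / 18.016
  insulin * glucose / 22.5
}

#' Upper-quartile insulin-resistance classification
#'
#' Flags the top 25% of the non-missing HOMA-IR distribution by rank:
#' individuals whose average rank (largest last) exceeds `0.75 * n`
#' among the `n` non-missing values.  With average-rank tie handling
#' the rule is deterministic and a fully tied distribution flags
#' nobody (with a warning).  Missing HOMA-IR gives a missing flag.
#'
#' @param homa vector of HOMA-IR values (may contain `NA`).
#' @return Logical vector, `NA` where HOMA-IR is missing.
#' @export
classify_insulin_resistance <- function(homa) {
  obs <- !is.na(homa)
  n <- sum(obs)
  if (n < 4) stop("need at least 4 non-missing HOMA-IR values")
  r <- rank(homa[obs], ties.method = "average")
  flag <- r > 0.75 * n
  if (!any(flag))
    warning("degenerate HOMA-IR distribution: no upper quartile flagged")
  out <- rep(NA, length(homa))
  out[obs] <- flag
  out
}

#' Diabetes classification
#'
#' Fasting plasma glucose of at least 7.0 mmol/L (inclusive) or
#' treatment with insulin or a hypoglycemic agent.  Ordinary
#' three-valued logic: a missing component leaves the result missing
#' unless the other component already decides it.
#'
#' @param glucose_mmol fasting glucose in mmol/L.
#' @param med_flag logical, on insulin or a hypoglycemic agent.
#' @return Logical vector.
#' @export
classify_diabetes <- function(glucose_mmol, med_flag) {
  if (all(is.na(glucose_mmol)) && all(is.na(med_flag)))
    stop("glucose and medication flag are both entirely missing")
  (glucose_mmol >= 7.0) | med_flag
}

#' Derive the analysis cohort
#'
#' Inner-joins ancestry estimates onto the phenotype table and computes
#' every derived variable the analysis uses: natural-log adiponectin,
#' BMI, HOMA-IR, and obesity / insulin-resistance / diabetes flags.
#' Individuals present in only one table are dropped (recorded in the
#' `"dropped"` attribute); per-variable missingness is recorded in the
#' `"missingness"` attribute.
#'
#' @param cohort phenotype data.frame with columns `individual_id`,
#'   `age`, `sex`, `adiponectin`, `weight`, `height`, `waist`,
#'   `triglycerides`, `hdl`, `glucose`, `insulin`, `sbp`, `dbp`,
#'   `activity`, `alcohol`, `crp`, `education`, `diabetes_meds`.
#' @param ancestry data.frame with `individual_id` and `s_hat` (as from
#'   [estimate_cohort]), or a column named `pea`.
#' @param glucose_unit declared unit of the `glucose` column.
#' @return A `derived_cohort` data.frame: the joined table plus
#'   `pea`, `log_adiponectin`, `bmi`, `homa_ir`, `obese`,
#'   `insulin_resistant`, `diabetic`.
#' @export
derive_cohort <- function(cohort, ancestry,
                          glucose_unit = c("mg/dL", "mmol/L")) {
  glucose_unit <- match.arg(glucose_unit)
  stopifnot(is.data.frame(cohort), is.data.frame(ancestry),
            "individual_id" %in% names(cohort),
            "individual_id" %in% names(ancestry))
  if (anyDuplicated(cohort$individual_id))
    stop("duplicate individual ids in phenotype table")
  pea_col <- if ("pea" %in% names(ancestry)) "pea" else "s_hat"
  if (!pea_col %in% names(ancestry))
    stop("ancestry table needs an 's_hat' or 'pea' column")
  ids <- intersect(cohort$individual_id, ancestry$individual_id)
  if (length(ids) == 0L) stop("no overlapping individual ids")
  orphans <- c(setdiff(cohort$individual_id, ids),
               setdiff(ancestry$individual_id, ids))
  dropped <- data.frame(individual_id = orphans,
                        reason = rep("no match in the other table",
                                     length(orphans)))
  if (nrow(dropped))
    message("dropping ", nrow(dropped),
            " individual(s) without a join partner")
  d <- cohort[match(ids, cohort$individual_id), , drop = FALSE]
  d$pea <- ancestry[[pea_col]][match(ids, ancestry$individual_id)]

  if (any(d$adiponectin <= 0, na.rm = TRUE))
    stop("adiponectin must be positive")
  d$log_adiponectin <- log(d$adiponectin)
  d$bmi <- compute_bmi(d$weight, d$height)
  glucose_mmol <- if (glucose_unit == "mg/dL") d$glucose / 18.016
                  else d$glucose
  d$homa_ir <- compute_homa_ir(d$glucose, d$insulin, glucose_unit)
  d$obese <- classify_obesity(d$bmi)
  d$insulin_resistant <- classify_insulin_resistance(d$homa_ir)
  d$diabetic <- classify_diabetes(glucose_mmol, d$diabetes_meds == "yes")
  rownames(d) <- NULL

  attr(d, "dropped") <- dropped
  attr(d, "missingness") <- vapply(d, function(x) sum(is.na(x)),
                                   integer(1))
  attr(d, "glucose_unit") <- glucose_unit
  class(d) <- c("derived_cohort", "data.frame")
  d
}
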