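# NfL post-processing: detection-limit capping with sensitivity analysis,
# tissue NfL as percent of total protein, the serum/CSF ratio that
# discounts central nervous system NfL release, and age-specific Z-scores
# on the natural-log scale.

#' Maximum validated detection limits per compartment
#'
#' @return Named numeric vector, pg/mL: `csf` 25000, `tissue` 7800.
#' @export
detectionLimits <- function() c(csf = 25000, tissue = 7800)

#' Cap a concentration at the compartment's detection limit
#'
#' Fluorescence values beyond the assay's validated range are replaced by
#' the respective maximum validated detection limit and flagged.
#'
#' @param value concentration(s) in pg/mL (> 0; `NA` passes through).
#' @param compartment `"csf"` or `"tissue"`.
#' @return data.frame with columns `value` (capped) and `capped` (logical).
#' @examples
#' capAtDetectionLimit(c(9000, 1200), "tissue")
#' @export
capAtDetectionLimit <- function(value, compartment) {
  limits <- detectionLimits()
  if (!compartment %in% names(limits))
    stop("unknown compartment '", compartment,
         "' (expected csf or tissue)", call. = FALSE)
  if (any(value <= 0, na.rm = TRUE))
    stop("concentrations must be positive", call. = FALSE)
  lim <- limits[[compartment]]
  capped <- !is.na(value) & value > lim
  data.frame(value = ifelse(capped, lim, value), capped = capped)
}

#' Tissue NfL as percent of total protein
#'
#' Converts a tissue-homogenate NfL concentration (pg/mL) and its
#' total-protein concentration (mg/mL) into NfL as a percentage of the
#' total protein fraction: `nfl / (protein * 1e9) * 100`.
#'
#' @param nflPgMl NfL in pg/mL (>= 0).
#' @param totalProteinMgMl total protein in mg/mL (> 0).
#' @return Percent of total protein.
#' @examples
#' tissuePctProtein(500, 0.5)  # 1e-4 %
#' @export
tissuePctProtein <- function(nflPgMl, totalProteinMgMl) {
  if (any(totalProteinMgMl <= 0, na.rm = TRUE))
    stop("total protein must be positive", call. = FALSE)
  if (any(nflPgMl < 0, na.rm = TRUE))
    stop("NfL must be non-negative", call. = FALSE)
  nflPgMl / (totalProteinMgMl * 1e9) * 100
}

#' Serum to CSF NfL ratio
#'
#' Discounts NfL released from central nervous system tissue. When the CSF
#' value was capped at its detection limit the true ratio can only be
#' smaller, so the result carries a lower-bound-uncertain flag.
#'
#' @param serum,csf concentrations in pg/mL (`NA` gives `NA`).
#' @param csfCapped logical flag(s) from [capAtDetectionLimit()].
#' @return data.frame with `ratio` and `lower_bound_uncertain`.
#' @examples
#' serumCsfRatio(50, 1000)
#' @export
serumCsfRatio <- function(serum, csf, csfCapped = FALSE) {
  if (any(c(serum, csf) <= 0, na.rm = TRUE))
    stop("concentrations must be positive", call. = FALSE)
  data.frame(ratio = serum / csf,
             lower_bound_uncertain = rep(csfCapped,
                                         length.out = length(serum)) &
               !is.na(serum) & !is.na(csf))
}

#' Parametric age reference model for serum NfL
#'
#' A pluggable stand-in for a published age-reference database: log-linear
#' mean in age with constant log-scale SD. The packaged defaults are
#' synthetic documentation constants (mu = ln 8 + 0.025 (age - 20),
#' sigma = 0.5) -- supply parameters from a validated reference for
#' clinical use.
#'
#' @param logBaseline natural-log serum NfL (pg/mL) at the centring age.
#' @param ageSlope per-year slope of the log-mean.
#' @param ageCenter centring age in years.
#' @param logSd constant log-scale SD (> 0).
#' @param ageSupport supported age range in years.
#' @return A list of class `"referenceModel"` with functions `mu(age)` and
#'   `sigma(age)` plus the parameters.
#' @export
referenceModel <- function(logBaseline = log(8), ageSlope = 0.025,
                           ageCenter = 20, logSd = 0.5,
                           ageSupport = c(18, 100)) {
  stopifnot(logSd > 0, ageSupport[1] < ageSupport[2])
  structure(list(
    mu = function(age) logBaseline + ageSlope * (age - ageCenter),
    sigma = function(age) rep(logSd, length(age)),
    parameters = list(logBaseline = logBaseline, ageSlope = ageSlope,
                      ageCenter = ageCenter, logSd = logSd,
                      ageSupport = ageSupport)
  ), class = "referenceModel")
}

#' Age-specific Z-score of a serum NfL value
#'
#' `Z = (ln(serum) - mu(age)) / sigma(age)` on the natural-log scale
#' (serum NfL is right-skewed).
#'
#' @param serum serum NfL in pg/mL (> 0).
#' @param age age in years, within the reference support.
#' @param ref a [referenceModel()].
#' @return Z-score(s).
#' @examples
#' ref <- referenceModel()
#' ageZScore(exp(ref$mu(60)), 60)  # 0
#' @export
ageZScore <- function(serum, age, ref = referenceModel()) {
  stopifnot(inherits(ref, "referenceModel"))
  sup <- ref$parameters$ageSupport
  if (any(age < sup[1] | age > sup[2], na.rm = TRUE))
    stop(sprintf("age outside the reference support [%g, %g] years",
                 sup[1], sup[2]), call. = FALSE)
  if (any(serum <= 0, na.rm = TRUE))
    stop("serum NfL must be positive", call. = FALSE)
  (log(serum) - ref$mu(age)) / ref$sigma(age)
}

#' Derive the full NfL panel from raw measurements
#'
#' Applies detection-limit capping (CSF, tissue), computes tissue NfL as
#' percent of total protein, the serum/CSF ratio with capping propagation,
#' and (when ages are supplied) age-specific serum Z-scores.
#'
#' @param measurements data.frame with `study_id`, `serum_nfl_pg_ml`,
#'   `csf_nfl_pg_ml`, `tissue_nfl_pg_ml`, `total_protein_mg_ml`.
#' @param cohort optional cohort data.frame supplying `age` per `study_id`.
#' @param ref a [referenceModel()] for the Z-scores.
#' @return data.frame with capped values, capping flags and derived
#'   quantities (`tissue_pct_protein`, `serum_csf_ratio`,
#'   `ratio_lower_bound_uncertain`, `serum_z` when ages are available).
#' @export
deriveNfl <- function(measurements, cohort = NULL, ref = referenceModel()) {
  need <- c("study_id", "serum_nfl_pg_ml", "csf_nfl_pg_ml",
            "tissue_nfl_pg_ml", "total_protein_mg_ml")
  stopifnot(all(need %in% names(measurements)))
  csf <- capAtDetectionLimit(measurements$csf_nfl_pg_ml, "csf")
  tis <- capAtDetectionLimit(measurements$tissue_nfl_pg_ml, "tissue")
  ratio <- serumCsfRatio(measurements$serum_nfl_pg_ml, csf$value,
                         csf$capped)
  out <- data.frame(
    study_id = measurements$study_id,
    serum_nfl_pg_ml = measurements$serum_nfl_pg_ml,
    csf_nfl_pg_ml = csf$value, csf_capped = csf$capped,
    tissue_nfl_pg_ml = tis$value, tissue_capped = tis$capped,
    total_protein_mg_ml = measurements$total_protein_mg_ml,
    tissue_pct_protein = tissuePctProtein(tis$value,
                                          measurements$total_protein_mg_ml),
    serum_csf_ratio = ratio$ratio,
    ratio_lower_bound_uncertain = ratio$lower_bound_uncertain,
    stringsAsFactors = FALSE
  )
  if (!is.null(cohort)) {
    age <- cohort$age[match(out$study_id, cohort$study_id)]
    out$serum_z <- ageZScore(out$serum_nfl_pg_ml, age, ref)
  }
  out
}

#' Sensitivity analysis of the detection-limit capping
#'
#' Replaces each capped CSF/tissue value by `limit * multiplier`,
#' recomputes the derived panel and re-runs a downstream analysis per
#' multiplier. Multiplier 1 reproduces the primary analysis exactly.
#'
#' @param measurements raw measurements (see [deriveNfl()]).
#' @param multipliers numeric vector of cap multipliers, all >= 1.
#' @param analysisFn callback `function(derived)` returning a
#'   [CorrelationResult-class] (or a one-row data.frame of numbers).
#' @param cohort,ref passed to [deriveNfl()].
#' @return data.frame with one row per multiplier: `multiplier`, `r`,
#'   `ci_low`, `ci_high`, `p`, `n` (or the callback's columns).
#' @export
cappingSensitivity <- function(measurements, multipliers = c(1, 1.5, 2, 5),
                               analysisFn, cohort = NULL,
                               ref = referenceModel()) {
  if (!length(multipliers)) stop("empty multiplier list", call. = FALSE)
  if (any(multipliers < 1)) stop("multipliers must be >= 1", call. = FALSE)
  lim <- detectionLimits()
  base <- deriveNfl(measurements, cohort, ref)
  do.call(rbind, lapply(multipliers, function(m) {
    d <- base
    d$csf_nfl_pg_ml[d$csf_capped] <- lim[["csf"]] * m
    d$tissue_nfl_pg_ml[d$tissue_capped] <- lim[["tissue"]] * m
    d$tissue_pct_protein <- tissuePctProtein(d$tissue_nfl_pg_ml,
                                             d$total_protein_mg_ml)
    d$serum_csf_ratio <- d$serum_nfl_pg_ml / d$csf_nfl_pg_ml
    res <- analysisFn(d)
    row <- if (is(res, "CorrelationResult"))
      data.frame(r = corEstimate(res), ci_low = corCI(res)[1],
                 ci_high = corCI(res)[2], p = corPValue(res),
                 n = corN(res)) else as.data.frame(res)
    cbind(data.frame(multiplier = m), row)
  }))
}
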