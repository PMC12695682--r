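# Synthetic cohort generator. Patients carry two latent damage levels --
# acute axonal degeneration and chronic axonal loss, both in [0, 1] -- plus
# a CNS-disease flag. NfL concentrations are log-normal with an age trend;
# the acute level raises serum (and tissue) NfL, CNS disease raises CSF NfL.
# The latents also drive the expected histological read-outs via
# groundTruthHistologyTargets(), so the full analysis chain can be tested
# for parameter recovery on data with known truth.

#' Simulation configuration for the synthetic cohort
#'
#' Defaults mirror the study conditions of the source cohort: 35 biopsied
#' patients aged 26--82, roughly a quarter with relevant CNS disease, a
#' strong log-scale acute-degeneration effect on serum NfL and moderate
#' log-normal noise.
#'
#' @param nPatients number of patients (>= 2).
#' @param ageRange min/max patient age in years.
#' @param betaAge per-year log-scale age slope of NfL.
#' @param betaAcute log-scale effect of the acute damage level (0--1) on
#'   serum, tissue and CSF NfL.
#' @param betaCns log-scale effect of CNS disease on CSF NfL.
#' @param csfAcuteShare fraction of the acute effect that also reaches CSF
#'   NfL (peripheral axonal breakdown raises serum far more than CSF, so
#'   the serum/CSF ratio retains most of the peripheral signal).
#' @param sigmaNoise log-scale residual SD.
#' @param pCns probability of relevant CNS disease.
#' @param baselineSerum,baselineCsf,baselineTissue NfL baselines in pg/mL at
#'   age 50 with no damage.
#' @param baselineProtein mean total-protein concentration of tissue
#'   homogenate aliquots in mg/mL.
#' @param acuteChronicRho Gaussian-copula correlation between the acute and
#'   chronic latent levels (real cohorts confound them; default uncoupled).
#' @return A validated list of class `"simulationConfig"`.
#' @examples
#' simulationConfig(nPatients = 10)
#' @export
simulationConfig <- function(nPatients = 35L, ageRange = c(26, 82),
                             betaAge = 0.02, betaAcute = 1.5, betaCns = 1.0,
                             csfAcuteShare = 0.3,
                             sigmaNoise = 0.4, pCns = 9 / 35,
                             baselineSerum = 10, baselineCsf = 600,
                             baselineTissue = 500, baselineProtein = 1.0,
                             acuteChronicRho = 0) {
  cfg <- list(nPatients = as.integer(nPatients), ageRange = ageRange,
              betaAge = betaAge, betaAcute = betaAcute, betaCns = betaCns,
              csfAcuteShare = csfAcuteShare,
              sigmaNoise = sigmaNoise, pCns = pCns,
              baselineSerum = baselineSerum, baselineCsf = baselineCsf,
              baselineTissue = baselineTissue,
              baselineProtein = baselineProtein,
              acuteChronicRho = acuteChronicRho)
  if (cfg$nPatients < 2L) stop("nPatients must be >= 2", call. = FALSE)
  if (cfg$sigmaNoise < 0) stop("sigmaNoise must be >= 0", call. = FALSE)
  if (cfg$pCns < 0 || cfg$pCns > 1) stop("pCns must lie in [0, 1]", call. = FALSE)
  if (any(c(cfg$baselineSerum, cfg$baselineCsf, cfg$baselineTissue,
            cfg$baselineProtein) <= 0))
    stop("baselines must be positive", call. = FALSE)
  if (abs(cfg$acuteChronicRho) > 1)
    stop("acuteChronicRho must lie in [-1, 1]", call. = FALSE)
  class(cfg) <- "simulationConfig"
  cfg
}

#' Simulate a synthetic biopsy cohort with NfL panels
#'
#' Draws latent acute/chronic damage levels (uniform marginals, optionally
#' correlated through a Gaussian copula), ages, sexes and CNS-disease flags,
#' then generates log-normal NfL concentrations:
#' `serum = exp(log(baselineSerum) + betaAge * (age - 50) +
#' betaAcute * acute + eps)`, CSF analogously with `betaCns * cns` added,
#' and tissue NfL increasing in the acute level. Identical seeds give
#' identical output.
#'
#' @param config a [simulationConfig()].
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return A list with components `cohort` (cohort-schema data.frame),
#'   `truth` (study_id, acute_level, chronic_level, cns_disease) and
#'   `measurements` (study_id, serum/csf/tissue NfL in pg/mL,
#'   total_protein_mg_ml).
#' @examples
#' sim <- simulateCohort(simulationConfig(nPatients = 5), seed = 1)
#' sim$measurements
#' @export
simulateCohort <- function(config = simulationConfig(), seed = NULL) {
  stopifnot(inherits(config, "simulationConfig"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$nPatients
  id <- sprintf("S%02d", seq_len(n))

  z1 <- rnorm(n)
  z2 <- config$acuteChronicRho * z1 +
    sqrt(1 - config$acuteChronicRho^2) * rnorm(n)
  acute <- pnorm(z1)
  chronic <- pnorm(z2)
  cns <- runif(n) < config$pCns

  age <- round(runif(n, config$ageRange[1], config$ageRange[2]))
  sex <- sample(SEX_LEVELS, n, replace = TRUE, prob = c(23, 12) / 35)
  onset <- round(exp(runif(n, log(2), log(180))))
  linpred <- config$betaAge * (age - 50)
  serum <- exp(log(config$baselineSerum) + linpred +
                 config$betaAcute * acute + rnorm(n, 0, config$sigmaNoise))
  csf <- exp(log(config$baselineCsf) + linpred +
               config$csfAcuteShare * config$betaAcute * acute +
               config$betaCns * cns +
               rnorm(n, 0, config$sigmaNoise))
  tissue <- exp(log(config$baselineTissue) +
                  config$betaAcute * acute +
                  rnorm(n, 0, config$sigmaNoise))
  protein <- config$baselineProtein * exp(rnorm(n, 0, 0.2))

  cohort <- data.frame(
    study_id = id, age = as.integer(age), sex = sex,
    clinical_dx = ifelse(acute > 0.6, "Vasculitic neuropathy (synthetic)",
                         "Axonal neuropathy (synthetic)"),
    path_dx = ifelse(chronic > 0.5, "Axonal neuropathy", "Mild changes"),
    timecourse = classifyTimecourse(onset),
    delta_days_to_biopsy = as.integer(round(rnorm(n, 0, 5))),
    cns_disease = ifelse(cns, "yes", "no"),
    vasculitis = ifelse(acute > 0.6, "definite_or_probable", "other"),
    stringsAsFactors = FALSE
  )
  cohort$delta_days_to_biopsy <-
    as.integer(clamp(cohort$delta_days_to_biopsy, -MAX_DELTA_DAYS, MAX_DELTA_DAYS))
  cohort <- validateCohort(cohort)

  list(
    cohort = cohort,
    truth = data.frame(study_id = id, acute_level = acute,
                       chronic_level = chronic, cns_disease = cns,
                       stringsAsFactors = FALSE),
    measurements = data.frame(study_id = id,
                              serum_nfl_pg_ml = serum,
                              csf_nfl_pg_ml = csf,
                              tissue_nfl_pg_ml = tissue,
                              total_protein_mg_ml = protein,
                              stringsAsFactors = FALSE)
  )
}

#' Histology model linking latent damage levels to expected read-outs
#'
#' Fixes the mapping from the latent acute/chronic levels to the five
#' observable histological parameters. Healthy myelinated-fiber density and
#' the neurofilament-positive area fraction fall linearly with chronic loss;
#' degenerating-fiber density, macrophage (CD68) area and the teased-fiber
#' ovoid fraction rise linearly with acute degeneration.
#'
#' @param healthyFiberDensity myelinated fibers/mm^2 of an intact sural
#'   nerve.
#' @param chronicLossMax maximal fraction of fibers/NF70 area lost at
#'   chronic level 1.
#' @param nf70HealthyPct NF70-positive percent of fascicular area of an
#'   intact nerve.
#' @param degenDensityMax degenerating fibers/mm^2 at acute level 1.
#' @param cd68PctMax CD68-positive percent of fascicular area at acute
#'   level 1.
#' @param ovoidFractionMax teased-fiber ovoid fraction at acute level 1.
#' @return A list of class `"histologyModel"`.
#' @export
histologyModel <- function(healthyFiberDensity = 5000, chronicLossMax = 0.8,
                           nf70HealthyPct = 25, degenDensityMax = 800,
                           cd68PctMax = 8, ovoidFractionMax = 0.9) {
  stopifnot(healthyFiberDensity > 0, chronicLossMax > 0, chronicLossMax <= 1,
            nf70HealthyPct > 0, nf70HealthyPct <= 80, degenDensityMax > 0,
            cd68PctMax > 0, cd68PctMax <= 80,
            ovoidFractionMax > 0, ovoidFractionMax <= 1)
  structure(list(healthyFiberDensity = healthyFiberDensity,
                 chronicLossMax = chronicLossMax,
                 nf70HealthyPct = nf70HealthyPct,
                 degenDensityMax = degenDensityMax,
                 cd68PctMax = cd68PctMax,
                 ovoidFractionMax = ovoidFractionMax),
            class = "histologyModel")
}

#' Expected histological parameters for given latent damage levels
#'
#' Deterministic targets: expected degenerating-fiber density, CD68 percent
#' area and ovoid fraction are strictly increasing in the acute level;
#' expected fiber density and NF70 percent area strictly decreasing in the
#' chronic level.
#'
#' @param acuteLevel,chronicLevel latent levels in \[0, 1\] (vectorised).
#' @param model a [histologyModel()].
#' @return data.frame with columns `fiber_density`, `nf70_pct_area`,
#'   `degen_density`, `cd68_pct_area`, `ovoid_fraction`.
#' @examples
#' groundTruthHistologyTargets(c(0, 0.5, 1), 0)
#' @export
groundTruthHistologyTargets <- function(acuteLevel, chronicLevel,
                                        model = histologyModel()) {
  stopifnot(inherits(model, "histologyModel"))
  if (any(acuteLevel < 0 | acuteLevel > 1) ||
      any(chronicLevel < 0 | chronicLevel > 1))
    stop("latent levels must lie in [0, 1]", call. = FALSE)
  data.frame(
    fiber_density = model$healthyFiberDensity *
      (1 - model$chronicLossMax * chronicLevel),
    nf70_pct_area = model$nf70HealthyPct *
      (1 - model$chronicLossMax * chronicLevel),
    degen_density = model$degenDensityMax * acuteLevel,
    cd68_pct_area = model$cd68PctMax * acuteLevel,
    ovoid_fraction = model$ovoidFractionMax * acuteLevel
  )
}

#' Write simulation outputs to CSV files
#'
#' Writes the cohort (cohort schema), measurements and ground-truth tables.
#'
#' @param sim result of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
writeSimulatedCohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cohort = file.path(dir, "cohort.csv"),
             measurements = file.path(dir, "measurements.csv"),
             truth = file.path(dir, "ground_truth.csv"))
  writeCohortTable(sim$cohort, paths["cohort"])
  write.csv(sim$measurements, paths["measurements"], row.names = FALSE)
  write.csv(sim$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}
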