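# End-to-end orchestration: simulate a cohort -> render per-patient slides
# -> segment and measure -> composite scores -> NfL derivation -> Spearman
# panel -> report and CSV outputs. Fully deterministic for a given seed;
# every output table carries a header with package version, seed and a
# configuration hash.

#' Pipeline configuration
#'
#' Bundles all stage parameters. The simulation block carries the
#' cohort-level study conditions; the render block fixes the synthetic
#' imaging scale (a package choice balancing realism against runtime, see
#' the vignette) and which modalities are produced.
#'
#' @param seed integer seed governing every random choice of the run.
#' @param sim a [simulationConfig()].
#' @param histology a [histologyModel()].
#' @param imageSizePx side length of the square rendered slides (pixels).
#' @param micronsPerPixel calibration of the rendered slides.
#' @param noiseSd,illumGradient sensor-noise SD and illumination-gradient
#'   amplitude passed to the renderers.
#' @param teasedFraction fraction of patients with a teased-fiber
#'   preparation (the subset with ovoid data); 0 disables the modality.
#' @param sectionCv log-scale coefficient of variation between a patient's
#'   expected parameter and the rendered section (section-to-section
#'   biological variability).
#' @param semithinDiameterUmRange rendered outer fiber-diameter range (um).
#' @param cd68RollingBallRadius rolling-ball radius (px) used at this image
#'   scale.
#' @param cnsRule subgroup rule for [runPanel()].
#' @param outputDir optional directory for CSV/report/log output.
#' @return A list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(seed = 1L, sim = simulationConfig(),
                           histology = histologyModel(),
                           imageSizePx = 96L, micronsPerPixel = 1.0,
                           noiseSd = 3, illumGradient = 0.04,
                           teasedFraction = 14 / 35, sectionCv = 0.12,
                           semithinDiameterUmRange = c(4, 8),
                           cd68RollingBallRadius = 24,
                           cnsRule = "exclude_yes_only",
                           outputDir = NULL) {
  stopifnot(inherits(sim, "simulationConfig"),
            inherits(histology, "histologyModel"),
            teasedFraction >= 0, teasedFraction <= 1)
  structure(list(seed = as.integer(seed), sim = sim, histology = histology,
                 imageSizePx = as.integer(imageSizePx),
                 micronsPerPixel = micronsPerPixel, noiseSd = noiseSd,
                 illumGradient = illumGradient,
                 teasedFraction = teasedFraction, sectionCv = sectionCv,
                 semithinDiameterUmRange = semithinDiameterUmRange,
                 cd68RollingBallRadius = cd68RollingBallRadius,
                 cnsRule = cnsRule, outputDir = outputDir),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys match the [pipelineConfig()] arguments; `sim` and
#' `histology` are nested maps passed to [simulationConfig()] and
#' [histologyModel()].
#'
#' @param path YAML file path.
#' @return A `"pipelineConfig"` list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(simulationConfig, y$sim)
  if (!is.null(y$histology)) y$histology <- do.call(histologyModel, y$histology)
  do.call(pipelineConfig, y)
}

# render + measure all modalities for one patient; returns a one-row
# data.frame of histological read-outs
measurePatientHistology <- function(target, config, teased) {
  sz <- c(config$imageSizePx, config$imageSizePx)
  mpp <- config$micronsPerPixel
  secFac <- function() exp(rnorm(1, 0, config$sectionCv))

  # semithin morphometry; the feasibility cap uses the effective packed
  # area per fiber (rendered radius plus separation) at this pixel scale
  areaMm2 <- fascicleLayoutAreaMm2(sz, mpp, 1L)
  areaPx <- areaMm2 * 1e6 / mpp^2
  roMeanPx <- max(3, mean(config$semithinDiameterUmRange) / 2 / mpp)
  maxFibers <- floor(0.32 * areaPx / (pi * (roMeanPx + 1.1)^2))
  nFib <- min(rpois(1, target$fiber_density * areaMm2), maxFibers)
  nDeg <- min(rpois(1, target$degen_density * areaMm2),
              max(0L, maxFibers - nFib))
  semi <- NULL
  for (attempt in 1:4) {
    semi <- tryCatch(
      renderSemithin(nFib, nDeg, imageSize = sz, micronsPerPixel = mpp,
                     outerDiameterUmRange = config$semithinDiameterUmRange,
                     noiseSd = config$noiseSd),
      error = function(e) NULL)
    if (!is.null(semi)) break
    nFib <- floor(nFib * 0.85)  # thin the section and retry packing
    nDeg <- floor(nDeg * 0.85)
  }
  if (is.null(semi))
    stop("semithin packing failed after retries", call. = FALSE)
  det <- detectFibers(semi$image, semi$rois)
  morph <- fiberDensity(det, semi$rois, mpp)

  # NF70 chronic-loss area fraction
  nf70Target <- clamp(target$nf70_pct_area * secFac(), 0, 60)
  nf70 <- renderIhcSlide(nf70Target, "nf70_dab", imageSize = sz,
                         micronsPerPixel = mpp, nFascicles = 1L,
                         noiseSd = config$noiseSd,
                         illumGradient = config$illumGradient)
  nf70Res <- nf70AreaFraction(nf70$image, nf70$rois)

  # CD68 in both orientations
  cd68Pct <- vapply(c("transverse", "longitudinal"), function(ornt) {
    tgt <- clamp(target$cd68_pct_area * secFac(), 0, 60)
    sl <- renderIhcSlide(tgt, "cd68_dab", imageSize = sz,
                         micronsPerPixel = mpp, nFascicles = 1L,
                         orientation = ornt, noiseSd = config$noiseSd,
                         illumGradient = config$illumGradient)
    pooledPctArea(suppressWarnings(
      cd68AreaFraction(sl$image, sl$rois,
                       cd68Params(config$cd68RollingBallRadius))))
  }, numeric(1))

  # teased fibers (subset only)
  ovoid <- NA_real_
  if (teased) {
    total <- sample(20:53, 1L)
    nOv <- rbinom(1L, total, target$ovoid_fraction)
    strip <- renderTeasedFibers(total, nOv, widthPx = 320L,
                                laneHeightPx = 8L, fiberThicknessPx = 3L,
                                noiseSd = config$noiseSd)
    ovoid <- suppressWarnings(ovoidFraction(strip$image))$ovoid_fraction
  }

  data.frame(
    nf70_pct_area = pooledPctArea(nf70Res),
    fiber_density = morph@fiberDensity,
    degen_density = morph@degenDensity,
    cd68_t_pct = cd68Pct[["transverse"]],
    cd68_l_pct = cd68Pct[["longitudinal"]],
    ovoid_fraction = ovoid
  )
}

#' Merge per-patient tables on study_id
#'
#' Left-joins onto the first table; any study_id in a later table that is
#' unknown to the first raises an error listing the offenders.
#'
#' @param ... data.frames, each with a `study_id` column.
#' @return The merged data.frame.
#' @export
mergePatientTables <- function(...) {
  tabs <- list(...)
  base <- tabs[[1]]
  for (t in tabs[-1]) {
    unknown <- setdiff(t$study_id, base$study_id)
    if (length(unknown))
      stop("unknown study_id in merged table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    base <- merge(base, t, by = "study_id", all.x = TRUE, sort = TRUE)
  }
  base
}

writeCsvWithHeader <- function(df, path, headerLines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(headerLines, con)
  write.csv(df, con, row.names = FALSE)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates a cohort with latent acute/chronic damage levels, renders and
#' measures the four slide modalities per patient, builds the acute
#' composite score and the chronic parameters, derives the NfL panel
#' (capping, serum/CSF ratio, age Z-scores) and runs the Spearman analysis
#' panel. Deterministic given `config$seed`; when `config$outputDir` is set
#' all tables, the text report, a log and a machine-readable manifest are
#' written there, each CSV headed by version, seed and configuration hash.
#'
#' @param config a [pipelineConfig()].
#' @return List with `cohort`, `truth`, `measurements`, `histology`,
#'   `scores`, `chronic`, `derived`, `merged`, `panel`, `summary`,
#'   `report`, `config`.
#' @examples
#' \donttest{
#' res <- runPipeline(pipelineConfig(seed = 7,
#'   sim = simulationConfig(nPatients = 8)))
#' head(res$panel)
#' }
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "pipelineConfig"))
  set.seed(config$seed)
  log <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(fmt, ...))
    log <<- c(log, line)
    invisible(line)
  }

  note("simulate: n = %d patients, seed = %d", config$sim$nPatients,
       config$seed)
  sim <- simulateCohort(config$sim)
  targets <- groundTruthHistologyTargets(sim$truth$acute_level,
                                         sim$truth$chronic_level,
                                         config$histology)
  n <- nrow(sim$cohort)
  nTeased <- round(config$teasedFraction * n)
  teasedIdx <- if (nTeased > 0) sort(sample.int(n, nTeased)) else integer(0)
  note("histology: %d px at %.2g um/px; teased subset n = %d",
       config$imageSizePx, config$micronsPerPixel, length(teasedIdx))

  histo <- do.call(rbind, lapply(seq_len(n), function(i) {
    row <- tryCatch(
      measurePatientHistology(targets[i, ], config, i %in% teasedIdx),
      error = function(e)
        stop(sprintf("histology stage failed for %s: %s",
                     sim$cohort$study_id[i], conditionMessage(e)),
             call. = FALSE))
    cbind(data.frame(study_id = sim$cohort$study_id[i]), row)
  }))

  note("scores: composing acute composite and chronic parameters")
  cd68T <- suppressWarnings(normalizeToDatasetMax(histo$cd68_t_pct))
  cd68L <- suppressWarnings(normalizeToDatasetMax(histo$cd68_l_pct))
  components <- data.frame(
    study_id = histo$study_id,
    degen_density = histo$degen_density,
    ovoid_fraction = histo$ovoid_fraction,
    cd68_total_pctmax = combineOrientations(cd68T, cd68L)
  )
  scores <- suppressWarnings(acuteComposite(components))
  chronic <- chronicParameters(histo$study_id, histo$nf70_pct_area,
                               histo$fiber_density)

  note("derive: NfL capping, ratio and age Z-scores")
  derived <- deriveNfl(sim$measurements, sim$cohort)

  merged <- mergePatientTables(
    sim$cohort[, c("study_id", "cns_disease")],
    scores[, c("study_id", "acute_composite", "n_components")],
    histo[, c("study_id", "nf70_pct_area", "fiber_density")],
    derived)

  note("correlate: Spearman panel (%s)", config$cnsRule)
  panel <- runPanel(merged, config$cnsRule)
  summary <- summarizeCohort(sim$cohort)
  report <- renderReport(panel, summary)

  out <- list(cohort = sim$cohort, truth = sim$truth,
              measurements = sim$measurements, histology = histo,
              scores = scores, chronic = chronic, derived = derived,
              merged = merged, panel = panel, summary = summary,
              report = report, config = config, log = log)

  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    cfgHash <- rlang::hash(config[setdiff(names(config), "outputDir")])
    hdr <- sprintf("# nflaxon %s; seed = %d; config_hash = %s",
                   as.character(utils::packageVersion("nflaxon")),
                   config$seed, cfgHash)
    tabs <- list(cohort = sim$cohort, measurements = sim$measurements,
                 ground_truth = sim$truth, histology = histo,
                 scores = scores, chronic_parameters = chronic,
                 nfl_derived = derived, merged = merged, panel = panel)
    for (nm in names(tabs))
      writeCsvWithHeader(tabs[[nm]],
                         file.path(config$outputDir, paste0(nm, ".csv")), hdr)
    writeLines(c(hdr, report), file.path(config$outputDir, "report.txt"))
    writeLines(log, file.path(config$outputDir, "run.log"))
    jsonlite::write_json(
      list(package = "nflaxon",
           version = as.character(utils::packageVersion("nflaxon")),
           seed = config$seed, config_hash = cfgHash,
           n_patients = n, tables = names(tabs)),
      file.path(config$outputDir, "manifest.json"), auto_unbox = TRUE)
    note("outputs written to %s", config$outputDir)
  }
  out
}
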