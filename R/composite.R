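# Acute axonal degeneration composite score. Three read-outs proxy acute
# degeneration: degenerating-fiber density, teased-fiber ovoid fraction and
# CD68+ macrophage area. Each is normalised to the dataset maximum (%max)
# and the available components are averaged into a single %max score per
# patient. The two chronic-loss parameters (NF70 percent area and
# myelinated-fiber density) are deliberately kept separate: they capture
# distinct aspects of chronic loss and are reported as-is.

#' Acute axonal degeneration composite score
#'
#' Normalises the degenerating-fiber density and ovoid fraction to their
#' dataset maxima (computed over patients with non-missing values); the
#' CD68 value is already on the %max scale. The composite is the mean of
#' the available components; patients with fewer than two available
#' components get `NA` with a warning. Teased-fiber preparations exist only
#' for a subset of patients, so a missing ovoid component is expected and
#' the remaining two components are averaged.
#'
#' @param components data.frame with columns `study_id`, `degen_density`
#'   (fibers/mm^2), `ovoid_fraction` (0--1 or `NA`), `cd68_total_pctmax`
#'   (%max).
#' @return data.frame with `study_id`, `acute_composite` (%max),
#'   `n_components`, and the three normalised components
#'   (`degen_pctmax`, `ovoid_pctmax`, `cd68_pctmax`).
#' @examples
#' acuteComposite(data.frame(study_id = c("a", "b"),
#'                           degen_density = c(50, 100),
#'                           ovoid_fraction = c(0.2, 0.4),
#'                           cd68_total_pctmax = c(30, 100)))
#' @export
acuteComposite <- function(components) {
  need <- c("study_id", "degen_density", "ovoid_fraction",
            "cd68_total_pctmax")
  stopifnot(all(need %in% names(components)))
  degen <- normalizeToDatasetMax(components$degen_density)
  ovoid <- if (all(is.na(components$ovoid_fraction)))
    rep(NA_real_, nrow(components)) else
      normalizeToDatasetMax(components$ovoid_fraction)
  cd68 <- components$cd68_total_pctmax
  mat <- cbind(degen, ovoid, cd68)
  nComp <- rowSums(!is.na(mat))
  score <- rowMeans(mat, na.rm = TRUE)
  score[nComp < 2L] <- NA_real_
  if (any(nComp < 2L))
    warning(sprintf("%d patient(s) with < 2 available components: no score",
                    sum(nComp < 2L)))
  data.frame(study_id = components$study_id, acute_composite = score,
             n_components = as.integer(nComp), degen_pctmax = degen,
             ovoid_pctmax = ovoid, cd68_pctmax = cd68,
             stringsAsFactors = FALSE)
}

#' Cross-correlation of the acute-score components
#'
#' Spearman rank correlation for each pair of acute components on
#' pairwise-complete observations; pairs with insufficient overlap (fewer
#' than 3 complete pairs) yield `NA` with the available count annotated.
#'
#' @param components data.frame as for [acuteComposite()].
#' @return data.frame with one row per component pair: `var1`, `var2`,
#'   `r`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
componentCrossCorrelation <- function(components) {
  vars <- c("degen_density", "ovoid_fraction", "cd68_total_pctmax")
  stopifnot(all(vars %in% names(components)))
  pairs <- utils::combn(vars, 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    x <- components[[pairs[1, k]]]
    y <- components[[pairs[2, k]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L)
      return(data.frame(var1 = pairs[1, k], var2 = pairs[2, k],
                        r = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        p = NA_real_, n = sum(ok), stringsAsFactors = FALSE))
    res <- spearmanCorrelation(x[ok], y[ok])
    data.frame(var1 = pairs[1, k], var2 = pairs[2, k],
               r = corEstimate(res), ci_low = corCI(res)[1],
               ci_high = corCI(res)[2], p = corPValue(res), n = corN(res),
               stringsAsFactors = FALSE)
  }))
}

#' Package the two chronic axonal-loss parameters as separate series
#'
#' No composite is formed for chronic loss; the NF70 percent area and the
#' myelinated-fiber density are emitted as two labelled per-patient series
#' (missing values dropped per series).
#'
#' @param studyId patient identifiers.
#' @param nf70PctArea NF70-positive percent of fascicular area.
#' @param fiberDensity myelinated fibers/mm^2.
#' @return data.frame in long form: `study_id`, `parameter`, `value`.
#' @export
chronicParameters <- function(studyId, nf70PctArea, fiberDensity) {
  stopifnot(length(studyId) == length(nf70PctArea),
            length(studyId) == length(fiberDensity))
  out <- rbind(
    data.frame(study_id = studyId, parameter = "nf70_pct_area",
               value = nf70PctArea, stringsAsFactors = FALSE),
    data.frame(study_id = studyId, parameter = "fiber_density",
               value = fiberDensity, stringsAsFactors = FALSE)
  )
  out[!is.na(out$value), , drop = FALSE]
}
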