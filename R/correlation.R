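# Spearman rank correlation with Fisher-z confidence intervals, the
# standard analysis battery (NfL measures x damage parameters, on the full
# cohort and restricted to patients without CNS disease), and plain-text
# report assembly. Serum NfL is right-skewed, hence rank statistics
# throughout; tests are two-tailed.

#' Spearman rank correlation with CI and two-tailed p
#'
#' Ranks use average ranks for ties; r is the Pearson correlation of the
#' ranks. The 95% CI comes from the Fisher z transform with standard error
#' `1/sqrt(n - 3)` (an approximation under ties), the two-tailed p from the
#' t approximation with `n - 2` degrees of freedom, or optionally from the
#' exact permutation distribution for small samples without ties.
#'
#' @param x,y numeric vectors; pairwise-complete observations are used.
#' @param pMethod `"t"` (default) or `"exact"` (delegated to
#'   [stats::cor.test()], n <= 10, no ties).
#' @return A [CorrelationResult-class].
#' @examples
#' spearmanCorrelation(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
#' @export
spearmanCorrelation <- function(x, y, pMethod = c("t", "exact")) {
  pMethod <- match.arg(pMethod)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (var(x) == 0 || var(y) == 0)
    stop("correlation undefined for a constant series", call. = FALSE)
  r <- cor(x, y, method = "spearman")
  if (n > 3L) {
    z <- atanh(clamp(r, -1 + 1e-15, 1 - 1e-15))
    hw <- qnorm(0.975) / sqrt(n - 3)
    ciLow <- tanh(z - hw); ciHigh <- tanh(z + hw)
  } else {
    ciLow <- NA_real_; ciHigh <- NA_real_
  }
  if (pMethod == "exact") {
    if (n > 10L)
      stop("exact permutation p supported for n <= 10 only", call. = FALSE)
    p <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  } else if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  new("CorrelationResult", r = r, ciLow = ciLow, ciHigh = ciHigh,
      p = min(1, p), n = as.integer(n), method = pMethod)
}

#' Flag a moderately strong, clinically meaningful correlation
#'
#' A correlation coefficient of 0.5 in absolute value is the cutoff for a
#' moderately strong correlation.
#'
#' @param result a [CorrelationResult-class] or a numeric r.
#' @return `TRUE` iff `|r| >= 0.5`.
#' @examples
#' moderateCorrelationFlag(0.5)
#' @export
moderateCorrelationFlag <- function(result) {
  r <- if (is(result, "CorrelationResult")) corEstimate(result) else result
  abs(r) >= 0.5
}

formatCorrelation <- function(object, digits = 2) {
  fmt <- function(v) formatC(round(v, digits), format = "f", digits = digits)
  ci <- if (is.na(object@ciLow)) "CI n/a" else
    sprintf("[%s to %s]", fmt(object@ciLow), fmt(object@ciHigh))
  sprintf("r = %s %s; p = %s; n = %d", fmt(object@r), ci,
          format.pval(object@p, digits = 2, eps = 1e-4), object@n)
}

# the analysis battery: NfL measures crossed with damage parameters
PANEL_X_VARS <- c(serum_nfl = "serum_nfl_pg_ml",
                  tissue_nfl = "tissue_nfl_pg_ml",
                  serum_csf_ratio = "serum_csf_ratio",
                  serum_z = "serum_z")
PANEL_Y_VARS <- c(acute_composite = "acute_composite",
                  nf70_pct_area = "nf70_pct_area",
                  fiber_density = "fiber_density")

#' Run the correlation analysis panel
#'
#' Crosses the NfL measures (serum NfL, tissue NfL, serum/CSF ratio,
#' age-adjusted serum Z-score) with the damage parameters (acute composite
#' score, NF70 percent area, myelinated-fiber density), on all patients and
#' restricted to patients without CNS disease. Per-analysis n reflects
#' pairwise-complete data; cells with fewer than 3 complete pairs or a
#' constant series yield `NA` rows.
#'
#' @param merged per-patient table joining scores, chronic parameters,
#'   derived NfL values and the `cns_disease` column on `study_id`.
#' @param cnsRule which patients the "without CNS disease" subgroup keeps:
#'   `"exclude_yes_only"` (default; patients with unclear status are
#'   retained) or `"exclude_yes_and_unclear"`.
#' @return data.frame with `x_var`, `y_var`, `subgroup`, `r`, `ci_low`,
#'   `ci_high`, `p`, `n`, `moderate`.
#' @export
runPanel <- function(merged, cnsRule = c("exclude_yes_only",
                                         "exclude_yes_and_unclear")) {
  cnsRule <- match.arg(cnsRule)
  xs <- PANEL_X_VARS[PANEL_X_VARS %in% names(merged)]
  ys <- PANEL_Y_VARS[PANEL_Y_VARS %in% names(merged)]
  if (!length(xs) || !length(ys))
    stop("merged table holds none of the panel variables", call. = FALSE)
  if (!"cns_disease" %in% names(merged))
    stop("merged table misses the cns_disease column", call. = FALSE)
  keepNoCns <- if (cnsRule == "exclude_yes_only")
    merged$cns_disease != "yes" else merged$cns_disease == "no"
  subgroups <- list(all = rep(TRUE, nrow(merged)), no_cns = keepNoCns)

  grid <- expand.grid(x = names(xs), y = names(ys),
                      subgroup = names(subgroups),
                      stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- subgroups[[grid$subgroup[i]]]
    x <- merged[[xs[grid$x[i]]]][sel]
    y <- merged[[ys[grid$y[i]]]][sel]
    nOk <- sum(is.finite(x) & is.finite(y))
    res <- tryCatch(spearmanCorrelation(x, y), error = function(e) NULL)
    if (is.null(res))
      return(data.frame(x_var = grid$x[i], y_var = grid$y[i],
                        subgroup = grid$subgroup[i], r = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                        n = nOk, moderate = NA, stringsAsFactors = FALSE))
    data.frame(x_var = grid$x[i], y_var = grid$y[i],
               subgroup = grid$subgroup[i], r = corEstimate(res),
               ci_low = corCI(res)[1], ci_high = corCI(res)[2],
               p = corPValue(res), n = corN(res),
               moderate = moderateCorrelationFlag(res),
               stringsAsFactors = FALSE)
  }))
}

#' Render a plain-text analysis report
#'
#' Deterministically ordered tabular report of `r [CI]; p; n` per analysis,
#' preceded by the cohort summary block; running the same panel twice gives
#' byte-identical output.
#'
#' @param panel data.frame from [runPanel()].
#' @param summary optional [CohortSummary-class] printed as a header block.
#' @param digits decimals for r and the CI bounds (1 mirrors clinical
#'   reporting style; default 2).
#' @return Character vector of report lines.
#' @export
renderReport <- function(panel, summary = NULL, digits = 2) {
  lines <- character(0)
  if (!is.null(summary)) {
    lines <- c(lines, "== Cohort ==",
               sprintf("patients: %d (%d m / %d f); CNS disease: %d; vasculitis: %d (%d acute/subacute); other dx: %d; median days biosample-to-biopsy: %g",
                       summary@nTotal, summary@nMale, summary@nFemale,
                       summary@nCnsYes, summary@nVasculitis,
                       summary@nVasculitisAcuteOrSubacute, summary@nOtherDx,
                       summary@medianDeltaDays),
               "")
  }
  lines <- c(lines, "== Spearman rank correlations ==")
  if (nrow(panel)) {
    ord <- order(panel$subgroup, panel$y_var, panel$x_var)
    panel <- panel[ord, , drop = FALSE]
    fmt <- function(v) formatC(round(v, digits), format = "f",
                               digits = digits)
    for (i in seq_len(nrow(panel))) {
      row <- panel[i, ]
      body <- if (is.na(row$r)) "not estimable" else
        sprintf("r = %s [%s to %s]; p = %s; n = %d%s",
                fmt(row$r), fmt(row$ci_low), fmt(row$ci_high),
                format.pval(row$p, digits = 2, eps = 1e-4), row$n,
                if (isTRUE(row$moderate)) " *" else "")
      lines <- c(lines, sprintf("%-8s %-16s vs %-16s %s", row$subgroup,
                                row$y_var, row$x_var, body))
    }
  }
  lines
}
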