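## Neurochemical co-localization profiles and individual-level statistics.

#' Canonical neurotransmitter template names
#'
#' The fixed 16-template order used for neurochemical profiles: serotonin
#' receptors (5-HT1a, 5-HT1b, 5-HT2a, 5HT4), dopamine receptors (D1, D2),
#' the dopamine and serotonin transporters (DAT, SERT), dopamine synthesis
#' capacity (FDOPA), GABAa, NMDA and mGluR5 receptors, the mu-opioid (MU)
#' and cannabinoid (CB1) receptors, the noradrenaline transporter (NAT) and
#' the vesicular acetylcholine transporter (VAChT).
#'
#' @return character vector of length 16.
#' @export
canonicalTemplateNames <- function() {
  c("5-HT1a", "5-HT1b", "5-HT2a", "5HT4", "D1", "D2", "DAT", "SERT",
    "FDOPA", "GABAa", "NMDA", "mGluR5", "MU", "CB1", "NAT", "VAChT")
}

#' Build a neurochemical profile from per-template co-localization results
#'
#' Collects the Fisher-z co-localization strengths of one contrast against
#' every template into a fixed-order vector. Input order is irrelevant;
#' missing or duplicated templates are an error.
#'
#' @param results list of ColocResult, one per template.
#' @param label contrast label for the profile.
#' @param templateOrder canonical template order; defaults to the 16
#'   canonical names when all are present, otherwise the sorted names seen.
#' @return a NeurochemProfile.
#' @export
buildProfile <- function(results, label,
                         templateOrder = NULL) {
  nm <- vapply(results, function(r) r@templateName, character(1))
  if (anyDuplicated(nm)) stop("duplicate template in profile input")
  if (is.null(templateOrder)) {
    templateOrder <- if (setequal(nm, canonicalTemplateNames()))
      canonicalTemplateNames() else sort(nm)
  }
  if (!setequal(nm, templateOrder))
    stop("profile input must contain exactly the templates: ",
         paste(setdiff(templateOrder, nm), collapse = ", "), " missing")
  z <- vapply(results, function(r) r@fisherZ, numeric(1))
  names(z) <- nm
  new("NeurochemProfile", z = z[templateOrder], contrastLabel = label)
}

#' Pearson correlation between two neurochemical profiles
#'
#' Correlates the Fisher-z vectors of two profiles over their (identical)
#' template order; with the 16 canonical templates the reported df is 14.
#'
#' @param a,b NeurochemProfiles with identical template order.
#' @return list with r, two-sided t-based p, Fisher 95% ci95 and df = n-2.
#' @export
profileCorrelation <- function(a, b) {
  if (!identical(names(a@z), names(b@z)))
    stop("profiles must share one template order")
  pearsonSummary(a@z, b@z)
}

#' Individual z-maps of cases relative to the control group
#'
#' For every case subject and region,
#' `z = (x_case - mean_controls) / sd_controls` (sd with n-1 denominator).
#' Regions with zero control sd become NA with a warning.
#'
#' @param caseRegions cases x regions matrix of region values.
#' @param controlRegions controls x regions matrix (>= 3 controls).
#' @return cases x regions matrix of z-scores.
#' @export
subjectZmaps <- function(caseRegions, controlRegions) {
  caseRegions <- as.matrix(caseRegions)
  controlRegions <- as.matrix(controlRegions)
  if (nrow(controlRegions) < 3) stop("need at least 3 controls")
  if (ncol(caseRegions) != ncol(controlRegions))
    stop("case and control matrices must share regions")
  mu <- colMeans(controlRegions)
  sdc <- apply(controlRegions, 2, sd)
  bad <- sdc == 0 | !is.finite(sdc)
  if (any(bad)) {
    warning(sum(bad), " region(s) with zero control sd set to missing")
    sdc[bad] <- NA_real_
  }
  sweep(sweep(caseRegions, 2, mu), 2, sdc, "/")
}

#' Individual co-localization strength of one subject's z-map
#'
#' The Fisher z of the partial Spearman correlation between a subject's
#' region-level z-map and a template map, adjusting for gray matter.
#' Saturated correlations (|rho| = 1) are clipped before atanh with a
#' warning so the result stays finite.
#'
#' @param zmap subject z-scores as RegionVector or numeric vector.
#' @param template template RegionVector.
#' @param gm gray-matter RegionVector.
#' @return Fisher z scalar.
#' @export
subjectColoc <- function(zmap, template, gm)
  fisherZ(partialSpearman(zmap, template, gm), clip = TRUE)

#' Correlate individual co-localization strengths with symptom scores
#'
#' Pearson correlation between per-subject Fisher-z co-localization
#' strengths for one template and one clinical score, dropping subjects
#' with missing scores; two-sided p, Fisher 95% CI and df = n - 2.
#'
#' @param subjectZ data.frame with a `subject` column and one Fisher-z
#'   column per template.
#' @param scores data.frame with a `subject` column and score columns.
#' @param template template column name in `subjectZ`.
#' @param score score column name in `scores`.
#' @return list with r, p, ci95, df and n.
#' @export
symptomCorrelation <- function(subjectZ, scores, template, score) {
  m <- merge(subjectZ[, c("subject", template)],
             scores[, c("subject", score)], by = "subject")
  z <- m[[template]]; s <- m[[score]]
  ok <- complete.cases(z, s)
  if (sum(ok) < 4) stop("need at least 4 subjects with both values")
  if (sd(s[ok]) == 0) stop("constant score vector")
  res <- pearsonSummary(z[ok], s[ok])
  res$n <- sum(ok)
  res
}
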