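## Region-of-interest effects: mean LCOR within significance masks and
## directional one-sample tests on drug-minus-placebo delta scores.

#' Mean map values inside a mask, per subject and condition
#'
#' @param maps nested list `maps[[subject]][[condition]]` of StatMaps.
#' @param mask 3D logical array (nonempty).
#' @return subjects x conditions matrix of means over finite masked voxels.
#' @export
extractMaskMeans <- function(maps, mask) {
  if (!any(mask)) stop("empty mask")
  vox <- which(mask)
  out <- t(vapply(maps, function(conds) {
    vapply(conds, function(m) {
      v <- m@data[vox]
      v <- v[is.finite(v)]
      if (length(v) == 0) stop("mask contains no finite voxels")
      mean(v)
    }, numeric(1))
  }, numeric(length(maps[[1]]))))
  out
}

#' Directional one-sample test on drug-minus-placebo delta scores
#'
#' Delta = drug - placebo per subject; a one-sample t-test against zero in
#' the hypothesised direction, with df = n - 1, Cohen's d = |mean| / sd,
#' and the one-sided 90% confidence interval open toward the hypothesised
#' tail.
#'
#' @param drugMeans,placeboMeans paired per-subject mean values (n >= 3).
#' @param direction "less" (drug reduces the measure) or "greater".
#' @param maskLabel label carried into the result.
#' @return a DeltaResult.
#' @export
deltaTest <- function(drugMeans, placeboMeans,
                      direction = c("less", "greater"),
                      maskLabel = "mask") {
  direction <- match.arg(direction)
  if (length(drugMeans) != length(placeboMeans))
    stop("paired vectors required")
  if (length(drugMeans) < 3) stop("need at least 3 subjects")
  delta <- drugMeans - placeboMeans
  if (sd(delta) == 0) stop("zero-variance delta scores")
  tt <- stats::t.test(delta, mu = 0, alternative = direction,
                      conf.level = 0.90)
  new("DeltaResult", t = unname(tt$statistic),
      df = as.integer(tt$parameter),
      pOneSided = tt$p.value,
      cohenD = abs(mean(delta)) / sd(delta),
      ciOneSided = as.numeric(tt$conf.int),
      direction = direction, maskLabel = maskLabel)
}
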