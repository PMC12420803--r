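## Region-level co-localization statistics: partial Spearman correlation
## adjusting for gray matter, spatial-autocorrelation-preserving surrogate
## permutation p-values, Fisher z, BH-FDR and Fisher's-method combination.

#' Partial Spearman correlation of two region vectors given a covariate
#'
#' Ranks x, y and the covariate (average ranks for ties) after pairwise
#' deletion of incomplete regions, residualizes rank-x and rank-y on
#' `[1, rank-cov]`, and returns the Pearson correlation of the residuals.
#' With a constant covariate this reduces exactly to the ordinary Spearman
#' rho. If a residual vector is identically zero (the covariate explains
#' the variable completely) the partial correlation is 0.
#'
#' @param x,y RegionVectors or numeric vectors.
#' @param cov covariate RegionVector or numeric vector (e.g. gray-matter
#'   probability).
#' @return partial Spearman rho in `[-1, 1]`.
#' @export
partialSpearman <- function(x, y, cov) {
  x <- if (is(x, "RegionVector")) x@values else as.numeric(x)
  y <- if (is(y, "RegionVector")) y@values else as.numeric(y)
  cov <- if (is(cov, "RegionVector")) cov@values else as.numeric(cov)
  ok <- complete.cases(x, y, cov)
  if (sum(ok) < 4) stop("need at least 4 complete regions")
  rx <- rank(x[ok]); ry <- rank(y[ok]); rc <- rank(cov[ok])
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("constant variable after ranking: correlation undefined")
  q <- qr(cbind(1, rc))
  ex <- qr.resid(q, rx)
  ey <- qr.resid(q, ry)
  ## residuals that vanish relative to the rank scale mean the covariate
  ## explains the variable completely: partial correlation 0
  if (sum(ex^2) <= 1e-20 * sum(rx^2) || sum(ey^2) <= 1e-20 * sum(ry^2))
    return(0)
  sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
}

## Remap every column of M onto the sorted source values by within-column
## rank (ties broken by position), using one global order() call.
colRankRemap <- function(M, sortedX) {
  n <- nrow(M); k <- ncol(M)
  idx <- order(col(M), M)
  rk <- integer(n * k)
  rk[idx] <- rep(seq_len(n), k)
  matrix(sortedX[rk], n, k)
}

## Column standardization with a zero-variance guard.
colStd <- function(M) {
  M <- as.matrix(M)
  mu <- colMeans(M)
  s <- apply(M, 2, sd)
  s[s < 1e-12] <- 1
  t((t(M) - mu) / s)
}

## Binned semivariogram support: pair indices and bin assignment for a set
## of centroids. Pairs beyond the 75th distance percentile are discarded
## (long lags are noisy and carry little autocorrelation signal); the rest
## fall into equal-count bins.
variogramBins <- function(centroids, nBins = 10) {
  n <- nrow(centroids)
  if (n < 4) stop("need at least 4 regions for a variogram")
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- sqrt(rowSums((centroids[ij[, 1], , drop = FALSE] -
                     centroids[ij[, 2], , drop = FALSE])^2))
  if (max(d) <= 0) stop("degenerate centroid geometry: all centroids equal")
  keep <- d <= stats::quantile(d, 0.75)
  ij <- ij[keep, , drop = FALSE]
  d <- d[keep]
  nBins <- min(nBins, max(2L, length(unique(d)) %/% 2L))
  br <- unique(stats::quantile(d, probs = seq(0, 1, length.out = nBins + 1)))
  bin <- cut(d, breaks = br, include.lowest = TRUE, labels = FALSE)
  list(i = ij[, 1], j = ij[, 2], bin = bin, nBins = length(br) - 1L)
}

## gamma(h) = mean of 0.5 (v_i - v_j)^2 within each distance bin; accepts a
## vector or a regions x k matrix (one variogram per column).
binnedVariogram <- function(values, vb) {
  values <- as.matrix(values)
  sq <- 0.5 * (values[vb$i, , drop = FALSE] - values[vb$j, , drop = FALSE])^2
  out <- rowsum(sq, vb$bin) / as.numeric(table(vb$bin))
  if (ncol(out) == 1) as.numeric(out) else out
}

#' Variogram-matched surrogate maps
#'
#' Generates null maps that preserve the spatial autocorrelation of a
#' source region map: the source values are randomly permuted, smoothed
#' across regions with a distance-decaying exponential kernel, mixed with
#' the unsmoothed permutation, and finally rank-remapped onto the original
#' value multiset. The kernel bandwidth and mixing weight are selected once
#' per source map by least-squares matching of the binned semivariogram
#' over pilot permutations; every surrogate is therefore an exact
#' rearrangement of the source values with matched spatial structure.
#'
#' @param map source RegionVector (or numeric vector).
#' @param centroids regions x 3 matrix of centroid mm coordinates.
#' @param nSurr number of surrogates (>= 100 for permutation p-values).
#' @param seed integer seed.
#' @param nPilot pilot permutations used to fit the variogram match.
#' @return a SurrogateSet (rows = surrogates; NA columns where the source
#'   map was missing).
#' @export
generateSurrogates <- function(map, centroids, nSurr, seed = 1L,
                               nPilot = 20L) {
  nm <- if (is(map, "RegionVector")) map@name else "map"
  x <- if (is(map, "RegionVector")) map@values else as.numeric(map)
  centroids <- as.matrix(centroids)
  if (nrow(centroids) != length(x))
    stop("centroids must match regions")
  if (nSurr < 1) stop("nSurr must be positive")
  ok <- is.finite(x)
  xs <- x[ok]
  cen <- centroids[ok, , drop = FALSE]
  R <- length(xs)
  vb <- variogramBins(cen)
  gSrc <- binnedVariogram(xs, vb)
  D <- as.matrix(stats::dist(cen))
  dq <- stats::quantile(D[upper.tri(D)],
                        c(0.05, 0.1, 0.2, 0.3, 0.45, 0.6, 0.8))
  deltas <- unique(pmax(dq, 1e-6))
  lambdas <- seq(0, 1, by = 0.05)
  ## candidate smoothing kernels: exponential and Gaussian distance decay
  kernelForms <- list(function(dl) exp(-D / dl),
                      function(dl) exp(-D^2 / (2 * dl^2)))
  sortedX <- sort(xs)

  withSeed(seed, "surrogates", {
    kernels <- unlist(lapply(kernelForms, function(f)
      lapply(deltas, function(dl) {
        K <- f(dl)
        K / rowSums(K)
      })), recursive = FALSE)
    ## pilot fit of (bandwidth, mixing weight), vectorized over pilots and
    ## mixing weights per kernel
    P0 <- vapply(seq_len(nPilot), function(i) xs[sample(R)], numeric(R))
    P0s <- colStd(P0)
    sse <- matrix(0, length(kernels), length(lambdas))
    for (a in seq_along(kernels)) {
      S <- colStd(kernels[[a]] %*% P0)
      Zall <- do.call(cbind, lapply(lambdas, function(lam)
        sqrt(lam) * S + sqrt(1 - lam) * P0s))
      Zall <- colRankRemap(Zall, sortedX)
      G <- binnedVariogram(Zall, vb)
      err <- colSums((G - gSrc)^2)
      sse[a, ] <- colSums(matrix(err, nrow = nPilot))
    }
    best <- which(sse == min(sse), arr.ind = TRUE)[1, ]
    K <- kernels[[best[1]]]
    lam <- lambdas[best[2]]

    P <- vapply(seq_len(nSurr), function(i) xs[sample(R)], numeric(R))
    S <- colStd(K %*% P)
    Pstd <- colStd(P)
    Z <- sqrt(lam) * S + sqrt(1 - lam) * Pstd
    surr <- colRankRemap(Z, sortedX)

    nChk <- min(50L, nSurr)
    gBar <- rowMeans(as.matrix(binnedVariogram(surr[, seq_len(nChk),
                                               drop = FALSE], vb)))
    fitErr <- mean(abs(gBar - gSrc) / pmax(gSrc, 1e-12))

    out <- matrix(NA_real_, nrow = nSurr, ncol = length(x))
    out[, ok] <- t(surr)
    new("SurrogateSet", maps = out, seed = as.integer(seed),
        variogramFitError = fitErr, sourceName = nm)
  })
}

## Batched partial Spearman of one contrast against the rows of a surrogate
## matrix (surrogates in rows), sharing the complete-region set `ok`.
partialSpearmanBatch <- function(x, mat, cov, ok) {
  rx <- rank(x[ok]); rc <- rank(cov[ok])
  q <- qr(cbind(1, rc))
  ex <- qr.resid(q, rx)
  Rk <- apply(mat[, ok, drop = FALSE], 1, rank)   # regions x surrogates
  Ey <- qr.resid(q, Rk)
  num <- colSums(Ey * ex)
  den <- sqrt(sum(ex^2) * colSums(Ey^2))
  ifelse(den > 1e-14, num / den, 0)
}

#' Co-localization test of a contrast map against a template map
#'
#' Computes the partial Spearman correlation between a region-level
#' contrast map and a template map adjusting for gray matter, and an exact
#' two-sided permutation p-value comparing the observed coefficient with
#' those obtained from the template's autocorrelation-preserving
#' surrogates: `p = (1 + #{|rho_surr| >= |rho|}) / (n_surr + 1)`. The
#' Fisher z transform and its normal-approximation 95% CI
#' (`tanh(z +/- 1.96 / sqrt(n - 3))`) are attached; the reported degrees of
#' freedom are `n_regions_used - 2`.
#'
#' @param contrast contrast RegionVector (e.g. a parcellated t-map).
#' @param template template RegionVector the surrogates were generated from.
#' @param gm gray-matter probability RegionVector.
#' @param surrogates a [generateSurrogates()] result for `template`.
#' @return a ColocResult.
#' @export
colocTest <- function(contrast, template, gm, surrogates) {
  x <- contrast@values; y <- template@values; g <- gm@values
  if (!identical(contrast@regionIds, template@regionIds) ||
      !identical(contrast@regionIds, gm@regionIds))
    stop("region vectors are not aligned")
  if (ncol(surrogates@maps) != length(y))
    stop("surrogates do not match the template's regions")
  ok <- complete.cases(x, y, g)
  rho <- partialSpearman(x, y, g)
  rhoSurr <- partialSpearmanBatch(x, surrogates@maps, g, ok)
  nSurr <- nrow(surrogates@maps)
  pPerm <- (1 + sum(abs(rhoSurr) >= abs(rho))) / (nSurr + 1)
  n <- sum(ok)
  z <- fisherZ(rho, clip = TRUE)
  ci <- tanh(z + c(-1, 1) * 1.96 / sqrt(n - 3))
  new("ColocResult", rho = rho, pPerm = pPerm, fisherZ = z, ci95 = ci,
      dfReport = as.integer(n - 2L), nRegionsUsed = as.integer(n),
      templateName = template@name)
}

#' Spatial similarity of two contrast maps
#'
#' Identical machinery to [colocTest()] with the second contrast in the
#' template slot: used for cross-cohort t-map similarity and for comparing
#' drug-induced with case-control alteration maps.
#'
#' @param contrastA,contrastB RegionVectors on one atlas.
#' @param gm gray-matter probability RegionVector.
#' @param surrogatesOfB surrogates generated from `contrastB`.
#' @return a ColocResult (templateName = contrastB's name).
#' @export
mapSimilarity <- function(contrastA, contrastB, gm, surrogatesOfB)
  colocTest(contrastA, contrastB, gm, surrogatesOfB)

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjusted p-values (monotone, capped at 1), as used for
#' the meta-combined co-localization table.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values.
#' @export
bhFdr <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Combine independent p-values with Fisher's method
#'
#' `X = -2 sum(log p)` is referred to a chi-square distribution with `2k`
#' degrees of freedom; with a single p-value the input is returned
#' unchanged.
#'
#' @param p vector of independent p-values in (0, 1].
#' @return the combined p-value.
#' @export
fisherCombine <- function(p) {
  if (length(p) < 1) stop("need at least one p-value")
  if (any(p <= 0)) stop("p-values of 0 are not combinable (log underflow)")
  if (any(p > 1)) stop("p-values must lie in (0, 1]")
  X <- -2 * sum(log(p))
  pchisq(X, df = 2 * length(p), lower.tail = FALSE)
}

#' Two-stage exploration/replication protocol with meta-combination
#'
#' Stage 1 flags templates with two-sided permutation p < alpha
#' (uncorrected) in the exploration cohort; stage 2 tests only flagged
#' templates in the replication cohort (replication = p < alpha with the
#' same sign of rho); stage 3 combines both cohorts' p-values per flagged
#' template with Fisher's method and applies Benjamini-Hochberg correction
#' across the flagged set.
#'
#' @param resultsA named list of ColocResult for every template (cohort A).
#' @param resultsB named list of ColocResult covering at least the flagged
#'   templates (cohort B).
#' @param alpha significance level for both stages.
#' @return data.frame with per-template rho/p for both cohorts, flags,
#'   replication status, combined and BH-adjusted p, and the final
#'   selection (replicated AND adjusted combined p < alpha).
#' @export
explorationReplication <- function(resultsA, resultsB, alpha = 0.05) {
  tmpl <- vapply(resultsA, function(r) r@templateName, character(1))
  names(resultsA) <- tmpl
  names(resultsB) <- vapply(resultsB, function(r) r@templateName,
                            character(1))
  out <- data.frame(template = tmpl,
                    rho_A = vapply(resultsA, function(r) r@rho, numeric(1)),
                    p_A = vapply(resultsA, function(r) r@pPerm, numeric(1)),
                    stringsAsFactors = FALSE)
  out$flagged <- out$p_A < alpha
  out$rho_B <- NA_real_; out$p_B <- NA_real_
  out$replicated <- FALSE
  out$p_combined <- NA_real_
  for (k in which(out$flagged)) {
    tb <- out$template[k]
    if (!tb %in% names(resultsB))
      stop("flagged template '", tb, "' missing from replication results")
    rb <- resultsB[[tb]]
    out$rho_B[k] <- rb@rho
    out$p_B[k] <- rb@pPerm
    out$replicated[k] <- rb@pPerm < alpha &&
      sign(rb@rho) == sign(out$rho_A[k])
    out$p_combined[k] <- fisherCombine(c(out$p_A[k], rb@pPerm))
  }
  out$p_fdr <- NA_real_
  if (any(out$flagged))
    out$p_fdr[out$flagged] <- bhFdr(out$p_combined[out$flagged])
  out$selected <- out$replicated & !is.na(out$p_fdr) & out$p_fdr < alpha
  rownames(out) <- NULL
  out
}
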