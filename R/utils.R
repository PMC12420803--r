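#' @useDynLib neurocoloc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif rbinom sd var cor cor.test qt pt pchisq
#'   p.adjust complete.cases qnorm dnorm
#' @importFrom stats setNames
#' @importFrom utils write.table read.table head
NULL

## FWHM of a Gaussian kernel to its standard deviation (same units).
FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))  # 1/2.3548

fwhmToSigma <- function(fwhm) fwhm * FWHM_TO_SIGMA

#' Derive a reproducible sub-stream seed from a root seed and a stage label
#'
#' All randomness in the pipeline flows from one root seed; each stage draws
#' from its own deterministic sub-stream so that inserting or reordering
#' stages does not perturb the others.
#'
#' @param seed integer root seed.
#' @param label character stage label.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
deriveSeed <- function(seed, label) {
  stopifnot(is.character(label), length(label) == 1L)
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483629
  as.integer((abs(as.numeric(seed)) %% 2147483629 * 7919 + h) %% 2147483629)
}

## Evaluate expr with the RNG seeded from (seed, label), restoring the
## caller's RNG state afterwards.
withSeed <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(deriveSeed(seed, label))
  expr
}

## Voxel index grid (1-based) for a 3D dim; returns n x 3 matrix.
voxelIndexGrid <- function(dm) {
  cbind(
    rep(seq_len(dm[1]), times = dm[2] * dm[3]),
    rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]),
    rep(seq_len(dm[3]), each = dm[1] * dm[2])
  )
}

## World (mm) coordinates of voxel indices under a 4x4 affine; indices are
## 1-based in R, the affine acts on 0-based indices (NIfTI convention).
voxelToWorld <- function(idx, affine) {
  idx0 <- cbind(idx - 1, 1)
  t(affine %*% t(idx0))[, 1:3, drop = FALSE]
}

worldToVoxel <- function(xyz, affine) {
  xyz1 <- cbind(xyz, 1)
  t(solve(affine) %*% t(xyz1))[, 1:3, drop = FALSE] + 1
}

## Default affine: isotropic voxels of size vox mm, grid centred at origin.
centredAffine <- function(dm, vox) {
  aff <- diag(c(vox, vox, vox, 1))
  aff[1:3, 4] <- -vox * (dm - 1) / 2
  aff
}

affinesEqual <- function(a, b, tol = 1e-5) {
  all(dim(a) == c(4, 4)) && all(dim(b) == c(4, 4)) && max(abs(a - b)) <= tol
}

## Fisher z helpers; |rho| = 1 is clipped to keep z finite.
fisherZ <- function(r, clip = FALSE) {
  if (clip && any(abs(r) >= 1, na.rm = TRUE)) {
    warning("correlation of magnitude 1 clipped before Fisher z transform")
    r <- pmin(pmax(r, -(1 - 1e-15)), 1 - 1e-15)
  }
  atanh(r)
}

## Two-sided p and Fisher CI for a Pearson correlation with df = n - 2.
pearsonSummary <- function(x, y, conf.level = 0.95) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance input to correlation")
  ct <- cor.test(x, y, method = "pearson", conf.level = conf.level)
  list(r = unname(ct$estimate), p = ct$p.value,
       ci95 = as.numeric(ct$conf.int), df = unname(ct$parameter))
}
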