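## Local synchronization (LCOR): per-voxel average temporal correlation with
## neighbouring voxels, distance-weighted by a Gaussian kernel, computed on
## confound-regressed time series and optionally smoothed afterwards.

#' Bundle confound regressors
#' @param regressors t x k numeric matrix (k = 0 allowed for intercept-only
#'   regression, i.e. temporal demeaning).
#' @param names optional column names.
#' @return a ConfoundSet (validated list).
#' @export
confoundSet <- function(regressors = matrix(0, 0, 0), names = NULL) {
  regressors <- as.matrix(regressors)
  if (length(regressors) && any(!is.finite(regressors)))
    stop("confound regressors must be finite")
  if (!is.null(names)) colnames(regressors) <- names
  structure(list(regressors = regressors), class = "ConfoundSet")
}

#' LCOR parameters
#'
#' The kernel FWHM (default 25 mm) sets the spatial scale of "local"; the
#' kernel is truncated at twice its FWHM, beyond which weights fall below
#' 1e-5 of the peak. Smoothing (default 6 mm FWHM) is applied to the LCOR
#' map, not the time series. The centre voxel is excluded from its own
#' average unless `includeSelf` (its self-correlation of 1 would inflate
#' every value).
#'
#' @param kernelFwhmMm Gaussian distance-weighting kernel FWHM in mm.
#' @param smoothFwhmMm FWHM of the post-hoc map smoothing (0 = none).
#' @param truncationRadiusMm kernel truncation radius in mm.
#' @param mask 3D logical analysis mask (NULL = all voxels).
#' @param includeSelf include the centre voxel in its own average.
#' @return an LcorParams (validated list).
#' @export
lcorParams <- function(kernelFwhmMm = 25, smoothFwhmMm = 6,
                       truncationRadiusMm = 2 * kernelFwhmMm, mask = NULL,
                       includeSelf = FALSE) {
  stopifnot(kernelFwhmMm > 0, smoothFwhmMm >= 0)
  if (truncationRadiusMm < kernelFwhmMm / 2)
    stop("truncationRadiusMm must be at least half the kernel FWHM")
  structure(list(kernelFwhmMm = kernelFwhmMm, smoothFwhmMm = smoothFwhmMm,
                 truncationRadiusMm = truncationRadiusMm, mask = mask,
                 includeSelf = includeSelf), class = "LcorParams")
}

#' Regress confounds out of every voxel time series
#'
#' Each voxel series is replaced by its least-squares residual against
#' `[intercept | regressors]`. Collinear regressor columns are dropped with
#' a warning. Residuals are orthogonal to every retained regressor.
#'
#' @param img a FunctionalImage.
#' @param confounds a [confoundSet()].
#' @return a FunctionalImage of residual series.
#' @export
regressConfounds <- function(img, confounds = confoundSet()) {
  d <- dim(img@data)
  nt <- d[4]
  R <- confounds$regressors
  if (length(R) && nrow(R) != nt)
    stop("confound rows (", nrow(R), ") != timepoints (", nt, ")")
  X <- if (length(R) == 0 || ncol(R) == 0) matrix(1, nt, 1,
         dimnames = list(NULL, "intercept"))
       else cbind(intercept = rep(1, nt), R)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning("dropping collinear confound column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  if (nt < ncol(X) + 2) stop("need at least k + 2 timepoints")
  Y <- matrix(img@data, nrow = prod(d[1:3]), ncol = nt)
  res <- t(qr.resid(qrX, t(Y)))
  new("FunctionalImage", data = array(res, dim = d), affine = img@affine,
      trSeconds = img@trSeconds)
}

## Geometry shared by all subjects on one grid: masked voxel coordinates and
## the truncated Gaussian weight structure. Returned closure computes LCOR
## for one image, so cohort-level runs pay the distance work once.
lcorEngine <- function(dm, affine, params) {
  mask <- params$mask
  if (is.null(mask)) mask <- array(TRUE, dim = dm)
  if (!all(dim(mask) == dm)) stop("mask shape does not match image")
  vox <- which(mask)
  if (length(vox) < 2) stop("mask must contain at least 2 voxels")
  idx <- arrayInd(vox, dm)
  xyz <- voxelToWorld(idx, affine)
  sigma <- fwhmToSigma(params$kernelFwhmMm)
  r2 <- params$truncationRadiusMm^2
  n <- length(vox)

  function(img4d) {
    nt <- dim(img4d)[4]
    Y <- matrix(img4d, nrow = prod(dm), ncol = nt)[vox, , drop = FALSE]
    Yc <- Y - rowMeans(Y)
    nrm <- sqrt(rowSums(Yc^2))
    valid <- nrm > 0
    if (!all(valid))
      warning(sum(!valid), " zero-variance voxel(s) set to missing")
    U <- Yc[valid, , drop = FALSE] / nrm[valid]
    xyzv <- xyz[valid, , drop = FALSE]
    nv <- nrow(U)
    out <- rep(NA_real_, n)
    lcorv <- numeric(nv)
    blk <- max(1L, floor(2e7 / nv))
    sq <- rowSums(xyzv^2)
    for (s in seq(1L, nv, by = blk)) {
      e <- min(s + blk - 1L, nv)
      b <- s:e
      D2 <- outer(sq[b], sq, "+") - 2 * xyzv[b, , drop = FALSE] %*% t(xyzv)
      D2[D2 < 0] <- 0
      W <- exp(-D2 / (2 * sigma^2))
      W[D2 > r2] <- 0
      if (!params$includeSelf) W[cbind(seq_along(b), b)] <- 0
      denom <- rowSums(W)
      numer <- rowSums((W %*% U) * U[b, , drop = FALSE])
      lcorv[b] <- ifelse(denom > 0, numer / denom, NA_real_)
    }
    out[valid] <- lcorv
    full <- array(NA_real_, dim = dm)
    full[vox] <- out
    full
  }
}

#' Compute the LCOR map of a functional image
#'
#' LCOR(v) is the Gaussian-distance-weighted average of the Pearson
#' correlations between voxel v's time series and every other masked voxel
#' within the truncation radius:
#' `LCOR(v) = sum_u w(d(v,u)) cor(x_v, x_u) / sum_u w(d(v,u))`,
#' with `w` a Gaussian of the stated FWHM (sigma = FWHM / 2.3548). Values
#' lie in `[-1, 1]`. Zero-variance voxels are returned as NA. If
#' `params$smoothFwhmMm > 0` the LCOR map is smoothed afterwards.
#'
#' @param img a FunctionalImage (typically confound-regressed).
#' @param params an [lcorParams()].
#' @return a StatMap labelled "LCOR".
#' @export
computeLcor <- function(img, params = lcorParams()) {
  dm <- dim(img@data)[1:3]
  eng <- lcorEngine(dm, img@affine, params)
  out <- eng(img@data)
  m <- statMapFromLcor(out, img@affine)
  if (params$smoothFwhmMm > 0) m <- gaussianSmooth(m, params$smoothFwhmMm)
  m
}

statMapFromLcor <- function(arr, affine)
  new("StatMap", data = arr, affine = affine, label = "LCOR", df = NA_real_)

#' Compute LCOR maps for a list of images sharing one grid
#'
#' Same result as mapping [computeLcor()] over the list, but the kernel
#' geometry is built once.
#'
#' @param imgs list of FunctionalImage on a common grid.
#' @param params an [lcorParams()].
#' @return list of StatMap.
#' @export
computeLcorMany <- function(imgs, params = lcorParams()) {
  stopifnot(length(imgs) >= 1)
  dm <- dim(imgs[[1]]@data)[1:3]
  aff <- imgs[[1]]@affine
  eng <- lcorEngine(dm, aff, params)
  lapply(imgs, function(im) {
    if (!all(dim(im@data)[1:3] == dm) || !affinesEqual(im@affine, aff))
      stop("all images must share one grid")
    m <- statMapFromLcor(eng(im@data), aff)
    if (params$smoothFwhmMm > 0) m <- gaussianSmooth(m, params$smoothFwhmMm)
    m
  })
}

#' Gaussian smoothing of a 3D map in mm units
#'
#' Separable Gaussian convolution with the kernel truncated at 3.5 sigma.
#' Mask-aware: non-finite voxels contribute nothing and the result is
#' renormalized by the smoothed finite-mask, so values do not bleed toward
#' edges. `fwhmMm = 0` returns the map unchanged.
#'
#' @param map a StatMap.
#' @param fwhmMm smoothing kernel FWHM in mm.
#' @return a StatMap.
#' @export
gaussianSmooth <- function(map, fwhmMm) {
  stopifnot(fwhmMm >= 0)
  if (fwhmMm == 0) return(map)
  voxmm <- sqrt(colSums(map@affine[1:3, 1:3]^2))
  dat <- map@data
  fin <- is.finite(dat)
  num <- ifelse(fin, dat, 0)
  den <- fin * 1
  for (ax in 1:3) {
    sig <- fwhmToSigma(fwhmMm) / voxmm[ax]
    rad <- max(1L, as.integer(ceiling(3.5 * sig)))
    w <- dnorm(-rad:rad, sd = sig)
    w <- w / sum(w)
    num <- convolveAxis(num, w, ax)
    den <- convolveAxis(den, w, ax)
  }
  out <- array(NA_real_, dim = dim(dat))
  pos <- den > 1e-12
  out[pos] <- num[pos] / den[pos]
  out[!fin] <- NA_real_
  new("StatMap", data = out, affine = map@affine, label = map@label,
      df = map@df)
}

## 1D convolution along one axis of a 3D array (zero padding) via a banded
## kernel matrix; grids are small enough that the dense product is cheap.
convolveAxis <- function(arr, w, axis) {
  dm <- dim(arr)
  n <- dm[axis]
  rad <- (length(w) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (k in -rad:rad) {
    i <- seq_len(n)
    j <- i + k
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- w[k + rad + 1L]
  }
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  m <- aperm(arr, perm)
  dmp <- dim(m)
  m <- K %*% matrix(m, nrow = n)
  m <- array(m, dim = dmp)
  aperm(m, order(perm))
}
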