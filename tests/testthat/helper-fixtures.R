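## Shared fixtures, generated in code; kept tiny so the suite stays fast.

tinySpec <- function(...) {
  args <- list(gridShape = c(10L, 10L, 10L), voxelSizeMm = 3,
               nRegions = 12L, nPerGroup = 5L, nTimepoints = 40L,
               nSites = 1L, seed = 42L)
  args[names(list(...))] <- list(...)
  do.call(syntheticSpec, args)
}

tinyAtlas <- function(spec = tinySpec()) makeAtlas(spec)

## A deterministic FunctionalImage with i.i.d. normal series.
noiseImage <- function(dm = c(4, 4, 4), nt = 30, seed = 1, voxelSizeMm = 3) {
  set.seed(seed)
  functionalImage(array(rnorm(prod(dm) * nt), dim = c(dm, nt)),
                  voxelSizeMm = voxelSizeMm)
}

## Brute-force LCOR oracle: double loop over masked voxels with explicit
## Gaussian weights; the reference for computeLcor.
lcorOracle <- function(img, params) {
  dm <- dim(imgData(img))[1:3]
  mask <- params$mask
  if (is.null(mask)) mask <- array(TRUE, dim = dm)
  vox <- which(mask)
  idx <- arrayInd(vox, dm)
  aff <- imgAffine(img)
  xyz <- t(aff %*% t(cbind(idx - 1, 1)))[, 1:3, drop = FALSE]
  sigma <- params$kernelFwhmMm / (2 * sqrt(2 * log(2)))
  Y <- matrix(imgData(img), nrow = prod(dm))[vox, , drop = FALSE]
  n <- length(vox)
  out <- array(NA_real_, dim = dm)
  for (a in seq_len(n)) {
    if (sd(Y[a, ]) == 0) next
    num <- 0; den <- 0
    for (b in seq_len(n)) {
      if (b == a && !params$includeSelf) next
      if (sd(Y[b, ]) == 0) next
      d <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
      if (d > params$truncationRadiusMm) next
      w <- exp(-d^2 / (2 * sigma^2))
      num <- num + w * cor(Y[a, ], Y[b, ])
      den <- den + w
    }
    out[vox[a]] <- if (den > 0) num / den else NA_real_
  }
  out
}

## Independent partial-Spearman oracle: explicit normal equations on ranks.
partialSpearmanOracle <- function(x, y, cov) {
  ok <- complete.cases(x, y, cov)
  rx <- rank(x[ok]); ry <- rank(y[ok]); rc <- rank(cov[ok])
  X <- cbind(1, rc)
  bx <- solve(t(X) %*% X, t(X) %*% rx)
  by <- solve(t(X) %*% X, t(X) %*% ry)
  ex <- rx - X %*% bx
  ey <- ry - X %*% by
  sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
}

## Connectivity check: is the voxel set of each atlas region 6-connected?
regionIsConnected <- function(atlas, id) {
  dm <- dim(imgData(atlas))
  vox <- which(imgData(atlas) == id)
  if (length(vox) <= 1) return(TRUE)
  idx <- arrayInd(vox, dm)
  key <- function(m) (m[, 3] - 1) * dm[1] * dm[2] + (m[, 2] - 1) * dm[1] + m[, 1]
  inset <- new.env()
  for (v in vox) assign(as.character(v), TRUE, envir = inset)
  seen <- c(vox[1])
  frontier <- vox[1]
  while (length(frontier)) {
    cur <- arrayInd(frontier, dm)
    nxt <- integer(0)
    for (ax in 1:3) for (dlt in c(-1, 1)) {
      nb <- cur
      nb[, ax] <- nb[, ax] + dlt
      okb <- nb[, ax] >= 1 & nb[, ax] <= dm[ax]
      cand <- key(nb[okb, , drop = FALSE])
      cand <- cand[cand %in% vox & !(cand %in% seen)]
      nxt <- c(nxt, cand)
    }
    nxt <- unique(nxt)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(vox)
}
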