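## Voxel-wise group comparison: OLS t-contrasts, TFCE, and max-statistic
## permutation inference with Freedman-Lane residual permutation.

#' Construct a design matrix with a contrast
#' @param X subjects x p numeric matrix (include the intercept explicitly).
#' @param contrast length-p contrast vector.
#' @param strata optional factor of exchangeability blocks (e.g. site);
#'   permutations are restricted within blocks.
#' @return a DesignMatrix (validated list).
#' @export
designMatrix <- function(X, contrast, strata = NULL) {
  X <- as.matrix(X)
  if (length(contrast) != ncol(X))
    stop("contrast length must equal the number of design columns")
  if (!is.null(strata) && length(strata) != nrow(X))
    stop("strata length must equal the number of subjects")
  structure(list(X = X, contrast = as.numeric(contrast),
                 strata = if (is.null(strata)) NULL else as.factor(strata)),
            class = "DesignMatrix")
}

#' Build the standard group-comparison design from a covariate table
#'
#' Columns: intercept, group indicator (case = 1), centred age, male
#' indicator, centred FIQ, centred motion, and dummy-coded site fixed
#' effects. The contrast selects the group column; site is also used as the
#' permutation stratum.
#'
#' @param covariates data.frame with columns group, age, sex, fiq,
#'   motion_translation_mm, site (missing optional columns are skipped).
#' @param caseLevel level of `group` coding cases.
#' @return a DesignMatrix.
#' @export
buildDesign <- function(covariates, caseLevel = "case") {
  grp <- as.numeric(covariates$group == caseLevel)
  X <- cbind(intercept = 1, group = grp)
  for (col in c("age", "fiq", "motion_translation_mm"))
    if (col %in% names(covariates))
      X <- cbind(X, scale(covariates[[col]], scale = FALSE))
  colnames(X)[(ncol(X) - sum(c("age", "fiq", "motion_translation_mm") %in%
                             names(covariates)) + 1):ncol(X)] <-
    intersect(c("age", "fiq", "motion_translation_mm"), names(covariates))
  if ("sex" %in% names(covariates))
    X <- cbind(X, sexM = as.numeric(covariates$sex == "M"))
  strata <- NULL
  if ("site" %in% names(covariates)) {
    site <- as.factor(covariates$site)
    if (nlevels(site) > 1) {
      sd_ <- stats::model.matrix(~ site)[, -1, drop = FALSE]
      X <- cbind(X, sd_)
    }
    strata <- site
  }
  contrast <- as.numeric(colnames(X) == "group")
  designMatrix(X, contrast, strata = strata)
}

## Stack subject StatMaps into a subjects x voxels matrix restricted to
## voxels finite in every subject; returns Y, the voxel index, grid info.
stackMaps <- function(maps) {
  dm <- dim(maps[[1]]@data)
  aff <- maps[[1]]@affine
  Y <- vapply(maps, function(m) {
    if (!all(dim(m@data) == dm) || !affinesEqual(m@affine, aff))
      stop("subject maps are not co-registered")
    as.vector(m@data)
  }, numeric(prod(dm)))
  Y <- t(Y)                       # subjects x voxels
  keep <- which(colSums(!is.finite(Y)) == 0)
  list(Y = Y[, keep, drop = FALSE], vox = keep, dim = dm, affine = aff)
}

## Core t-statistic: Y subjects x voxels, full-rank X, contrast c.
tStatistic <- function(Y, X, contrast, XtXinv = NULL, df = NULL) {
  if (is.null(XtXinv)) XtXinv <- chol2inv(chol(crossprod(X)))
  if (is.null(df)) df <- nrow(X) - qr(X)$rank
  beta <- XtXinv %*% crossprod(X, Y)
  rss <- colSums((Y - X %*% beta)^2)
  cvar <- drop(t(contrast) %*% XtXinv %*% contrast)
  se <- sqrt(pmax(rss / df, 0) * cvar)
  num <- drop(contrast %*% beta)
  t <- ifelse(se > 0, num / se, 0)
  list(t = t, df = df)
}

#' Voxel-wise OLS t-contrast across subjects
#'
#' Fits `y_v = X b + e` independently at every voxel and returns the
#' contrast t-map `t = c'b / sqrt(s^2 c'(X'X)^-1 c)` with `df = n - rank(X)`
#' stored in the map. Voxels non-finite in any subject are NA.
#'
#' @param maps list of co-registered subject StatMaps.
#' @param design a [designMatrix()].
#' @return a StatMap labelled "t_contrast" with its df.
#' @export
fitVoxelwiseGlm <- function(maps, design) {
  X <- design$X
  if (nrow(X) != length(maps)) stop("one map per design row required")
  if (length(maps) < ncol(X) + 2) stop("need at least p + 2 subjects")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  st <- stackMaps(maps)
  ts <- tStatistic(st$Y, X, design$contrast)
  arr <- array(NA_real_, dim = st$dim)
  arr[st$vox] <- ts$t
  new("StatMap", data = arr, affine = st$affine, label = "t_contrast",
      df = as.numeric(ts$df))
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' `TFCE(v) = sum_h extent(v, h)^E h^H dh` over heights from 0 up to the
#' map maximum, with 26-connectivity cluster extents; the negative tail is
#' obtained by transforming the negated map identically and is returned
#' with negative sign. NA voxels are treated as background and stay NA.
#'
#' @param tMap a StatMap.
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh height step; default `max(|t|) / 100`.
#' @return a StatMap labelled "tfce".
#' @export
tfceTransform <- function(tMap, E = 0.5, H = 2, dh = NULL) {
  v <- tMap@data
  nas <- !is.finite(v)
  v[nas] <- 0
  if (is.null(dh)) {
    mx <- max(abs(v))
    dh <- if (mx > 0) mx / 100 else 1
  }
  out <- tfce_cpp(as.numeric(v), as.integer(dim(v)), E, H, dh)
  arr <- array(out, dim = dim(v))
  arr[nas] <- NA_real_
  new("StatMap", data = arr, affine = tMap@affine, label = "tfce",
      df = NA_real_)
}

## All permutations of seq_len(n) (n small), as a list.
allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- allPermutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (pos in 0:(n - 1L)) {
    k <- k + 1L
    out[[k]] <- as.integer(append(p, n, after = pos))
  }
  out
}

## Draw one within-strata permutation of seq_len(n).
strataPermutation <- function(n, strata) {
  p <- seq_len(n)
  if (is.null(strata)) return(sample(p))
  for (lv in levels(strata)) {
    i <- which(strata == lv)
    if (length(i) > 1) p[i] <- i[sample(length(i))]
  }
  p
}

#' Permutation inference on a voxel-wise group contrast
#'
#' Freedman-Lane residual permutation: the reduced model (all columns with
#' zero contrast weight) is fitted, its residuals are permuted (within
#' exchangeability strata when given) and added back to the reduced-model
#' fit, and the full-model contrast t-map is recomputed. Max-|t| and
#' max-|TFCE| null distributions give family-wise-error p-values
#' `p = (1 + #{perm max >= observed}) / (n_perm + 1)`. Significant voxels
#' must pass BOTH the voxel-FWE and the TFCE-FWE criterion at `alpha`,
#' split by contrast sign. When fewer distinct within-strata permutations
#' than `nPerm` exist they are enumerated exhaustively (with a message) and
#' `p = #{perm max >= observed} / N` over all N permutations including the
#' identity.
#'
#' @param maps list of co-registered subject StatMaps.
#' @param design a [designMatrix()] (strata used as permutation blocks).
#' @param nPerm number of permutations (>= 100 recommended).
#' @param alpha family-wise significance level.
#' @param seed integer seed.
#' @param E,H TFCE exponents.
#' @return an InferenceResult.
#' @export
permutationInference <- function(maps, design, nPerm = 1000L, alpha = 0.05,
                                 seed = 1L, E = 0.5, H = 2) {
  X <- design$X
  contrast <- design$contrast
  st <- stackMaps(maps)
  Y <- st$Y
  n <- nrow(Y)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient design")
  XtXinv <- chol2inv(chol(crossprod(X)))
  df <- n - ncol(X)

  obs <- tStatistic(Y, X, contrast, XtXinv, df)
  tArr <- array(0, dim = st$dim); tArr[st$vox] <- obs$t
  dh <- if (max(abs(obs$t)) > 0) max(abs(obs$t)) / 100 else 1
  tfceObs <- array(tfce_cpp(as.numeric(tArr), as.integer(st$dim), E, H, dh),
                   dim = st$dim)

  ## reduced (nuisance-only) model
  X0 <- X[, contrast == 0, drop = FALSE]
  if (ncol(X0) == 0) X0 <- matrix(1, n, 1)
  qr0 <- qr(X0)
  F0 <- qr.fitted(qr0, Y)
  R0 <- qr.resid(qr0, Y)

  strata <- design$strata
  logNDistinct <- if (is.null(strata)) lfactorial(n) else
    sum(lfactorial(table(strata)))
  exhaustive <- FALSE
  perms <- NULL
  if (logNDistinct <= log(nPerm)) {
    exhaustive <- TRUE
    if (is.null(strata)) perms <- allPermutations(n)
    else {
      perms <- list(seq_len(n))
      for (lv in levels(strata)) {
        i <- which(strata == lv)
        sub <- allPermutations(length(i))
        perms <- unlist(lapply(perms, function(p)
          lapply(sub, function(q) { p[i] <- i[q]; p })), recursive = FALSE)
      }
    }
    message("only ", length(perms),
            " distinct permutations; enumerating exhaustively")
  }
  nIter <- if (exhaustive) length(perms) else nPerm

  withSeed(seed, "permutation_inference", {
    maxT <- numeric(nIter)
    maxTfce <- numeric(nIter)
    for (j in seq_len(nIter)) {
      p <- if (exhaustive) perms[[j]] else strataPermutation(n, strata)
      Yp <- F0 + R0[p, , drop = FALSE]
      tp <- tStatistic(Yp, X, contrast, XtXinv, df)$t
      maxT[j] <- max(abs(tp))
      tpArr <- array(0, dim = st$dim); tpArr[st$vox] <- tp
      tf <- tfce_cpp(as.numeric(tpArr), as.integer(st$dim), E, H, dh)
      maxTfce[j] <- max(abs(tf))
    }

    denom <- if (exhaustive) nIter else nIter + 1
    add <- if (exhaustive) 0 else 1
    pVox <- (add + vapply(abs(obs$t), function(x) sum(maxT >= x),
                          numeric(1))) / denom
    pTfceVec <- (add + vapply(abs(tfceObs[st$vox]),
                              function(x) sum(maxTfce >= x),
                              numeric(1))) / denom

    pVoxArr <- array(NA_real_, dim = st$dim); pVoxArr[st$vox] <- pVox
    pTfceArr <- array(NA_real_, dim = st$dim); pTfceArr[st$vox] <- pTfceVec
    tMapArr <- array(NA_real_, dim = st$dim); tMapArr[st$vox] <- obs$t
    tfceOut <- array(NA_real_, dim = st$dim)
    tfceOut[st$vox] <- tfceObs[st$vox]

    sig <- !is.na(pVoxArr) & pVoxArr < alpha & pTfceArr < alpha
    sigPos <- sig & !is.na(tMapArr) & tMapArr > 0
    sigNeg <- sig & !is.na(tMapArr) & tMapArr < 0

    new("InferenceResult",
        tMap = new("StatMap", data = tMapArr, affine = st$affine,
                   label = "t_contrast", df = as.numeric(df)),
        tfceMap = new("StatMap", data = tfceOut, affine = st$affine,
                      label = "tfce", df = NA_real_),
        fweP = new("StatMap", data = pVoxArr, affine = st$affine,
                   label = "fwe_p_voxel", df = NA_real_),
        fwePTfce = new("StatMap", data = pTfceArr, affine = st$affine,
                       label = "fwe_p_tfce", df = NA_real_),
        sigMaskPos = sigPos, sigMaskNeg = sigNeg,
        nPermutations = as.integer(nIter), seed = as.integer(seed))
  })
}
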