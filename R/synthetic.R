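## Synthetic study generator: atlases, smooth template maps, multi-subject
## cohorts with template-shaped group effects, three-condition drug
## sessions and clinical scores with known ground truth.
##
## Signal model: within region r, every voxel time series is
##   x_v(t) = w * g_r(t) + (1 - w) * e_v(t),
## a mix of a shared low-pass-filtered regional signal g_r and i.i.d. voxel
## noise e_v. The mixing weight w in [0, 1] is the ground-truth local
## synchronization dial (true LCOR is monotone in w); case-group subjects
## have w shifted by effectSize * standardized template value per region.

#' Construct a SyntheticSpec
#'
#' @param gridShape integer triple of grid dimensions.
#' @param voxelSizeMm isotropic voxel size in mm.
#' @param nRegions number of atlas regions.
#' @param nPerGroup subjects per group.
#' @param nTimepoints timepoints per run.
#' @param effectMapName template whose shape the case-group effect follows
#'   (NA = no effect).
#' @param effectSize mixing-weight shift per unit of standardized template
#'   value (negative = case-group reduction where the template is high).
#' @param noiseSd voxel noise standard deviation.
#' @param nSites number of acquisition sites (additive region offsets).
#' @param seed integer root seed.
#' @return a SyntheticSpec.
#' @export
syntheticSpec <- function(gridShape = c(16L, 16L, 16L), voxelSizeMm = 3,
                          nRegions = 40L, nPerGroup = 20L,
                          nTimepoints = 120L, effectMapName = NA_character_,
                          effectSize = 0, noiseSd = 1, nSites = 2L,
                          seed = 1L) {
  new("SyntheticSpec", gridShape = as.integer(gridShape),
      voxelSizeMm = voxelSizeMm, nRegions = as.integer(nRegions),
      nPerGroup = as.integer(nPerGroup), nTimepoints = as.integer(nTimepoints),
      effectMapName = as.character(effectMapName), effectSize = effectSize,
      noiseSd = noiseSd, nSites = as.integer(nSites), seed = as.integer(seed))
}

## 6-neighbour linear indices of linear voxel indices on a grid; returns a
## matrix with NA outside the grid.
neighbours6 <- function(lin, dm) {
  idx <- arrayInd(lin, dm)
  out <- matrix(NA_integer_, nrow = length(lin), ncol = 6)
  k <- 0L
  for (ax in 1:3) for (dlt in c(-1L, 1L)) {
    k <- k + 1L
    nb <- idx
    nb[, ax] <- nb[, ax] + dlt
    ok <- nb[, ax] >= 1L & nb[, ax] <= dm[ax]
    out[ok, k] <- (nb[ok, 3] - 1L) * dm[1] * dm[2] +
      (nb[ok, 2] - 1L) * dm[1] + nb[ok, 1]
  }
  out
}

## Ellipsoidal brain-like mask inscribed in the grid.
brainMask <- function(dm) {
  ctr <- (dm + 1) / 2
  rad <- pmax((dm - 1) / 2, 1)
  idx <- voxelIndexGrid(dm)
  d <- ((idx[, 1] - ctr[1]) / rad[1])^2 + ((idx[, 2] - ctr[2]) / rad[2])^2 +
       ((idx[, 3] - ctr[3]) / rad[3])^2
  array(d <= 1, dim = dm)
}

#' Generate a contiguous synthetic parcellation
#'
#' Grows `nRegions` spatially contiguous regions from random seed voxels
#' inside an ellipsoidal brain mask (6-connected region growing with random
#' tie-breaking under the fixed seed) until every mask voxel carries
#' exactly one label in 1..nRegions; 0 is background. Region centroids are
#' the mean mm coordinates of the member voxels.
#'
#' @param spec a SyntheticSpec (seed, grid and region count are used).
#' @return a LabelAtlas.
#' @export
makeAtlas <- function(spec) {
  dm <- spec@gridShape
  mask <- brainMask(dm)
  vox <- which(mask)
  K <- spec@nRegions
  if (K > length(vox))
    stop("invalid spec: nRegions (", K, ") exceeds mask voxel count (",
         length(vox), ")")
  affine <- centredAffine(dm, spec@voxelSizeMm)
  withSeed(spec@seed, "atlas", {
    lab <- integer(prod(dm))
    seeds <- sample(vox, K)
    lab[seeds] <- seq_len(K)
    frontier <- as.list(seeds)
    active <- rep(TRUE, K)
    nLeft <- length(vox) - K
    while (nLeft > 0 && any(active)) {
      for (r in sample(which(active))) {
        fr <- frontier[[r]]
        nb <- neighbours6(fr, dm)
        cand <- nb[!is.na(nb)]
        cand <- unique(cand[mask[cand] & lab[cand] == 0L])
        if (length(cand) == 0) {
          active[r] <- FALSE
          next
        }
        pick <- if (length(cand) == 1) cand else sample(cand, 1)
        lab[pick] <- r
        ## prune frontier voxels with no remaining unassigned neighbours
        fr <- c(fr, pick)
        nb2 <- neighbours6(fr, dm)
        keep <- vapply(seq_along(fr), function(i) {
          nn <- nb2[i, ]
          nn <- nn[!is.na(nn)]
          any(mask[nn] & lab[nn] == 0L)
        }, logical(1))
        frontier[[r]] <- fr[keep]
        if (length(frontier[[r]]) == 0) active[r] <- FALSE
        nLeft <- nLeft - 1L
        if (nLeft == 0) break
      }
    }
    ## isolated leftovers (disconnected mask pockets): nearest seed wins
    left <- vox[lab[vox] == 0L]
    if (length(left)) {
      xyzL <- voxelToWorld(arrayInd(left, dm), affine)
      xyzS <- voxelToWorld(arrayInd(seeds, dm), affine)
      for (i in seq_along(left)) {
        d2 <- colSums((t(xyzS) - xyzL[i, ])^2)
        lab[left[i]] <- which.min(d2)
      }
    }
    labArr <- array(lab, dim = dm)
    idx <- arrayInd(vox, dm)
    xyz <- voxelToWorld(idx, affine)
    cen <- apply(xyz, 2, function(col) rowsum(col, lab[vox]))
    cnt <- as.numeric(table(lab[vox]))
    cen <- cen / cnt
    regions <- data.frame(id = seq_len(K),
                          name = sprintf("R%03d", seq_len(K)),
                          x = cen[, 1], y = cen[, 2], z = cen[, 3])
    new("LabelAtlas", labels = labArr, affine = affine, regions = regions)
  })
}

## Square root of a squared-exponential covariance over centroids; used to
## sample smooth Gaussian random fields at the region level.
grfFactor <- function(centroids, lengthScaleMm) {
  D2 <- as.matrix(stats::dist(centroids))^2
  K <- exp(-D2 / (2 * max(lengthScaleMm, 1e-6)^2))
  e <- eigen(K, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(vals), length(vals))
}

rescaleRange <- function(x, lo, hi) {
  rng <- range(x)
  if (diff(rng) < 1e-12) return(rep((lo + hi) / 2, length(x)))
  lo + (x - rng[1]) / diff(rng) * (hi - lo)
}

#' Generate smooth region-level template maps
#'
#' Samples `nMaps` spatially smooth Gaussian random fields at the atlas
#' region centroids (squared-exponential covariance with the given length
#' scale) and min-max rescales each to [0, 100]. With `nMaps = 16` the maps
#' carry the canonical receptor/transporter names. A smooth gray-matter
#' probability map in [0, 1] is generated alongside.
#'
#' @param atlas a LabelAtlas.
#' @param nMaps number of template maps.
#' @param smoothnessMm Gaussian-field length scale in mm (near 0 gives
#'   spatially independent values).
#' @param seed integer seed.
#' @return a TemplateMapSet.
#' @export
makeTemplateMaps <- function(atlas, nMaps = 16L, smoothnessMm = 20,
                             seed = 1L) {
  if (nMaps < 1) stop("nMaps must be >= 1")
  reg <- regionTable(atlas)
  cen <- as.matrix(reg[, c("x", "y", "z")])
  R <- nrow(cen)
  L <- grfFactor(cen, smoothnessMm)
  withSeed(seed, "templates", {
    raw <- L %*% matrix(rnorm(R * (nMaps + 1L)), R)
    maps <- apply(raw[, seq_len(nMaps), drop = FALSE], 2, rescaleRange,
                  lo = 0, hi = 100)
    colnames(maps) <- if (nMaps == 16L) canonicalTemplateNames() else
      sprintf("template%02d", seq_len(nMaps))
    gm <- rescaleRange(raw[, nMaps + 1L], 0.25, 0.95)
    new("TemplateMapSet", maps = maps, gm = gm,
        regionIds = as.integer(reg$id), centroids = cen)
  })
}

## Shared low-pass regional signals: white noise filtered with a short
## moving average, then standardized per region.
smoothSignals <- function(R, nt, window = 3L) {
  G <- matrix(rnorm(R * (nt + window - 1L)), R)
  G <- t(apply(G, 1, function(g)
    as.numeric(stats::filter(g, rep(1 / window, window), sides = 1))))
  G <- G[, window:(nt + window - 1L), drop = FALSE]
  G <- G - rowMeans(G)
  G / sqrt(rowSums(G^2) / (nt - 1))
}

## One subject's 4D volume from per-region mixing weights.
subjectVolume <- function(wRegions, labArr, mask, nt, noiseSd) {
  dm <- dim(labArr)
  nv <- prod(dm)
  R <- length(wRegions)
  G <- smoothSignals(R, nt)
  lab <- as.vector(labArr)
  X <- matrix(rnorm(nv * nt, sd = noiseSd), nv, nt)
  inb <- lab > 0L
  w <- wRegions[lab[inb]]
  X[inb, ] <- w * G[lab[inb], , drop = FALSE] + (1 - w) * X[inb, ]
  array(X, dim = c(dm, nt))
}

clampWeights <- function(w) pmin(pmax(w, 0.05), 0.95)

#' Generate a synthetic case-control cohort
#'
#' Each subject is a FunctionalImage built from the mixing-weight model
#' (see the module header): per-region weights combine a baseline of 0.5,
#' a subject-level offset, region-level jitter, an additive site offset,
#' and -- for case subjects -- `effectSize` times the standardized template
#' the SyntheticSpec names. Covariates (group, age, sex, FIQ, motion, site) are
#' drawn from documented distributions; the realized weight matrix is kept
#' as ground truth.
#'
#' @param spec a SyntheticSpec.
#' @param atlas a LabelAtlas from [makeAtlas()].
#' @param templates a TemplateMapSet (required when `spec` names an
#'   effect template).
#' @return a Cohort.
#' @export
makeCohort <- function(spec, atlas, templates = NULL) {
  R <- nrow(regionTable(atlas))
  n <- 2L * spec@nPerGroup
  nt <- spec@nTimepoints
  tnorm <- rep(0, R)
  if (!is.na(spec@effectMapName) && nzchar(spec@effectMapName)) {
    if (is.null(templates) ||
        !spec@effectMapName %in% templateNames(templates))
      stop("effectMapName '", spec@effectMapName, "' not in templates")
    tv <- templates@maps[, spec@effectMapName]
    tnorm <- (tv - mean(tv)) / sd(tv)
  }
  withSeed(spec@seed, "cohort", {
    group <- rep(c("control", "case"), each = spec@nPerGroup)
    sexP <- ifelse(group == "case", 0.15, 0.25)
    covariates <- data.frame(
      subject = sprintf("S%03d", seq_len(n)),
      group = group,
      age = round(stats::rlnorm(n, log(16), 0.35), 1),
      sex = ifelse(rbinom(n, 1, sexP) == 1, "F", "M"),
      fiq = round(rnorm(n, 108, 15), 1),
      motion_translation_mm = round(pmin(abs(rnorm(n, 0.9, 0.6)) + 0.05, 6), 2),
      motion_rotation_deg = round(pmin(abs(rnorm(n, 0.9, 0.6)) + 0.05, 6), 2),
      site = sprintf("site%d", sample.int(spec@nSites, n, replace = TRUE)),
      stringsAsFactors = FALSE)
    siteOff <- matrix(rnorm(spec@nSites * R, sd = 0.03), spec@nSites, R)
    w <- matrix(0.5, n, R)
    w <- w + rnorm(n, sd = 0.04) +
      matrix(rnorm(n * R, sd = 0.02), n, R) +
      siteOff[as.integer(factor(covariates$site,
                                sprintf("site%d", seq_len(spec@nSites)))), ,
              drop = FALSE]
    w <- w + outer(as.numeric(group == "case"), spec@effectSize * tnorm)
    w <- clampWeights(w)
    images <- lapply(seq_len(n), function(s)
      new("FunctionalImage",
          data = subjectVolume(w[s, ], atlas@labels, NULL, nt, spec@noiseSd),
          affine = atlas@affine, trSeconds = 2))
    new("Cohort", images = images, covariates = covariates,
        groundTruth = list(w = w, effectMapName = spec@effectMapName,
                           effectSize = spec@effectSize,
                           siteOffsets = siteOff))
  })
}

#' Generate a within-subject three-condition drug dataset
#'
#' Each subject contributes one run per condition (two drugs and placebo)
#' sharing a subject-level baseline weight profile; condition `c` shifts
#' the mixing weight of every voxel inside mask `m` by
#' `conditionEffects[[c]][m]`.
#'
#' @param nSubjects number of subjects (>= 3).
#' @param atlas a LabelAtlas.
#' @param masks named list of two disjoint logical 3D arrays.
#' @param conditionEffects named list (one element per drug condition) of
#'   numeric vectors named after `masks`; placebo is implicit zero.
#' @param spec a SyntheticSpec (seed, timepoints, noise are used).
#' @return a DrugDataset.
#' @export
makeDrugSessions <- function(nSubjects, atlas, masks, conditionEffects,
                             spec) {
  if (nSubjects < 3) stop("need at least 3 subjects")
  if (length(masks) != 2 || is.null(names(masks)))
    stop("masks must be a named list of two arrays")
  if (any(masks[[1]] & masks[[2]])) stop("masks must be disjoint")
  conds <- c(names(conditionEffects), "placebo")
  R <- nrow(regionTable(atlas))
  dm <- dim(atlas@labels)
  nt <- spec@nTimepoints
  lab <- as.vector(atlas@labels)
  withSeed(spec@seed, "drug", {
    wBase <- clampWeights(
      matrix(0.5 + rnorm(nSubjects, sd = 0.04), nSubjects, R) +
        matrix(rnorm(nSubjects * R, sd = 0.02), nSubjects, R))
    images <- lapply(seq_len(nSubjects), function(s) {
      runs <- lapply(conds, function(cn) {
        shift <- array(0, dim = dm)
        if (cn != "placebo")
          for (mn in names(masks))
            shift[masks[[mn]]] <- conditionEffects[[cn]][[mn]]
        ## voxel-level weights: regional baseline plus the mask shift
        wVox <- rep(NA_real_, prod(dm))
        inb <- lab > 0L
        wVox[inb] <- clampWeights(wBase[s, lab[inb]] + as.vector(shift)[inb])
        G <- smoothSignals(R, nt)
        X <- matrix(rnorm(prod(dm) * nt, sd = spec@noiseSd), prod(dm), nt)
        X[inb, ] <- wVox[inb] * G[lab[inb], , drop = FALSE] +
          (1 - wVox[inb]) * X[inb, ]
        new("FunctionalImage", data = array(X, dim = c(dm, nt)),
            affine = atlas@affine, trSeconds = 2)
      })
      names(runs) <- conds
      runs
    })
    new("DrugDataset", images = images, conditions = conds, masks = masks,
        groundTruth = list(wBase = wBase,
                           conditionEffects = conditionEffects))
  })
}

#' Generate clinical symptom scores coupled to co-localization strength
#'
#' `score = coupling * standardized(strength) + sqrt(1 - coupling^2) * noise`,
#' affinely mapped to plausible symptom-scale ranges (total plus three
#' subscores: communication, reciprocal social interaction, stereotyped
#' behaviors/restricted interests) and rounded to integer scale points.
#' `coupling = 0` gives scores independent of strength.
#'
#' @param cohort the Cohort whose case subjects receive scores.
#' @param strength numeric vector of per-case co-localization strengths.
#' @param coupling correlation dial in [-1, 1].
#' @param seed integer seed.
#' @return data.frame subject, total, communication, rsi, sbri.
#' @export
makeClinicalScores <- function(cohort, strength, coupling, seed = 1L) {
  stopifnot(abs(coupling) <= 1)
  cases <- cohort@covariates$subject[cohort@covariates$group == "case"]
  if (length(strength) != length(cases))
    stop("need one strength value per case subject")
  z <- as.numeric(colStd(matrix(strength)))
  withSeed(seed, "clinical_scores", {
    latent <- function() coupling * z +
      sqrt(1 - coupling^2) * rnorm(length(z))
    clampRound <- function(x, lo, hi) pmin(pmax(round(x), lo), hi)
    data.frame(subject = cases,
               total = clampRound(12 + 4 * latent(), 0, 30),
               communication = clampRound(4 + 2.5 * latent(), 0, 10),
               rsi = clampRound(7.5 + 3 * latent(), 0, 14),
               sbri = clampRound(2.5 + 2 * latent(), 0, 8),
               stringsAsFactors = FALSE)
  })
}
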