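test_that("atlas generation tiles the mask with contiguous regions", {
  ## two regions on a 4x4x4 grid: labels partition the mask exactly
  sp2 <- syntheticSpec(gridShape = c(4, 4, 4), nRegions = 2, nPerGroup = 2,
                       nTimepoints = 20, seed = 7)
  at2 <- makeAtlas(sp2)
  mask <- neurocoloc:::brainMask(c(4L, 4L, 4L))
  labs <- imgData(at2)
  expect_true(all(labs[mask] %in% 1:2))
  expect_true(all(labs[!mask] == 0))
  expect_true(all(1:2 %in% labs))

  ## determinism: same spec and seed give identical label volumes
  expect_identical(imgData(makeAtlas(sp2)), labs)

  ## regions grown from seeds are 6-connected
  at <- tinyAtlas()
  for (id in regionTable(at)$id)
    expect_true(regionIsConnected(at, id))

  ## region count exceeding the mask errors
  expect_error(makeAtlas(syntheticSpec(gridShape = c(3, 3, 3),
                                       nRegions = 27, seed = 1)),
               "invalid spec")
})

test_that("a 119-region atlas has correct brute-force centroids", {
  sp <- syntheticSpec(gridShape = c(24, 24, 24), nRegions = 119,
                      nPerGroup = 2, seed = 3)
  at <- makeAtlas(sp)
  reg <- regionTable(at)
  expect_identical(nrow(reg), 119L)
  labs <- imgData(at)
  expect_true(all(tabulate(labs[labs > 0], 119) > 0))
  aff <- imgAffine(at)
  for (id in c(1L, 37L, 119L)) {
    vox <- which(labs == id)
    idx <- arrayInd(vox, dim(labs))
    xyz <- t(aff %*% t(cbind(idx - 1, 1)))[, 1:3, drop = FALSE]
    expect_equal(unlist(reg[reg$id == id, c("x", "y", "z")]),
                 colMeans(xyz), tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("template maps have the canonical names, range and smoothness", {
  at <- tinyAtlas(tinySpec(gridShape = c(12L, 12L, 12L), nRegions = 30L))
  tm <- makeTemplateMaps(at, nMaps = 16, smoothnessMm = 15, seed = 2)
  expect_identical(templateNames(tm), canonicalTemplateNames())
  expect_true(all(apply(tm@maps, 2, min) == 0))
  expect_true(all(apply(tm@maps, 2, max) == 100))
  expect_true(all(tm@gm >= 0 & tm@gm <= 1))

  ## near-zero length scale: values at neighbouring centroids decorrelate
  cen <- tm@centroids
  nn <- apply(as.matrix(dist(cen)) + diag(Inf, nrow(cen)), 1, which.min)
  lag1 <- function(smooth, seed) {
    m <- makeTemplateMaps(at, nMaps = 1, smoothnessMm = smooth, seed = seed)
    v <- m@maps[, 1]
    cor(v, v[nn])
  }
  roughMean <- mean(vapply(1:50, function(s) lag1(0.01, s), numeric(1)))
  smoothMean <- mean(vapply(1:50, function(s) lag1(15, s), numeric(1)))
  expect_lt(abs(roughMean), 0.1)
  expect_gt(smoothMean, 0.5)

  ## maps from independent seeds are uncorrelated on average
  rho <- vapply(1:200, function(s) {
    m1 <- makeTemplateMaps(at, 1, 15, seed = s)@maps[, 1]
    m2 <- makeTemplateMaps(at, 1, 15, seed = 10000 + s)@maps[, 1]
    cor(m1, m2, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rho)), 0.05)
})

test_that("cohorts are deterministic with calibrated null and effect", {
  at <- tinyAtlas(tinySpec(gridShape = c(6L, 6L, 6L), nRegions = 8L))
  tm <- makeTemplateMaps(at, nMaps = 16, smoothnessMm = 12, seed = 4)

  ## bit-identical regeneration under a fixed seed
  spE <- tinySpec(gridShape = c(6L, 6L, 6L), nRegions = 8L, nPerGroup = 4L,
                  nTimepoints = 20L, effectMapName = "NMDA",
                  effectSize = -0.1, seed = 99L)
  c1 <- makeCohort(spE, at, tm)
  c2 <- makeCohort(spE, at, tm)
  expect_identical(cohortImages(c1)[[3]]@data, cohortImages(c2)[[3]]@data)
  expect_identical(cohortCovariates(c1), cohortCovariates(c2))

  ## null effect: per-region group difference in the true synchronization
  ## weight rejects at ~alpha
  rej <- vapply(1:300, function(i) {
    sp0 <- tinySpec(gridShape = c(6L, 6L, 6L), nRegions = 8L,
                    nPerGroup = 10L, nTimepoints = 20L, seed = 1000L + i)
    co <- makeCohort(sp0, at, tm)
    w <- co@groundTruth$w
    grp <- cohortCovariates(co)$group
    t.test(w[grp == "case", 1], w[grp == "control", 1])$p.value < 0.05
  }, logical(1))
  ci <- binom.test(sum(rej), 300, 0.05)$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])

  ## injected negative NMDA effect: the group difference profile is
  ## negatively rank-correlated with the NMDA template
  hits <- vapply(1:100, function(i) {
    sp <- tinySpec(gridShape = c(6L, 6L, 6L), nRegions = 8L,
                   nPerGroup = 10L, nTimepoints = 20L,
                   effectMapName = "NMDA", effectSize = -0.1,
                   seed = 2000L + i)
    co <- makeCohort(sp, at, tm)
    w <- co@groundTruth$w
    grp <- cohortCovariates(co)$group
    diffW <- colMeans(w[grp == "case", ]) - colMeans(w[grp == "control", ])
    cor(diffW, tm@maps[, "NMDA"], method = "spearman") < 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("drug sessions share baselines and respect mask effects", {
  at <- tinyAtlas(tinySpec(gridShape = c(8L, 8L, 8L), nRegions = 10L))
  labs <- imgData(at)
  m1 <- labs > 0 & labs <= 3
  m2 <- labs > 3 & labs <= 6
  masks <- list(decrease = m1, increase = m2)
  sp <- tinySpec(gridShape = c(8L, 8L, 8L), nTimepoints = 20L, seed = 5L)

  dd <- makeDrugSessions(6, at, masks,
                         list(ketamine = c(decrease = -0.2, increase = 0),
                              midazolam = c(decrease = 0, increase = 0.2)),
                         sp)
  expect_identical(dd@conditions, c("ketamine", "midazolam", "placebo"))
  expect_identical(length(dd@images), 6L)
  ## determinism
  dd2 <- makeDrugSessions(6, at, masks, dd@groundTruth$conditionEffects, sp)
  expect_identical(dd@images[[2]]$placebo@data, dd2@images[[2]]$placebo@data)

  ## overlapping masks error
  expect_error(makeDrugSessions(6, at, list(a = m1, b = m1),
                                list(ketamine = c(a = 0, b = 0),
                                     midazolam = c(a = 0, b = 0)), sp),
               "disjoint")
})

test_that("clinical scores couple to strength at the requested level", {
  at <- tinyAtlas(tinySpec(gridShape = c(4L, 4L, 4L), nRegions = 2L))
  tm <- makeTemplateMaps(at, nMaps = 1, smoothnessMm = 5, seed = 1)
  sp <- tinySpec(gridShape = c(4L, 4L, 4L), nRegions = 2L,
                 nPerGroup = 200L, nTimepoints = 20L, seed = 8L)
  co <- makeCohort(sp, at, tm)
  set.seed(81)
  strength <- rnorm(200)

  ## determinism
  s1 <- makeClinicalScores(co, strength, 0.5, seed = 11)
  s2 <- makeClinicalScores(co, strength, 0.5, seed = 11)
  expect_identical(s1, s2)

  ## coupling 0.9 at n = 200 recovers r within 0.1
  s9 <- makeClinicalScores(co, strength, 0.9, seed = 12)
  expect_lt(abs(cor(s9$total, strength) - 0.9), 0.1)

  ## coupling 0: mean correlation ~0 across 200 independent draws
  r0 <- vapply(1:200, function(i)
    cor(makeClinicalScores(co, strength, 0, seed = 100 + i)$total,
        strength), numeric(1))
  expect_lt(abs(mean(r0)), 0.05)

  expect_error(makeClinicalScores(co, strength[-1], 0.5, 1), "one strength")
})
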