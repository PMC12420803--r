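test_that("partial Spearman reduces correctly in its limit cases", {
  set.seed(41)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30); g <- runif(30)

  ## constant covariate: exactly the ordinary Spearman rho
  expect_equal(partialSpearman(x, y, rep(1, 30)),
               cor(x, y, method = "spearman"), tolerance = 1e-12)

  ## y identical to the covariate: fully explained, partial rho = 0
  expect_lt(abs(partialSpearman(x, g, g)), 1e-10)

  ## hand-sized vectors match the normal-equations-on-ranks oracle
  x6 <- c(3.2, 1.1, 5.0, 2.2, 4.4, 0.7)
  y6 <- c(2.0, 2.0, 6.1, 1.0, 5.5, 3.3)   # includes a tie
  g6 <- c(0.9, 0.3, 0.8, 0.2, 0.7, 0.4)
  expect_equal(partialSpearman(x6, y6, g6),
               partialSpearmanOracle(x6, y6, g6), tolerance = 1e-12)

  ## missing regions are dropped pairwise
  x7 <- c(x6, NA); y7 <- c(y6, 1); g7 <- c(g6, 0.5)
  expect_equal(partialSpearman(x7, y7, g7),
               partialSpearmanOracle(x6, y6, g6), tolerance = 1e-12)

  ## degenerate inputs error
  expect_error(partialSpearman(rep(1, 10), rnorm(10), runif(10)),
               "constant")
  expect_error(partialSpearman(1:3, 1:3, 1:3), "at least 4")
})

test_that("surrogates rearrange source values and match its variogram", {
  atlas <- tinyAtlas(tinySpec(gridShape = c(14L, 14L, 14L), nRegions = 40L))
  cen <- as.matrix(regionTable(atlas)[, c("x", "y", "z")])
  tm <- makeTemplateMaps(atlas, nMaps = 1, smoothnessMm = 18, seed = 5)
  src <- templateMap(tm, "template01")

  s <- generateSurrogates(src, cen, 120, seed = 9)
  ## every surrogate is an exact rearrangement of the source values
  for (i in c(1, 60, 120))
    expect_equal(sort(s@maps[i, ]), sort(src@values), tolerance = 1e-12)

  ## variogram match: mean absolute relative deviation below 25%
  expect_lt(s@variogramFitError, 0.25)

  ## determinism under a fixed seed
  s2 <- generateSurrogates(src, cen, 120, seed = 9)
  expect_identical(s@maps, s2@maps)

  ## degenerate geometry errors
  expect_error(generateSurrogates(src, cen * 0, 100, seed = 1),
               "degenerate")
})

test_that("coloc test statistics follow their defining identities", {
  set.seed(43)
  n <- 60
  cen <- matrix(rnorm(n * 3, sd = 25), ncol = 3)
  y <- regionVector(rnorm(n), name = "tmpl")
  gmc <- regionVector(rep(0.5, n), name = "gm")
  surr <- generateSurrogates(y, cen, 199, seed = 3)

  ## contrast identical to the template, constant gm: rho 1, minimal p
  ## (the saturated rho is clipped before atanh, with a warning)
  expect_warning(res <- colocTest(regionVector(y@values), y, gmc, surr),
                 "clipped")
  expect_equal(res@rho, 1, tolerance = 1e-12)
  expect_equal(res@pPerm, 1 / 200)
  expect_identical(res@dfReport, as.integer(n - 2))
  expect_lte(res@ci95[1], res@ci95[2])
  expect_equal(tanh(res@fisherZ), res@rho, tolerance = 1e-9)

  ## map similarity is the same machinery with a contrast as template
  sim <- suppressWarnings(
    mapSimilarity(regionVector(y@values, name = "a"), y, gmc, surr))
  expect_equal(sim@rho, res@rho)
  expect_identical(sim@templateName, "tmpl")
})

test_that("Fisher z round trip is exact for correlations below 1", {
  r <- seq(-0.999, 0.999, length.out = 41)
  expect_equal(tanh(atanh(r)), r, tolerance = 1e-12)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bhFdr(0.031), 0.031)                      # m = 1 unchanged
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(44)
  p <- runif(25)
  expect_true(all(bhFdr(p) >= p))
  expect_true(all(bhFdr(p) <= 1))
  expect_error(bhFdr(c(0.5, 0)), "0, 1")
})

test_that("Fisher's method matches its closed forms", {
  expect_equal(fisherCombine(0.2), 0.2, tolerance = 1e-12)   # k = 1 identity
  x <- 0.05 * 0.05
  expect_equal(fisherCombine(c(0.05, 0.05)), x * (1 - log(x)),
               tolerance = 1e-9)
  expect_equal(fisherCombine(c(1, 1)), 1)
  expect_error(fisherCombine(c(0.5, 0)), "underflow")
})

## Minimal ColocResult builder for protocol tests.
fakeColoc <- function(name, rho, p, n = 40L)
  new("ColocResult", rho = rho, pPerm = p, fisherZ = atanh(rho),
      ci95 = sort(tanh(atanh(rho) + c(-1, 1) * 0.3)),
      dfReport = n - 2L, nRegionsUsed = n, templateName = name)

test_that("exploration/replication protocol flags, replicates, combines", {
  A <- list(fakeColoc("t1", -0.5, 0.002), fakeColoc("t2", 0.3, 0.04),
            fakeColoc("t3", 0.1, 0.60))
  B <- list(fakeColoc("t1", -0.4, 0.010), fakeColoc("t2", -0.35, 0.02),
            fakeColoc("t3", 0.2, 0.50))
  tab <- explorationReplication(A, B, alpha = 0.05)
  expect_identical(tab$flagged, c(TRUE, TRUE, FALSE))
  ## t1 replicates (same sign, p < alpha); t2 fails on the sign flip
  expect_identical(tab$replicated, c(TRUE, FALSE, FALSE))
  expect_equal(tab$p_combined[1], fisherCombine(c(0.002, 0.010)))
  ## BH runs across the flagged set only
  expect_equal(tab$p_fdr[tab$flagged],
               bhFdr(tab$p_combined[tab$flagged]))
  expect_true(tab$selected[1])
  expect_false(any(tab$selected[-1]))
  ## unflagged templates never enter stage 2
  expect_true(all(is.na(tab$p_B[!tab$flagged])))
})
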