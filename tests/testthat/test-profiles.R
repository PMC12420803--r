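fakeResult <- function(name, rho)
  new("ColocResult", rho = rho, pPerm = 0.5, fisherZ = atanh(rho),
      ci95 = c(-1, 1), dfReport = 38L, nRegionsUsed = 40L,
      templateName = name)

test_that("profiles assemble in canonical order regardless of input order", {
  nms <- canonicalTemplateNames()
  set.seed(51)
  rho <- runif(16, -0.4, 0.4)
  res <- Map(fakeResult, nms, rho)
  prof <- buildProfile(res, "autism")
  expect_identical(names(prof@z), nms)
  expect_equal(unname(prof@z), atanh(rho), tolerance = 1e-12)

  ## a single rho of 0.5 lands at atanh(0.5) = 0.5493
  expect_equal(unname(buildProfile(res, "x")@z[which(rho == rho[3])[1]]),
               atanh(rho[3]), tolerance = 1e-12)

  ## permuted input order yields the identical profile
  prof2 <- buildProfile(res[sample(16)], "autism")
  expect_identical(prof2@z, prof@z)

  ## missing and duplicated templates are errors
  expect_error(buildProfile(res[-1], "x",
                            templateOrder = nms), "missing")
  expect_error(buildProfile(c(res, res[1]), "x"), "duplicate")
})

test_that("profile correlation uses the 16-template df convention", {
  set.seed(52)
  z1 <- rnorm(16); z2 <- 0.7 * z1 + rnorm(16, sd = 0.4)
  p1 <- new("NeurochemProfile", z = setNames(z1, canonicalTemplateNames()),
            contrastLabel = "a")
  p2 <- new("NeurochemProfile", z = setNames(z2, canonicalTemplateNames()),
            contrastLabel = "b")
  pc <- profileCorrelation(p1, p2)
  expect_identical(unname(pc$df), 14L)
  ## direct covariance-formula oracle
  oracle <- sum((z1 - mean(z1)) * (z2 - mean(z2))) /
    sqrt(sum((z1 - mean(z1))^2) * sum((z2 - mean(z2))^2))
  expect_equal(pc$r, oracle, tolerance = 1e-12)
  ## identical (non-constant) profiles correlate at exactly 1
  expect_equal(profileCorrelation(p1, p1)$r, 1, tolerance = 1e-12)
  ## zero-variance profile errors
  pz <- new("NeurochemProfile",
            z = setNames(rep(0.2, 16), canonicalTemplateNames()),
            contrastLabel = "flat")
  expect_error(profileCorrelation(p1, pz), "zero-variance")
})

test_that("subject z-maps standardize against the control group", {
  ## hand example: controls {0,1,2}, case value 3 -> z = 2
  controls <- matrix(c(0, 1, 2), ncol = 1)
  cases <- matrix(3, ncol = 1)
  expect_equal(subjectZmaps(cases, controls)[1, 1], 2)

  ## case equal to the control mean -> all-zero z-map
  set.seed(53)
  C <- matrix(rnorm(60), 6)
  z0 <- subjectZmaps(matrix(colMeans(C), 1), C)
  expect_true(all(abs(z0) < 1e-12))

  ## a control scored against its own group statistics is ~N(0, 1)
  Cbig <- matrix(rnorm(30 * 400), 30)
  zc <- subjectZmaps(Cbig[1, , drop = FALSE], Cbig[-1, , drop = FALSE])
  expect_lt(abs(mean(zc)), 0.15)
  expect_lt(abs(sd(zc) - 1), 0.15)

  ## zero control sd becomes missing with a warning
  C2 <- C; C2[, 3] <- 1
  expect_warning(z2 <- subjectZmaps(matrix(rnorm(10), 1), C2), "zero")
  expect_true(is.na(z2[1, 3]))
  expect_error(subjectZmaps(cases, controls[1:2, , drop = FALSE]),
               "3 controls")
})

test_that("subject-level co-localization is antisymmetric and finite", {
  set.seed(54)
  z <- rnorm(40); tmpl <- rnorm(40); gm <- runif(40)
  a <- subjectColoc(z, regionVector(tmpl), regionVector(gm))
  b <- subjectColoc(-z, regionVector(tmpl), regionVector(gm))
  expect_equal(a, -b, tolerance = 1e-10)

  ## saturation: identical maps with constant gm clip rather than blow up
  expect_warning(zz <- subjectColoc(tmpl, regionVector(tmpl),
                                    regionVector(rep(1, 40))), "clipped")
  expect_true(is.finite(zz))

  ## null maps give near-zero strength on average
  m <- mean(replicate(200, {
    subjectColoc(rnorm(30), regionVector(tmpl[1:30]),
                 regionVector(gm[1:30]))
  }))
  expect_lt(abs(m), 0.05)
})

test_that("symptom correlations respect missingness and degeneracy", {
  set.seed(55)
  n <- 238
  z <- rnorm(n)
  sc <- 0.4 * z + rnorm(n, sd = 0.9)
  subjZ <- data.frame(subject = sprintf("S%03d", 1:n), NMDA = z)
  scores <- data.frame(subject = sprintf("S%03d", 1:n), total = sc)
  res <- symptomCorrelation(subjZ, scores, "NMDA", "total")
  expect_identical(unname(res$df), 236L)
  expect_equal(res$r, cor(z, sc), tolerance = 1e-12)

  ## missing scores are dropped from n and df
  scores$total[1:38] <- NA
  res2 <- symptomCorrelation(subjZ, scores, "NMDA", "total")
  expect_identical(res2$n, 200L)
  expect_identical(unname(res2$df), 198L)

  ## constant scores error
  scores$total <- 3
  expect_error(symptomCorrelation(subjZ, scores, "NMDA", "total"),
               "constant")
})
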