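## Study orchestration: synthetic study generation, motion exclusion, and
## the full exploration -> replication -> meta-combination -> drug ->
## individual-level workflow driven by one config and one root seed.

#' Construct (or read) a study configuration
#'
#' All randomness flows from `seed` through named per-stage sub-streams.
#' The synthetic sections describe the two cohorts and the drug dataset;
#' analysis parameters mirror the study defaults (alpha 0.05, 1000
#' permutations and surrogates, LCOR kernel 25 mm, smoothing 6 mm, motion
#' exclusion at 3 mm translation / 3 degrees rotation) and can be reduced
#' for small runs.
#'
#' @param seed root seed.
#' @param outDir output directory (NULL = no files written).
#' @param gridShape,voxelSizeMm,nRegions,nPerGroup,nTimepoints,noiseSd,nSites
#'   synthetic cohort geometry, passed to [syntheticSpec()].
#' @param nTemplates number of template maps (16 = canonical names).
#' @param templateSmoothnessMm template Gaussian-field length scale.
#' @param effectMapName,effectSize injected case-control effect.
#' @param nDrugSubjects subjects in the drug dataset.
#' @param drugEffects named list of per-mask weight shifts per drug.
#' @param scoreCoupling coupling of symptom scores to the true individual
#'   co-localization strength.
#' @param alpha,nPerm,nSurr inference parameters.
#' @param kernelFwhmMm,smoothFwhmMm LCOR parameters.
#' @param translationMm,rotationDeg motion exclusion thresholds.
#' @param dropFirstVolumes,noSmoothing,noGmRegression,alternateAtlas
#'   robustness switches.
#' @param writeVolumes also write NIfTI volumes (t-maps, masks, atlas).
#' @return a StudyConfig (validated list).
#' @export
studyConfig <- function(seed = 1L, outDir = NULL,
                        gridShape = c(12L, 12L, 12L), voxelSizeMm = 4,
                        nRegions = 40L, nPerGroup = 20L, nTimepoints = 60L,
                        noiseSd = 1, nSites = 2L, nTemplates = 16L,
                        templateSmoothnessMm = 18,
                        effectMapName = NA_character_, effectSize = 0,
                        nDrugSubjects = 12L,
                        drugEffects = list(
                          ketamine = c(decrease = -0.12, increase = 0),
                          midazolam = c(decrease = 0, increase = 0.12)),
                        scoreCoupling = 0.3,
                        alpha = 0.05, nPerm = 200L, nSurr = 200L,
                        kernelFwhmMm = 25, smoothFwhmMm = 6,
                        translationMm = 3, rotationDeg = 3,
                        dropFirstVolumes = 0L, noSmoothing = FALSE,
                        noGmRegression = FALSE, alternateAtlas = FALSE,
                        writeVolumes = FALSE) {
  stopifnot(alpha > 0, alpha < 1, nPerm >= 10, nSurr >= 10)
  cfg <- as.list(environment())
  class(cfg) <- "StudyConfig"
  cfg
}

#' @rdname studyConfig
#' @param path YAML file with studyConfig fields.
#' @export
readStudyConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(studyConfig, vals)
}

#' Exclude subjects by head motion
#'
#' Subjects strictly exceeding either threshold (translation > 3 mm or
#' rotation > 3 degrees by default) are removed; values equal to a
#' threshold are kept.
#'
#' @param covariates data.frame with motion_translation_mm and
#'   motion_rotation_deg columns.
#' @param translationMm,rotationDeg exclusion thresholds.
#' @return the retained covariate rows (attribute "excluded" holds the
#'   dropped subject ids).
#' @export
excludeByMotion <- function(covariates, translationMm = 3, rotationDeg = 3) {
  need <- c("motion_translation_mm", "motion_rotation_deg")
  if (!all(need %in% names(covariates)))
    stop("missing motion column(s): ",
         paste(setdiff(need, names(covariates)), collapse = ", "))
  drop <- covariates$motion_translation_mm > translationMm |
          covariates$motion_rotation_deg > rotationDeg
  if (all(drop)) stop("no subjects remain after motion exclusion")
  kept <- covariates[!drop, , drop = FALSE]
  attr(kept, "excluded") <- covariates$subject[drop]
  kept
}

#' Generate a complete synthetic study
#'
#' Builds the shared atlas and template set, two independent cohorts
#' (exploration and replication) with the same injected effect, a
#' three-condition drug dataset whose drug effects act inside
#' template-shaped voxel masks, and clinical scores coupled to each case
#' subject's true co-localization strength.
#'
#' @param config a [studyConfig()].
#' @return list with atlas, templates, cohortA, cohortB, drug, scoresA,
#'   scoresB (and atlasAlt when the alternate-atlas switch is on).
#' @export
synthesizeStudy <- function(config) {
  baseSpec <- function(label, nPerGroup = config$nPerGroup)
    syntheticSpec(gridShape = config$gridShape,
                  voxelSizeMm = config$voxelSizeMm,
                  nRegions = config$nRegions, nPerGroup = nPerGroup,
                  nTimepoints = config$nTimepoints,
                  effectMapName = config$effectMapName,
                  effectSize = config$effectSize, noiseSd = config$noiseSd,
                  nSites = config$nSites,
                  seed = deriveSeed(config$seed, label))
  atlas <- makeAtlas(baseSpec("atlas"))
  templates <- makeTemplateMaps(atlas, nMaps = config$nTemplates,
                                smoothnessMm = config$templateSmoothnessMm,
                                seed = deriveSeed(config$seed, "templates"))
  cohortA <- makeCohort(baseSpec("cohortA"), atlas, templates)
  cohortB <- makeCohort(baseSpec("cohortB"), atlas, templates)

  ## drug masks mimic decrease/increase significance masks with distinct
  ## neurochemical geographies: the "decrease" mask sits in the top
  ## quartile of the effect template (the regions the case-control deficit
  ## lives in), the "increase" mask in the top quartile of a second
  ## template, minus any overlap
  nms <- templateNames(templates)
  ref <- if (!is.na(config$effectMapName) && nzchar(config$effectMapName))
    config$effectMapName else nms[1]
  ref2 <- if ("GABAa" %in% setdiff(nms, ref)) "GABAa" else
    setdiff(nms, ref)[1]
  topQuartile <- function(nm) {
    m <- broadcastRegions(templateMap(templates, nm), atlas)@data
    !is.na(m) & m >= stats::quantile(m[!is.na(m)], 0.75)
  }
  masks <- list(decrease = topQuartile(ref))
  masks$increase <- topQuartile(ref2) & !masks$decrease
  drug <- makeDrugSessions(config$nDrugSubjects, atlas, masks,
                           config$drugEffects, baseSpec("drug", 2L))

  trueStrength <- function(cohort) {
    w <- cohort@groundTruth$w
    grp <- cohort@covariates$group
    tv <- templates@maps[, ref]
    dev <- sweep(w[grp == "case", , drop = FALSE], 2,
                 colMeans(w[grp == "control", , drop = FALSE]))
    apply(dev, 1, function(d) cor(d, tv, method = "spearman"))
  }
  scoresA <- makeClinicalScores(cohortA, trueStrength(cohortA),
                                config$scoreCoupling,
                                deriveSeed(config$seed, "scoresA"))
  scoresB <- makeClinicalScores(cohortB, trueStrength(cohortB),
                                config$scoreCoupling,
                                deriveSeed(config$seed, "scoresB"))
  out <- list(atlas = atlas, templates = templates, cohortA = cohortA,
              cohortB = cohortB, drug = drug, scoresA = scoresA,
              scoresB = scoresB)
  if (isTRUE(config$alternateAtlas)) {
    altSpec <- baseSpec("atlasAlt")
    altSpec@nRegions <- as.integer(max(10L, round(config$nRegions * 1.5)))
    out$atlasAlt <- makeAtlas(altSpec)
  }
  out
}

## Write a data.frame deterministically as TSV.
writeTsv <- function(df, dir, file) {
  if (is.null(dir)) return(invisible(NULL))
  write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
              row.names = FALSE)
}

colocToRow <- function(r) data.frame(
  template = r@templateName, rho = r@rho, p_perm = r@pPerm,
  fisher_z = r@fisherZ, ci_low = r@ci95[1], ci_high = r@ci95[2],
  df = r@dfReport, n_regions = r@nRegionsUsed, stringsAsFactors = FALSE)

## LCOR maps for a subject list under the config's parameters.
cohortLcor <- function(images, atlas, config) {
  if (config$dropFirstVolumes > 0)
    images <- lapply(images, function(im) {
      nt <- dim(im@data)[4]
      new("FunctionalImage",
          data = im@data[, , , (config$dropFirstVolumes + 1):nt,
                         drop = FALSE],
          affine = im@affine, trSeconds = im@trSeconds)
    })
  mask <- atlas@labels > 0
  params <- lcorParams(kernelFwhmMm = config$kernelFwhmMm,
                       smoothFwhmMm = if (config$noSmoothing) 0 else
                         config$smoothFwhmMm,
                       mask = mask)
  images <- lapply(images, function(im) {
    conf <- if (config$noGmRegression) confoundSet() else {
      Y <- matrix(im@data, ncol = dim(im@data)[4])
      confoundSet(matrix(colMeans(Y[as.vector(mask), , drop = FALSE],
                                  na.rm = TRUE)), "tissue_mean")
    }
    regressConfounds(im, conf)
  })
  computeLcorMany(images, params)
}

## Per-template surrogate sets under one root seed.
templateSurrogates <- function(templates, nSurr, seed) {
  cen <- templates@centroids
  sets <- lapply(templateNames(templates), function(nm)
    generateSurrogates(templateMap(templates, nm), cen, nSurr,
                       seed = deriveSeed(seed, paste0("surr_", nm))))
  names(sets) <- templateNames(templates)
  sets
}

## Co-localization of one contrast RegionVector against every template.
colocAllTemplates <- function(contrast, templates, surrSets) {
  gm <- grayMatterMap(templates)
  res <- lapply(templateNames(templates), function(nm)
    colocTest(contrast, templateMap(templates, nm), gm, surrSets[[nm]]))
  names(res) <- templateNames(templates)
  res
}

#' Run the full study workflow
#'
#' Executes, in order: motion-based subject exclusion; LCOR per subject;
#' exploration-cohort voxel-wise GLM with permutation/TFCE inference;
#' co-localization of the exploration t-map with every template;
#' replication-cohort t-map and co-localization; the two-stage
#' exploration/replication protocol with Fisher combination and BH
#' correction; cross-cohort map similarity; drug-condition delta tests in
#' the exploration significance masks; drug contrast co-localizations and
#' neurochemical profile correlations; and individual z-map
#' co-localizations correlated with symptom scores (raw and BH-adjusted).
#' Every stage logs its seed and counts; any failure aborts naming the
#' stage, leaving earlier outputs in place.
#'
#' @param config a [studyConfig()].
#' @param data optional pre-generated [synthesizeStudy()] output.
#' @return a StudyReport list of result tables and inference objects.
#' @export
runStudy <- function(config, data = NULL) {
  if (!is.null(config$outDir) &&
      !dir.exists(config$outDir))
    dir.create(config$outDir, recursive = TRUE)
  logLines <- character(0)
  t0 <- proc.time()[["elapsed"]]
  logStage <- function(stage, ...) {
    msg <- sprintf("stage=%s seed=%d elapsed_s=%.1f %s", stage, config$seed,
                   proc.time()[["elapsed"]] - t0,
                   paste(sprintf("%s=%s", names(list(...)), list(...)),
                         collapse = " "))
    logLines <<- c(logLines, msg)
    if (!is.null(config$outDir))
      writeLines(logLines, file.path(config$outDir, "study_log.txt"))
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("study stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (is.null(data)) data <- stage("synthesize", synthesizeStudy(config))
  atlas <- data$atlas; templates <- data$templates
  if (!is.null(config$outDir)) {
    yaml::write_yaml(unclass(config)[!vapply(config, is.function,
                                             logical(1))],
                     file.path(config$outDir, "config_echo.yaml"))
    if (isTRUE(config$writeVolumes)) {
      writeVolume(atlas, file.path(config$outDir, "atlas.nii.gz"))
      writeRegionTable(atlas, file.path(config$outDir, "atlas_regions.tsv"))
    }
  }

  report <- list(config = config)

  keptA <- stage("motion_exclusion", excludeByMotion(
    cohortCovariates(data$cohortA), config$translationMm, config$rotationDeg))
  keptB <- stage("motion_exclusion", excludeByMotion(
    cohortCovariates(data$cohortB), config$translationMm, config$rotationDeg))
  idxA <- match(keptA$subject, cohortCovariates(data$cohortA)$subject)
  idxB <- match(keptB$subject, cohortCovariates(data$cohortB)$subject)
  logStage("motion_exclusion", kept_A = nrow(keptA), kept_B = nrow(keptB))
  writeTsv(keptA, config$outDir, "covariates_A.tsv")
  writeTsv(keptB, config$outDir, "covariates_B.tsv")

  lcorA <- stage("lcor", cohortLcor(cohortImages(data$cohortA)[idxA],
                                    atlas, config))
  lcorB <- stage("lcor", cohortLcor(cohortImages(data$cohortB)[idxB],
                                    atlas, config))
  logStage("lcor", subjects = length(lcorA) + length(lcorB))

  designA <- buildDesign(keptA)
  infA <- stage("glm_inference", permutationInference(
    lcorA, designA, nPerm = config$nPerm, alpha = config$alpha,
    seed = deriveSeed(config$seed, "glm_A")))
  report$inferenceA <- infA
  logStage("glm_inference", n_perm = infA@nPermutations,
           sig_pos = sum(infA@sigMaskPos), sig_neg = sum(infA@sigMaskNeg))
  tMapB <- stage("glm_replication",
                 fitVoxelwiseGlm(lcorB, buildDesign(keptB)))
  if (!is.null(config$outDir) && isTRUE(config$writeVolumes)) {
    writeVolume(infA@tMap, file.path(config$outDir, "tmap_A.nii.gz"))
    writeVolume(tMapB, file.path(config$outDir, "tmap_B.nii.gz"))
  }

  surrSets <- stage("surrogates", templateSurrogates(
    templates, config$nSurr, deriveSeed(config$seed, "surrogates")))
  contrastA <- parcellate(infA@tMap, atlas)
  contrastA@name <- "t_contrast_A"
  contrastB <- parcellate(tMapB, atlas)
  contrastB@name <- "t_contrast_B"
  colocA <- stage("coloc_exploration",
                  colocAllTemplates(contrastA, templates, surrSets))
  colocB <- stage("coloc_replication",
                  colocAllTemplates(contrastB, templates, surrSets))
  report$colocA <- do.call(rbind, lapply(colocA, colocToRow))
  report$colocB <- do.call(rbind, lapply(colocB, colocToRow))
  writeTsv(report$colocA, config$outDir, "coloc_A.tsv")
  writeTsv(report$colocB, config$outDir, "coloc_B.tsv")

  report$replication <- stage("replication_protocol",
    explorationReplication(colocA, colocB, alpha = config$alpha))
  writeTsv(report$replication, config$outDir, "replication.tsv")
  logStage("replication_protocol",
           flagged = sum(report$replication$flagged),
           replicated = sum(report$replication$replicated),
           selected = sum(report$replication$selected))

  gm <- grayMatterMap(templates)
  surrB <- stage("map_similarity", generateSurrogates(
    contrastB, templates@centroids, config$nSurr,
    seed = deriveSeed(config$seed, "similarity")))
  simAB <- stage("map_similarity",
                 mapSimilarity(contrastA, contrastB, gm, surrB))
  report$similarityAB <- colocToRow(simAB)
  writeTsv(report$similarityAB, config$outDir, "similarity_AB.tsv")

  ## ---- pharmacological dataset -------------------------------------
  drugConds <- setdiff(data$drug@conditions, "placebo")
  lcorDrug <- stage("lcor_drug", lapply(data$drug@images, function(runs)
    setNames(cohortLcor(runs, atlas, config), names(runs))))
  masksA <- list(decrease = infA@sigMaskNeg, increase = infA@sigMaskPos)
  deltaRows <- list()
  for (drugName in drugConds) {
    for (mn in names(masksA)) {
      if (!any(masksA[[mn]])) next
      means <- extractMaskMeans(lcorDrug, masksA[[mn]])
      dr <- deltaTest(means[, drugName], means[, "placebo"],
                      direction = if (mn == "decrease") "less" else "greater",
                      maskLabel = mn)
      deltaRows[[paste(drugName, mn, sep = "_")]] <- data.frame(
        drug = drugName, mask = mn, t = dr@t, df = dr@df,
        p_one_sided = dr@pOneSided, cohen_d = dr@cohenD,
        ci_low = dr@ciOneSided[1], ci_high = dr@ciOneSided[2],
        stringsAsFactors = FALSE)
    }
  }
  report$deltaTests <- if (length(deltaRows)) do.call(rbind, deltaRows)
    else data.frame()
  if (!is.null(config$outDir))
    jsonlite::write_json(report$deltaTests,
                         file.path(config$outDir, "delta_tests.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  logStage("delta_tests", rows = nrow(report$deltaTests))

  ## drug contrast maps: paired one-sample t on drug-minus-placebo maps
  drugColoc <- list()
  drugContrasts <- list()
  for (drugName in drugConds) {
    diffs <- lapply(lcorDrug, function(runs)
      new("StatMap", data = runs[[drugName]]@data - runs[["placebo"]]@data,
          affine = atlas@affine, label = paste0(drugName, "_minus_placebo"),
          df = NA_real_))
    tm <- stage("drug_contrast", fitVoxelwiseGlm(
      diffs, designMatrix(matrix(1, length(diffs), 1), 1)))
    rv <- parcellate(tm, atlas)
    rv@name <- paste0("t_", drugName)
    drugContrasts[[drugName]] <- rv
    drugColoc[[drugName]] <- stage("drug_coloc",
      colocAllTemplates(rv, templates, surrSets))
    tbl <- do.call(rbind, lapply(drugColoc[[drugName]], colocToRow))
    tbl$p_fdr <- bhFdr(tbl$p_perm)
    report[[paste0("coloc_", drugName)]] <- tbl
    writeTsv(tbl, config$outDir, paste0("coloc_", drugName, ".tsv"))
  }

  ## ---- neurochemical profiles --------------------------------------
  profiles <- list(
    cohortA = buildProfile(colocA, "cohortA"),
    cohortB = buildProfile(colocB, "cohortB"))
  for (drugName in drugConds)
    profiles[[drugName]] <- buildProfile(drugColoc[[drugName]], drugName)
  report$profiles <- data.frame(
    template = names(profiles[[1]]@z),
    do.call(cbind, lapply(profiles, function(p) unname(p@z))),
    stringsAsFactors = FALSE)
  writeTsv(report$profiles, config$outDir, "profiles.tsv")

  pairs <- list(c("cohortA", "cohortB"))
  for (drugName in drugConds)
    pairs <- c(pairs, list(c("cohortA", drugName), c("cohortB", drugName)))
  if (length(drugConds) == 2)
    pairs <- c(pairs, list(drugConds))
  profCor <- do.call(rbind, lapply(pairs, function(pp) {
    pc <- profileCorrelation(profiles[[pp[1]]], profiles[[pp[2]]])
    data.frame(profile_a = pp[1], profile_b = pp[2], r = pc$r, p = pc$p,
               ci_low = pc$ci95[1], ci_high = pc$ci95[2], df = pc$df,
               stringsAsFactors = FALSE)
  }))
  report$profileCorrelations <- profCor
  writeTsv(profCor, config$outDir, "profile_correlations.tsv")
  logStage("profiles", pairs = nrow(profCor))

  ## ---- individual-level analysis -----------------------------------
  report$symptomCorrelations <- stage("individual", {
    regMatA <- t(vapply(lcorA, function(m) parcellate(m, atlas)@values,
                        numeric(nrow(regionTable(atlas)))))
    isCase <- keptA$group == "case"
    zm <- subjectZmaps(regMatA[isCase, , drop = FALSE],
                       regMatA[!isCase, , drop = FALSE])
    selTmpl <- report$replication$template[report$replication$selected]
    if (length(selTmpl) == 0) data.frame() else {
      subjZ <- data.frame(subject = keptA$subject[isCase],
                          stringsAsFactors = FALSE)
      for (nm in selTmpl)
        subjZ[[nm]] <- apply(zm, 1, function(zr)
          subjectColoc(regionVector(zr, regionIds(gm)),
                       templateMap(templates, nm), gm))
      report$subjectColoc <- subjZ
      writeTsv(subjZ, config$outDir, "subject_coloc_A.tsv")
      rows <- list()
      for (nm in selTmpl) for (sc in c("total", "communication", "rsi",
                                       "sbri")) {
        sr <- symptomCorrelation(subjZ, data$scoresA, nm, sc)
        rows[[paste(nm, sc)]] <- data.frame(
          template = nm, score = sc, r = sr$r, p = sr$p,
          ci_low = sr$ci95[1], ci_high = sr$ci95[2], df = sr$df, n = sr$n,
          stringsAsFactors = FALSE)
      }
      tbl <- do.call(rbind, rows)
      tbl$p_fdr <- bhFdr(tbl$p)
      tbl
    }
  })
  writeTsv(report$symptomCorrelations, config$outDir,
           "symptom_correlations.tsv")
  logStage("individual", rows = nrow(report$symptomCorrelations))

  ## optional robustness: alternate parcellation of the exploration stage
  if (isTRUE(config$alternateAtlas) && !is.null(data$atlasAlt)) {
    report$colocA_alt <- stage("alternate_atlas", {
      tmplAlt <- makeTemplateMaps(data$atlasAlt, nMaps = config$nTemplates,
                                  smoothnessMm = config$templateSmoothnessMm,
                                  seed = deriveSeed(config$seed, "templates"))
      surrAlt <- templateSurrogates(tmplAlt, config$nSurr,
                                    deriveSeed(config$seed, "surr_alt"))
      cA <- parcellate(infA@tMap, data$atlasAlt)
      do.call(rbind, lapply(colocAllTemplates(cA, tmplAlt, surrAlt),
                            colocToRow))
    })
    writeTsv(report$colocA_alt, config$outDir, "coloc_A_alt.tsv")
  }

  logStage("done")
  report$log <- logLines
  class(report) <- "StudyReport"
  report
}
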