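## Central S4 data containers. All volumes live on an explicit grid
## (array + 4x4 voxel-to-mm affine); region-level statistics use the
## RegionVector as their common currency.

#' FunctionalImage: a 4D voxel time-series grid
#'
#' Carrier for one subject's (preprocessed or synthetic) BOLD run:
#' a 4D array indexed (x, y, z, t), a voxel-to-world affine and the
#' repetition time in seconds.
#'
#' @slot data 4D numeric array (x, y, z, t).
#' @slot affine 4x4 invertible voxel-to-mm matrix (0-based voxel indices).
#' @slot trSeconds positive repetition time in seconds.
#' @export
setClass("FunctionalImage",
  representation(data = "array", affine = "matrix", trSeconds = "numeric"))

setValidity("FunctionalImage", function(object) {
  d <- dim(object@data)
  if (length(d) != 4) return("data must be a 4D array (x, y, z, t)")
  if (d[4] < 2) return("need at least 2 timepoints")
  if (!all(dim(object@affine) == c(4, 4))) return("affine must be 4x4")
  if (abs(det(object@affine)) < 1e-12) return("affine must be invertible")
  if (length(object@trSeconds) != 1 || object@trSeconds <= 0)
    return("trSeconds must be a positive scalar")
  TRUE
})

#' StatMap: a 3D statistical or parameter map
#'
#' @slot data 3D numeric array.
#' @slot affine 4x4 voxel-to-mm matrix.
#' @slot label free-text label, e.g. "LCOR" or "t_contrast".
#' @slot df degrees of freedom carried with t-maps (NA when not applicable).
#' @export
setClass("StatMap",
  representation(data = "array", affine = "matrix", label = "character",
                 df = "numeric"),
  prototype(label = "map", df = NA_real_))

setValidity("StatMap", function(object) {
  if (length(dim(object@data)) != 3) return("data must be a 3D array")
  if (!all(dim(object@affine) == c(4, 4))) return("affine must be 4x4")
  if (!is.na(object@df) && object@df < 0) return("df must be nonnegative")
  TRUE
})

#' LabelAtlas: an integer-labelled parcellation
#'
#' Nonzero voxel values are region ids; 0 is background. The region table
#' fixes the canonical region order used by every RegionVector.
#'
#' @slot labels 3D integer array.
#' @slot affine 4x4 voxel-to-mm matrix.
#' @slot regions data.frame with columns id, name, x, y, z (centroid, mm).
#' @export
setClass("LabelAtlas",
  representation(labels = "array", affine = "matrix", regions = "data.frame"))

setValidity("LabelAtlas", function(object) {
  if (length(dim(object@labels)) != 3) return("labels must be a 3D array")
  if (any(object@labels < 0)) return("labels must be nonnegative")
  ids <- object@regions$id
  if (anyDuplicated(ids)) return("region ids must be unique")
  used <- setdiff(unique(as.vector(object@labels)), 0)
  if (!all(used %in% ids)) return("every nonzero label must appear in regions")
  if (!all(c("id", "name", "x", "y", "z") %in% names(object@regions)))
    return("regions needs columns id, name, x, y, z")
  TRUE
})

#' RegionVector: per-region scalar values aligned to an atlas
#'
#' @slot values numeric values, one per region (NA marks missing regions).
#' @slot regionIds integer region ids in atlas region-table order.
#' @slot name label of the quantity (e.g. a template name).
#' @export
setClass("RegionVector",
  representation(values = "numeric", regionIds = "integer", name = "character"),
  prototype(name = "values"))

setValidity("RegionVector", function(object) {
  if (length(object@values) != length(object@regionIds))
    return("values and regionIds must have equal length")
  if (anyDuplicated(object@regionIds)) return("regionIds must be unique")
  TRUE
})

#' TemplateMapSet: smooth region-level template maps plus a gray-matter map
#'
#' @slot maps regions x maps numeric matrix, columns named by template.
#' @slot gm gray-matter probability per region, in [0, 1].
#' @slot regionIds region ids (atlas order).
#' @slot centroids regions x 3 matrix of centroid mm coordinates.
#' @export
setClass("TemplateMapSet",
  representation(maps = "matrix", gm = "numeric", regionIds = "integer",
                 centroids = "matrix"))

setValidity("TemplateMapSet", function(object) {
  if (nrow(object@maps) != length(object@regionIds))
    return("maps rows must match regionIds")
  if (is.null(colnames(object@maps)) || anyDuplicated(colnames(object@maps)))
    return("maps must have unique column names")
  if (length(object@gm) != length(object@regionIds))
    return("gm must have one value per region")
  if (any(object@gm < 0 | object@gm > 1)) return("gm must lie in [0, 1]")
  TRUE
})

#' SurrogateSet: spatial-autocorrelation-preserving null maps
#'
#' Each row is a rearrangement of the source map's values whose binned
#' variogram has been matched to the source by least squares.
#'
#' @slot maps n_surrogates x regions matrix.
#' @slot seed integer seed used.
#' @slot variogramFitError nonnegative mean absolute relative deviation
#'   between surrogate and source binned variograms.
#' @slot sourceName name of the source map.
#' @export
setClass("SurrogateSet",
  representation(maps = "matrix", seed = "integer",
                 variogramFitError = "numeric", sourceName = "character"),
  prototype(sourceName = "map"))

setValidity("SurrogateSet", function(object) {
  if (object@variogramFitError < 0) return("variogramFitError must be >= 0")
  TRUE
})

#' ColocResult: one map-vs-map partial-correlation test
#'
#' @slot rho partial Spearman correlation in [-1, 1].
#' @slot pPerm two-sided surrogate-permutation p value in (0, 1].
#' @slot fisherZ atanh(rho).
#' @slot ci95 95% confidence interval (Fisher approximation).
#' @slot dfReport reported degrees of freedom, regions used minus 2.
#' @slot nRegionsUsed complete regions entering the statistic.
#' @slot templateName template (or second-map) name.
#' @export
setClass("ColocResult",
  representation(rho = "numeric", pPerm = "numeric", fisherZ = "numeric",
                 ci95 = "numeric", dfReport = "integer",
                 nRegionsUsed = "integer", templateName = "character"))

setValidity("ColocResult", function(object) {
  if (abs(object@rho) > 1) return("rho must lie in [-1, 1]")
  if (object@pPerm <= 0 || object@pPerm > 1) return("pPerm must be in (0, 1]")
  if (length(object@ci95) != 2 || object@ci95[1] > object@ci95[2])
    return("ci95 must be an ordered pair")
  if (object@dfReport != object@nRegionsUsed - 2L)
    return("dfReport must equal nRegionsUsed - 2")
  TRUE
})

#' NeurochemProfile: Fisher-z co-localization strengths across templates
#'
#' The canonical 16-template order is fixed so profiles from different
#' contrasts are directly comparable.
#'
#' @slot z named Fisher-z vector in canonical template order.
#' @slot contrastLabel label of the contrast the profile describes.
#' @export
setClass("NeurochemProfile",
  representation(z = "numeric", contrastLabel = "character"))

setValidity("NeurochemProfile", function(object) {
  if (is.null(names(object@z)) || anyDuplicated(names(object@z)))
    return("z must be named with unique template names")
  if (any(!is.finite(object@z))) return("profile z values must be finite")
  TRUE
})

#' InferenceResult: voxel-wise permutation inference output
#'
#' @slot tMap observed t-contrast map.
#' @slot tfceMap signed TFCE transform of the t-map.
#' @slot fweP voxel-level family-wise-error p map (max-|t| null).
#' @slot fwePTfce TFCE family-wise-error p map (max-TFCE null).
#' @slot sigMaskPos,sigMaskNeg disjoint logical arrays of voxels passing
#'   both the voxel-FWE and TFCE-FWE criteria, split by contrast sign.
#' @slot nPermutations,seed bookkeeping.
#' @export
setClass("InferenceResult",
  representation(tMap = "StatMap", tfceMap = "StatMap", fweP = "StatMap",
                 fwePTfce = "StatMap", sigMaskPos = "array",
                 sigMaskNeg = "array", nPermutations = "integer",
                 seed = "integer"))

setValidity("InferenceResult", function(object) {
  pv <- object@fweP@data; pt <- object@fwePTfce@data
  if (any(pv < 0 | pv > 1, na.rm = TRUE)) return("fweP outside [0, 1]")
  if (any(pt < 0 | pt > 1, na.rm = TRUE)) return("fwePTfce outside [0, 1]")
  if (any(object@sigMaskPos & object@sigMaskNeg))
    return("positive and negative significance masks must be disjoint")
  TRUE
})

#' DeltaResult: one-sample directional test on drug-minus-placebo scores
#'
#' @slot t t statistic; @slot df degrees of freedom (n - 1).
#' @slot pOneSided one-sided p value in the hypothesised direction.
#' @slot cohenD |mean delta| / sd(delta).
#' @slot ciOneSided one-sided 90% confidence bound pair (one side infinite).
#' @slot direction "less" or "greater".
#' @slot maskLabel which significance mask the means came from.
#' @export
setClass("DeltaResult",
  representation(t = "numeric", df = "integer", pOneSided = "numeric",
                 cohenD = "numeric", ciOneSided = "numeric",
                 direction = "character", maskLabel = "character"),
  prototype(maskLabel = "mask"))

setValidity("DeltaResult", function(object) {
  if (!object@direction %in% c("less", "greater"))
    return("direction must be 'less' or 'greater'")
  if (object@pOneSided <= 0 || object@pOneSided >= 1)
    return("pOneSided must be in (0, 1)")
  if (length(object@ciOneSided) != 2 || !any(is.infinite(object@ciOneSided)))
    return("ciOneSided must be a pair with one infinite bound")
  TRUE
})

#' Cohort: a synthetic multi-subject case-control dataset
#'
#' @slot images list of FunctionalImage, one per subject.
#' @slot covariates data.frame: subject, group, age, sex, fiq,
#'   motion_translation_mm, motion_rotation_deg, site.
#' @slot groundTruth list with the generating quantities (mixing-weight
#'   matrix, injected effect, template name) for validation.
#' @export
setClass("Cohort",
  representation(images = "list", covariates = "data.frame",
                 groundTruth = "list"))

setValidity("Cohort", function(object) {
  if (length(object@images) != nrow(object@covariates))
    return("one covariate row per image required")
  if (!all(c("subject", "group") %in% names(object@covariates)))
    return("covariates need subject and group columns")
  TRUE
})

#' DrugDataset: a within-subject three-condition pharmacological dataset
#'
#' @slot images nested list images[[subject]][[condition]].
#' @slot conditions condition names (two drugs then placebo).
#' @slot masks named list of disjoint logical 3D arrays the condition
#'   effects act on.
#' @slot groundTruth generating quantities.
#' @export
setClass("DrugDataset",
  representation(images = "list", conditions = "character", masks = "list",
                 groundTruth = "list"))

setValidity("DrugDataset", function(object) {
  if (length(object@conditions) < 2) return("need at least two conditions")
  ok <- vapply(object@images, function(s)
    identical(sort(names(s)), sort(object@conditions)), logical(1))
  if (!all(ok)) return("every subject needs one image per condition")
  TRUE
})

#' SyntheticSpec: parameters of the synthetic study generator
#'
#' @slot gridShape integer triple of voxel grid dimensions.
#' @slot voxelSizeMm positive isotropic voxel size.
#' @slot nRegions number of atlas regions (>= 2).
#' @slot nPerGroup subjects per group (>= 2).
#' @slot nTimepoints timepoints per run (>= 20).
#' @slot effectMapName template shaping the group effect, or NA for none.
#' @slot effectSize mixing-weight shift per unit of standardized template.
#' @slot noiseSd voxel noise standard deviation.
#' @slot nSites number of acquisition sites.
#' @slot seed integer root seed.
#' @export
setClass("SyntheticSpec",
  representation(gridShape = "integer", voxelSizeMm = "numeric",
                 nRegions = "integer", nPerGroup = "integer",
                 nTimepoints = "integer", effectMapName = "character",
                 effectSize = "numeric", noiseSd = "numeric",
                 nSites = "integer", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (length(object@gridShape) != 3 || any(object@gridShape < 2))
    return("gridShape must be a triple of dimensions >= 2")
  if (object@voxelSizeMm <= 0) return("voxelSizeMm must be positive")
  if (object@nRegions < 2) return("need at least 2 regions")
  if (object@nRegions > prod(object@gridShape))
    return("nRegions exceeds voxel count")
  if (object@nPerGroup < 2) return("need at least 2 subjects per group")
  if (object@nTimepoints < 20) return("need at least 20 timepoints")
  if (object@noiseSd <= 0) return("noiseSd must be positive")
  if (object@nSites < 1) return("need at least one site")
  TRUE
})
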