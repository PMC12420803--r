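## Generics, accessors and show methods.

#' Extract the voxel data array
#' @param x a FunctionalImage, StatMap or LabelAtlas.
#' @return the underlying array.
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' @rdname imgData
#' @export
setMethod("imgData", "FunctionalImage", function(x) x@data)
#' @rdname imgData
#' @export
setMethod("imgData", "StatMap", function(x) x@data)
#' @rdname imgData
#' @export
setMethod("imgData", "LabelAtlas", function(x) x@labels)

#' Extract the voxel-to-world affine
#' @param x an image-like object.
#' @return 4x4 numeric matrix.
#' @export
setGeneric("imgAffine", function(x) standardGeneric("imgAffine"))

#' @rdname imgAffine
#' @export
setMethod("imgAffine", "FunctionalImage", function(x) x@affine)
#' @rdname imgAffine
#' @export
setMethod("imgAffine", "StatMap", function(x) x@affine)
#' @rdname imgAffine
#' @export
setMethod("imgAffine", "LabelAtlas", function(x) x@affine)

#' Region table of an atlas
#' @param x a LabelAtlas.
#' @return data.frame with id, name and centroid columns x, y, z (mm).
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' @rdname regionTable
#' @export
setMethod("regionTable", "LabelAtlas", function(x) x@regions)

#' Values of a RegionVector (named by region id)
#' @param x a RegionVector.
#' @return numeric vector.
#' @export
setGeneric("regionValues", function(x) standardGeneric("regionValues"))

#' @rdname regionValues
#' @export
setMethod("regionValues", "RegionVector", function(x) {
  v <- x@values
  names(v) <- x@regionIds
  v
})

#' Region ids of a region-level object
#' @param x a RegionVector or TemplateMapSet.
#' @return integer vector of region ids.
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @rdname regionIds
#' @export
setMethod("regionIds", "RegionVector", function(x) x@regionIds)
#' @rdname regionIds
#' @export
setMethod("regionIds", "TemplateMapSet", function(x) x@regionIds)

#' Template map accessors
#'
#' `templateNames` lists the maps in a TemplateMapSet; `templateMap` extracts
#' one as a RegionVector; `grayMatterMap` extracts the gray-matter
#' probability RegionVector.
#'
#' @param x a TemplateMapSet.
#' @param name template name.
#' @return character vector, or a RegionVector.
#' @export
setGeneric("templateNames", function(x) standardGeneric("templateNames"))
#' @rdname templateNames
#' @export
setMethod("templateNames", "TemplateMapSet", function(x) colnames(x@maps))

#' @rdname templateNames
#' @export
setGeneric("templateMap", function(x, name) standardGeneric("templateMap"))
#' @rdname templateNames
#' @export
setMethod("templateMap", "TemplateMapSet", function(x, name) {
  if (!name %in% colnames(x@maps)) stop("unknown template: ", name)
  new("RegionVector", values = unname(x@maps[, name]),
      regionIds = x@regionIds, name = name)
})

#' @rdname templateNames
#' @export
setGeneric("grayMatterMap", function(x) standardGeneric("grayMatterMap"))
#' @rdname templateNames
#' @export
setMethod("grayMatterMap", "TemplateMapSet", function(x)
  new("RegionVector", values = x@gm, regionIds = x@regionIds, name = "gm"))

#' Cohort accessors
#' @param x a Cohort or DrugDataset.
#' @return list of images, or the covariate data.frame.
#' @export
setGeneric("cohortImages", function(x) standardGeneric("cohortImages"))
#' @rdname cohortImages
#' @export
setMethod("cohortImages", "Cohort", function(x) x@images)

#' @rdname cohortImages
#' @export
setGeneric("cohortCovariates", function(x) standardGeneric("cohortCovariates"))
#' @rdname cohortImages
#' @export
setMethod("cohortCovariates", "Cohort", function(x) x@covariates)

setMethod("show", "FunctionalImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("FunctionalImage %dx%dx%d voxels, %d timepoints, TR %.3g s\n",
              d[1], d[2], d[3], d[4], object@trSeconds))
})

setMethod("show", "StatMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("StatMap '%s' %dx%dx%d%s\n", object@label, d[1], d[2], d[3],
              if (is.na(object@df)) "" else sprintf(", df = %g", object@df)))
})

setMethod("show", "LabelAtlas", function(object) {
  cat(sprintf("LabelAtlas: %d regions on a %s grid\n",
              nrow(object@regions),
              paste(dim(object@labels), collapse = "x")))
})

setMethod("show", "RegionVector", function(object) {
  cat(sprintf("RegionVector '%s' over %d regions (%d missing)\n",
              object@name, length(object@values), sum(is.na(object@values))))
})

setMethod("show", "TemplateMapSet", function(object) {
  cat(sprintf("TemplateMapSet: %d maps over %d regions\n  %s\n",
              ncol(object@maps), nrow(object@maps),
              paste(colnames(object@maps), collapse = ", ")))
})

setMethod("show", "ColocResult", function(object) {
  cat(sprintf(
    "ColocResult vs '%s': rho(%d) = %.3f, p_perm = %.4g, 95%% CI [%.3f, %.3f]\n",
    object@templateName, object@dfReport, object@rho, object@pPerm,
    object@ci95[1], object@ci95[2]))
})

setMethod("show", "NeurochemProfile", function(object) {
  cat(sprintf("NeurochemProfile '%s' over %d templates\n",
              object@contrastLabel, length(object@z)))
})

setMethod("show", "InferenceResult", function(object) {
  cat(sprintf(
    "InferenceResult: %d permutations; %d positive / %d negative significant voxels\n",
    object@nPermutations, sum(object@sigMaskPos), sum(object@sigMaskNeg)))
})

setMethod("show", "DeltaResult", function(object) {
  cat(sprintf(
    "DeltaResult [%s, %s]: T(%d) = %.3f, one-sided p = %.4g, d = %.3f\n",
    object@maskLabel, object@direction, object@df, object@t,
    object@pOneSided, object@cohenD))
})

setMethod("show", "Cohort", function(object) {
  tab <- table(object@covariates$group)
  cat(sprintf("Cohort: %d subjects (%s)\n", length(object@images),
              paste(sprintf("%s = %d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "DrugDataset", function(object) {
  cat(sprintf("DrugDataset: %d subjects x conditions %s\n",
              length(object@images), paste(object@conditions, collapse = ", ")))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: grid %s at %g mm, %d regions, %d/group, %d timepoints, seed %d\n",
    paste(object@gridShape, collapse = "x"), object@voxelSizeMm,
    object@nRegions, object@nPerGroup, object@nTimepoints, object@seed))
})
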