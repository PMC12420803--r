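## Volume input/output and the voxel <-> region interface.
## All NIfTI reading/writing goes through RNifti; internally volumes are
## plain arrays plus a voxel-to-mm affine, all held on the atlas grid.

#' Construct a FunctionalImage
#' @param data 4D numeric array (x, y, z, t).
#' @param affine 4x4 voxel-to-mm matrix; default centres the grid at the
#'   origin with `voxelSizeMm` isotropic voxels.
#' @param trSeconds repetition time in seconds.
#' @param voxelSizeMm voxel size used when `affine` is NULL.
#' @return a FunctionalImage.
#' @export
functionalImage <- function(data, affine = NULL, trSeconds = 2,
                            voxelSizeMm = 3) {
  if (is.null(affine)) affine <- centredAffine(dim(data)[1:3], voxelSizeMm)
  new("FunctionalImage", data = data, affine = affine, trSeconds = trSeconds)
}

#' Construct a StatMap
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-mm matrix (NULL = centred isotropic grid).
#' @param label map label.
#' @param df degrees of freedom (NA when not a t-map).
#' @param voxelSizeMm voxel size used when `affine` is NULL.
#' @return a StatMap.
#' @export
statMap <- function(data, affine = NULL, label = "map", df = NA_real_,
                    voxelSizeMm = 3) {
  if (is.null(affine)) affine <- centredAffine(dim(data), voxelSizeMm)
  new("StatMap", data = data, affine = affine, label = label,
      df = as.numeric(df))
}

#' Construct a RegionVector
#' @param values numeric per-region values.
#' @param regionIds integer region ids (defaults to 1..length).
#' @param name label.
#' @return a RegionVector.
#' @export
regionVector <- function(values, regionIds = seq_along(values),
                         name = "values") {
  new("RegionVector", values = as.numeric(values),
      regionIds = as.integer(regionIds), name = name)
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers over RNifti. `readFunctionalImage` reads a 4D volume (TR
#' taken from the header unless overridden); `readStatMap` and
#' `readLabelAtlas` read 3D volumes; the atlas additionally needs its region
#' table (TSV with columns id, name, x, y, z).
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param trSeconds optional TR override.
#' @param label,df passed to [statMap()].
#' @param regionTablePath TSV region table for an atlas.
#' @return the corresponding S4 object.
#' @export
readFunctionalImage <- function(path, trSeconds = NULL) {
  nii <- RNifti::readNifti(path)
  tr <- if (!is.null(trSeconds)) trSeconds else {
    pd <- attr(RNifti::niftiHeader(nii), "pixdim")
    p4 <- RNifti::niftiHeader(nii)$pixdim[5]
    if (is.na(p4) || p4 <= 0) 2 else p4
  }
  new("FunctionalImage", data = unclass(nii)[, , , , drop = FALSE],
      affine = unclass(RNifti::xform(nii))[, , drop = FALSE],
      trSeconds = tr)
}

#' @rdname readFunctionalImage
#' @export
readStatMap <- function(path, label = "map", df = NA_real_) {
  nii <- RNifti::readNifti(path)
  new("StatMap", data = unclass(nii)[, , , drop = FALSE],
      affine = unclass(RNifti::xform(nii))[, , drop = FALSE],
      label = label, df = as.numeric(df))
}

#' @rdname readFunctionalImage
#' @export
readLabelAtlas <- function(path, regionTablePath) {
  nii <- RNifti::readNifti(path)
  regions <- read.table(regionTablePath, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
  labs <- array(as.integer(round(unclass(nii))), dim = dim(nii)[1:3])
  new("LabelAtlas", labels = labs,
      affine = unclass(RNifti::xform(nii))[, , drop = FALSE],
      regions = regions)
}

#' Write a volume object to NIfTI
#'
#' @param x FunctionalImage, StatMap or LabelAtlas.
#' @param path destination file (.nii or .nii.gz).
#' @param datatype on-disk datatype ("float" by default; atlases are written
#'   as "int16"/"int32" automatically).
#' @return the path, invisibly.
#' @export
writeVolume <- function(x, path, datatype = "float") {
  if (is(x, "LabelAtlas")) {
    arr <- x@labels
    datatype <- if (max(arr) <= 32767) "int16" else "int32"
    aff <- x@affine
  } else if (is(x, "FunctionalImage")) {
    arr <- x@data; aff <- x@affine
  } else if (is(x, "StatMap")) {
    arr <- x@data; aff <- x@affine
  } else stop("unsupported object of class ", class(x))
  nii <- RNifti::asNifti(arr)
  nii <- RNifti::`sform<-`(nii, structure(aff, code = 2L))
  if (is(x, "FunctionalImage"))
    nii <- RNifti::asNifti(nii, pixdim = c(RNifti::pixdim(nii)[1:3],
                                           x@trSeconds))
  RNifti::writeNifti(nii, path, datatype = datatype)
  invisible(path)
}

#' Write an atlas region table as TSV
#' @param atlas a LabelAtlas.
#' @param path destination TSV.
#' @return the path, invisibly.
#' @export
writeRegionTable <- function(atlas, path) {
  write.table(regionTable(atlas), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Parcellate a voxel map to region means
#'
#' Averages a StatMap over the voxels of each atlas region, ignoring
#' non-finite voxels; regions with no finite voxel get NA. Map and atlas
#' must share shape and affine (tolerance 1e-5).
#'
#' @param map a StatMap.
#' @param atlas a LabelAtlas.
#' @param statistic summary statistic; only "mean" is defined.
#' @return a RegionVector in atlas region order.
#' @export
parcellate <- function(map, atlas, statistic = "mean") {
  statistic <- match.arg(statistic, "mean")
  if (!all(dim(map@data) == dim(atlas@labels)))
    stop("map and atlas grids differ in shape")
  if (!affinesEqual(map@affine, atlas@affine))
    stop("map and atlas affines differ beyond tolerance")
  ids <- atlas@regions$id
  if (length(ids) == 0) stop("empty atlas")
  lab <- as.vector(atlas@labels)
  val <- as.vector(map@data)
  keep <- lab > 0 & is.finite(val)
  sums <- rowsum(val[keep], lab[keep])
  cnts <- rowsum(rep(1, sum(keep)), lab[keep])
  out <- rep(NA_real_, length(ids))
  m <- match(as.integer(rownames(sums)), ids)
  out[m[!is.na(m)]] <- (sums / cnts)[!is.na(m)]
  new("RegionVector", values = out, regionIds = as.integer(ids),
      name = map@label)
}

#' Paint region values onto the atlas grid
#'
#' Inverse of [parcellate()] for piecewise-constant maps: every voxel of
#' region r receives `values[r]`; background voxels get NA.
#'
#' @param rv a RegionVector aligned to `atlas`.
#' @param atlas a LabelAtlas.
#' @return a StatMap on the atlas grid.
#' @export
broadcastRegions <- function(rv, atlas) {
  ids <- atlas@regions$id
  if (!identical(as.integer(ids), rv@regionIds))
    stop("RegionVector is not aligned to this atlas")
  lut <- rep(NA_real_, max(ids))
  lut[ids] <- rv@values
  lab <- atlas@labels
  out <- array(NA_real_, dim = dim(lab))
  nz <- lab > 0
  out[nz] <- lut[lab[nz]]
  new("StatMap", data = out, affine = atlas@affine, label = rv@name,
      df = NA_real_)
}

#' Nearest-neighbour resampling of a label atlas
#'
#' Transfers labels onto a target grid by nearest-neighbour lookup; labels
#' are never interpolated, so the output label set is a subset of
#' `{0} U input labels`. Regions that vanish are dropped from the table.
#'
#' @param atlas a LabelAtlas.
#' @param targetShape integer triple of the target grid.
#' @param targetAffine 4x4 voxel-to-mm matrix of the target grid.
#' @return a LabelAtlas on the target grid.
#' @export
resampleNearest <- function(atlas, targetShape, targetAffine) {
  if (abs(det(atlas@affine)) < 1e-12 || abs(det(targetAffine)) < 1e-12)
    stop("degenerate affine")
  dm <- dim(atlas@labels)
  idx <- voxelIndexGrid(as.integer(targetShape))
  xyz <- voxelToWorld(idx, targetAffine)
  src <- round(worldToVoxel(xyz, atlas@affine))
  inside <- src[, 1] >= 1 & src[, 1] <= dm[1] &
            src[, 2] >= 1 & src[, 2] <= dm[2] &
            src[, 3] >= 1 & src[, 3] <= dm[3]
  out <- integer(nrow(idx))
  lin <- (src[inside, 3] - 1) * dm[1] * dm[2] +
         (src[inside, 2] - 1) * dm[1] + src[inside, 1]
  out[inside] <- atlas@labels[lin]
  labs <- array(as.integer(out), dim = targetShape)
  kept <- atlas@regions[atlas@regions$id %in% setdiff(unique(out), 0), ,
                        drop = FALSE]
  new("LabelAtlas", labels = labs, affine = targetAffine, regions = kept)
}
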