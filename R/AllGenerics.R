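#' @rdname accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' @rdname accessors
#' @export
setGeneric("imgAffine", function(x) standardGeneric("imgAffine"))

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname accessors
#' @export
setGeneric("scaleDet", function(x) standardGeneric("scaleDet"))

#' Accessors for volume and transform objects
#'
#' \code{imgData} returns the raw 3D array, \code{imgAffine} the 4x4
#' voxel-to-world matrix, \code{voxelSpacing} the per-axis voxel size in mm,
#' \code{voxelVolume} the volume of one voxel in mm^3, and \code{scaleDet}
#' the absolute determinant of the linear part of an [AffineTransform-class]
#' (the native-to-template volume scaling factor).
#'
#' @param x a [BrainVolume-class], [LabelVolume-class] or
#'   [AffineTransform-class].
#' @return See details; scalar or vector numerics.
#' @name accessors
#' @aliases imgData imgAffine voxelSpacing voxelVolume scaleDet
NULL

setMethod("imgData", "BrainVolume", function(x) x@data)
setMethod("imgAffine", "BrainVolume", function(x) x@affine)
setMethod("voxelSpacing", "BrainVolume",
  function(x) sqrt(colSums(x@affine[1:3, 1:3]^2)))
setMethod("voxelVolume", "BrainVolume",
  function(x) abs(det(x@affine[1:3, 1:3])))
setMethod("scaleDet", "AffineTransform",
  function(x) abs(det(x@matrix[1:3, 1:3])))

setMethod("show", "BrainVolume", function(object) {
  d <- dim(object@data)
  sp <- voxelSpacing(object)
  cat(sprintf("%s: %d x %d x %d voxels, spacing %.2f x %.2f x %.2f mm\n",
              class(object), d[1], d[2], d[3], sp[1], sp[2], sp[3]))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "AffineTransform", function(object) {
  cat("AffineTransform (native world -> template world)\n")
  print(round(object@matrix, 4))
  cat(sprintf("  |det| = %.4f, converged = %s, metric = %.4f\n",
              scaleDet(object), object@converged, object@metric))
})

setMethod("show", "TemplateSpace", function(object) {
  d <- dim(object@template@data)
  cat(sprintf("TemplateSpace: %d x %d x %d grid\n", d[1], d[2], d[3]))
  cat(sprintf("  ICV %.0f mm^3, ventricle prior %.0f mm^3, %d atlas codes\n",
              sum(object@icvMask@data) * voxelVolume(object@icvMask),
              sum(object@ventriclePrior@data) *
                voxelVolume(object@ventriclePrior),
              nrow(object@codeTable)))
})

setMethod("show", "PatchLibrary", function(object) {
  cat(sprintf("PatchLibrary: %d labelled entries, candidate mask %d voxels (dilation %g)\n",
              length(object@images), sum(object@candidateMask@data),
              object@dilation))
})

setMethod("show", "SVMModel", function(object) {
  cat("SVMModel (linear, z-scored features)\n")
  w <- setNames(round(object@weights, 4), object@featureNames)
  print(w)
  cat(sprintf("  bias %.4f, C = %g, class weights = %s, n = %d pos / %d neg\n",
              object@bias, object@cost, object@classWeights,
              object@nPos, object@nNeg))
})

setMethod("show", "ConfusionMatrix", function(object) {
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2, 2,
              byrow = TRUE,
              dimnames = list(c("true bvFTD", "true other"),
                              c("pred bvFTD", "pred other")))
  print(m)
})

setMethod("show", "VentricleFeatures", function(object) {
  cat(sprintf("VentricleFeatures: total %.0f mm^3 (norm %.4f), APR %.3f (log %.3f)\n",
              object@totalVol, object@totalVolNorm, object@apr,
              object@aprLog))
  cat(sprintf("  LR frontal log %.3f, LR temporal log %.3f, ICV %.0f mm^3\n",
              object@lrFrontalLog, object@lrTemporalLog, object@icv))
})

#' @export
#' @describeIn VentricleFeatures-class flatten to a one-row data.frame with
#'   the feature-table column layout.
as.data.frame.VentricleFeatures <- function(x, ...) {
  vols <- as.list(x@compartmentVols)
  names(vols) <- paste0("vol_", names(x@compartmentVols))
  data.frame(age = x@age, sex = x@sexCode, icv_mm3 = x@icv,
             total_vv_norm = x@totalVolNorm, apr = x@apr, apr_log = x@aprLog,
             lr_frontal_log = x@lrFrontalLog,
             lr_temporal_log = x@lrTemporalLog,
             total_vol_mm3 = x@totalVol, anterior_vol_mm3 = x@anteriorVol,
             posterior_vol_mm3 = x@posteriorVol,
             vols, check.names = FALSE)
}
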