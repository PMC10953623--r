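#' @useDynLib ventmorph, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats cor cor.test t.test optim quantile rnorm runif sd
#'   setNames lm.fit predict
#' @importFrom utils read.csv write.csv modifyList
#' @importFrom graphics hist
NULL

#' 3D scalar brain volume with world-space geometry
#'
#' A 3D intensity grid together with a 4x4 affine mapping 0-based voxel
#' indices to world coordinates in mm (RAS convention: +x right, +y anterior,
#' +z superior). A voxel's world position is the position of its centre.
#'
#' @slot data 3D numeric array.
#' @slot affine 4x4 numeric matrix, voxel index (0-based) to world mm.
#' @export
setClass("BrainVolume",
  representation(data = "array", affine = "matrix"))

setValidity("BrainVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  else {
    if (abs(det(object@affine)) < 1e-12)
      msg <- c(msg, "affine must be invertible")
    sp <- sqrt(colSums(object@affine[1:3, 1:3]^2))
    if (any(sp <= 0)) msg <- c(msg, "voxel spacing must be positive")
  }
  if (any(dim(object@data) < 2L))
    msg <- c(msg, "grid must have at least 2 voxels per axis")
  if (length(msg)) msg else TRUE
})

#' Integer label volume on the same geometry as its source image
#'
#' @slot data 3D array of non-negative integers (0/1 for binary masks).
#' @slot affine as [BrainVolume-class].
#' @export
setClass("LabelVolume", contains = "BrainVolume")

setValidity("LabelVolume", function(object) {
  v <- object@data
  if (any(v < 0) || any(v != round(v)))
    return("label data must be non-negative integers")
  TRUE
})

#' World-to-world affine transform (native to stereotaxic)
#'
#' @slot matrix 4x4 matrix mapping native world mm to template world mm.
#' @slot converged logical; FALSE flags a low-confidence registration.
#' @slot metric similarity value (normalized cross-correlation) at the optimum.
#' @export
setClass("AffineTransform",
  representation(matrix = "matrix", converged = "logical", metric = "numeric"),
  prototype(converged = TRUE, metric = NA_real_))

setValidity("AffineTransform", function(object) {
  if (!all(dim(object@matrix) == c(4L, 4L)))
    return("matrix must be 4x4")
  if (abs(det(object@matrix[1:3, 1:3])) <= 0)
    return("linear part must have positive |determinant|")
  TRUE
})

#' Stereotaxic template space bundle
#'
#' Template intensity image, intracranial-volume (ICV) mask, 8-compartment
#' lobar atlas (frontal/parietal/temporal/occipital x hemisphere) with its
#' code table, and a ventricle prior mask, all on one grid. The world origin
#' sits at the anterior-commissure-like anchor so the coronal y = -12 mm
#' split plane is well defined.
#'
#' @slot template [BrainVolume-class] template intensity image.
#' @slot icvMask [LabelVolume-class] binary ICV mask.
#' @slot atlas [LabelVolume-class] lobar parcellation (codes 1..8).
#' @slot codeTable data.frame with columns code, lobe, hemisphere, name.
#' @slot ventriclePrior [LabelVolume-class] binary ventricle prior.
#' @export
setClass("TemplateSpace",
  representation(template = "BrainVolume", icvMask = "LabelVolume",
                 atlas = "LabelVolume", codeTable = "data.frame",
                 ventriclePrior = "LabelVolume"))

setValidity("TemplateSpace", function(object) {
  d <- dim(object@template@data)
  for (s in c("icvMask", "atlas", "ventriclePrior"))
    if (!identical(dim(slot(object, s)@data), d))
      return(sprintf("%s grid does not match template grid", s))
  need <- c("code", "lobe", "hemisphere")
  if (!all(need %in% names(object@codeTable)))
    return("codeTable must have columns code, lobe, hemisphere")
  TRUE
})

#' Library of labelled examples for patch-based label fusion
#'
#' @slot images list of [BrainVolume-class], intensity-normalized, on the
#'   template grid.
#' @slot labels list of [LabelVolume-class] binary ventricle labels.
#' @slot candidateMask [LabelVolume-class]: union of the library labels
#'   dilated by a ball; fusion is restricted to this mask.
#' @slot dilation dilation radius (voxels) used to build candidateMask.
#' @export
setClass("PatchLibrary",
  representation(images = "list", labels = "list",
                 candidateMask = "LabelVolume", dilation = "numeric"))

setValidity("PatchLibrary", function(object) {
  if (length(object@images) < 1L) return("library is empty")
  if (length(object@images) != length(object@labels))
    return("images and labels differ in length")
  d <- dim(object@candidateMask@data)
  for (i in seq_along(object@images)) {
    if (!identical(dim(object@images[[i]]@data), d))
      return(sprintf("library image %d is not on the template grid", i))
    if (!identical(dim(object@labels[[i]]@data), d))
      return(sprintf("library label %d is not on the template grid", i))
    if (any(!object@labels[[i]]@data %in% c(0, 1)))
      return(sprintf("library label %d is not binary", i))
  }
  TRUE
})

#' Linear support-vector classifier for the ventricular feature vector
#'
#' Stores the training z-scoring statistics and the linear decision function
#' w . z(x) + b; prediction is "compatible with bvFTD" when the score is
#' >= 0 (ties count as positive).
#'
#' @slot featureNames feature order, fixed and recorded in the model file.
#' @slot center,scale per-feature training mean and standard deviation.
#' @slot weights,bias linear decision function in z-scored space.
#' @slot cost soft-margin penalty C.
#' @slot classWeights logical; inverse-frequency class weighting used.
#' @slot nPos,nNeg training class sizes.
#' @slot seed training seed.
#' @export
setClass("SVMModel",
  representation(featureNames = "character", center = "numeric",
                 scale = "numeric", weights = "numeric", bias = "numeric",
                 cost = "numeric", classWeights = "logical",
                 nPos = "integer", nNeg = "integer", seed = "integer"))

setValidity("SVMModel", function(object) {
  k <- length(object@featureNames)
  if (length(object@center) != k || length(object@scale) != k ||
      length(object@weights) != k)
    return("center, scale and weights must match featureNames in length")
  if (any(object@scale <= 0)) return("scaling standard deviations must be > 0")
  if (length(object@bias) != 1L) return("bias must be a scalar")
  TRUE
})

#' Ventricular feature vector for one subject
#'
#' Volumes are native-space mm^3. \code{totalVolNorm} is total ventricle
#' volume divided by ICV (not log-transformed); \code{aprLog} is
#' ln(anterior/posterior) with the split at stereotaxic y = -12 mm;
#' \code{lrFrontalLog}/\code{lrTemporalLog} are ln(left/right) compartment
#' volume ratios.
#'
#' @slot compartmentVols named numeric, mm^3 per lobe x hemisphere.
#' @slot anteriorVol,posteriorVol,totalVol mm^3.
#' @slot apr,aprLog anterior-posterior ratio and its log.
#' @slot lrFrontalLog,lrTemporalLog left-right log-ratios.
#' @slot totalVolNorm total volume / ICV.
#' @slot icv intracranial volume, mm^3.
#' @slot age years.
#' @slot sexCode male = 1, female = 0.
#' @export
setClass("VentricleFeatures",
  representation(compartmentVols = "numeric", anteriorVol = "numeric",
                 posteriorVol = "numeric", totalVol = "numeric",
                 apr = "numeric", aprLog = "numeric",
                 lrFrontalLog = "numeric", lrTemporalLog = "numeric",
                 totalVolNorm = "numeric", icv = "numeric",
                 age = "numeric", sexCode = "numeric"))

#' Confusion matrix for one binary classification task
#'
#' Positive class is "compatible with bvFTD".
#'
#' @slot tp,fn,fp,tn non-negative integer counts.
#' @export
setClass("ConfusionMatrix",
  representation(tp = "integer", fn = "integer", fp = "integer",
                 tn = "integer"))

setValidity("ConfusionMatrix", function(object) {
  v <- c(object@tp, object@fn, object@fp, object@tn)
  if (any(v < 0)) return("counts must be non-negative")
  if (sum(v) == 0) return("confusion matrix is empty")
  TRUE
})
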