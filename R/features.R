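#' Split a ventricle mask at the stereotaxic coronal plane
#'
#' A voxel belongs to the anterior portion iff its centre's world
#' y-coordinate is strictly greater than the split plane (default
#' y = -12 mm); the two portions partition the mask.
#'
#' @param mask template-space binary [LabelVolume-class].
#' @param ySplit coronal split coordinate in template world mm.
#' @return list with \code{anterior} and \code{posterior}
#'   [LabelVolume-class] masks.
#' @export
splitAnteriorPosterior <- function(mask, ySplit = -12) {
  y <- worldAxis(mask, 2)
  m <- mask@data > 0
  list(anterior = labelVolume(m & y > ySplit, mask@affine),
       posterior = labelVolume(m & y <= ySplit, mask@affine))
}

#' Anterior-posterior ratio and its log
#'
#' @param anteriorVol,posteriorVol volumes in mm^3; \code{posteriorVol}
#'   must be positive.
#' @return list with \code{apr} and \code{aprLog}.
#' @export
computeAPR <- function(anteriorVol, posteriorVol) {
  if (!(posteriorVol > 0))
    stop("undefined APR: posterior volume is zero", call. = FALSE)
  apr <- anteriorVol / posteriorVol
  list(apr = apr, aprLog = log(apr))
}

# compartment display names, in feature-table column order
compartmentNames <- function(codeTable) {
  paste0(codeTable$lobe, "_", toupper(substr(codeTable$hemisphere, 1, 1)))
}

# propagate atlas labels outward (6-neighbour sweeps, deterministic axis
# order) until every voxel in `need` carries a label; approximates
# nearest-compartment assignment on the isotropic template grid
propagateLabels <- function(atlas, need) {
  a <- atlas
  d <- dim(a)
  uncovered <- function() any(need & a == 0)
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  it <- 0
  while (uncovered() && it < max(d)) {
    grown <- a
    for (s in shifts) {
      sh <- shiftArray(a, s)
      fill <- grown == 0 & sh > 0
      grown[fill] <- sh[fill]
    }
    a <- grown
    it <- it + 1
  }
  a
}

# integer shift of a 3D array, zero-filled
shiftArray <- function(x, s) {
  d <- dim(x)
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    if (s[ax] >= 0) {
      dst[[ax]] <- (1 + s[ax]):d[ax]
      src[[ax]] <- 1:(d[ax] - s[ax])
    } else {
      dst[[ax]] <- 1:(d[ax] + s[ax])
      src[[ax]] <- (1 - s[ax]):d[ax]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

#' Per-compartment ventricular volumes from the lobar atlas
#'
#' Counts mask voxels per atlas compartment. Mask voxels falling on
#' background atlas code are assigned to the nearest labelled compartment
#' (iterative 6-neighbour label propagation on the isotropic grid).
#'
#' @param mask template-space binary [LabelVolume-class].
#' @param atlas [LabelVolume-class] lobar label volume (codes 1..8).
#' @param codeTable data.frame with columns code, lobe, hemisphere.
#' @return named numeric vector of volumes (mm^3), one per compartment.
#' @export
parcellateVolumes <- function(mask, atlas, codeTable) {
  if (!identical(dim(mask@data), dim(atlas@data)))
    stop("mask and atlas grids differ", call. = FALSE)
  m <- mask@data > 0
  a <- atlas@data
  if (any(m & a == 0)) a <- propagateLabels(a, m)
  counts <- tabulate(a[m], nbins = max(codeTable$code))
  vv <- voxelVolume(mask)
  setNames(counts[codeTable$code] * vv, compartmentNames(codeTable))
}

#' Assemble the ventricular feature vector
#'
#' Applies the anterior/posterior split, the lobar parcellation, ICV
#' normalization and the log-ratio transforms. Template-space voxel counts
#' are converted to native mm^3 by dividing by the registration volume
#' scaling (\code{scaleDet}), so volumes and \code{totalVolNorm} refer to
#' the subject's own head.
#'
#' @param mask template-space binary [LabelVolume-class].
#' @param atlas [LabelVolume-class] lobar atlas.
#' @param codeTable atlas code table.
#' @param icv subject intracranial volume in mm^3 (see [estimateICV()]).
#' @param age years.
#' @param sexCode male = 1, female = 0.
#' @param scaleDet native-to-template volume scale factor (1 when the mask
#'   already lives in native space).
#' @param ySplit coronal split plane (template world mm).
#' @return A [VentricleFeatures-class].
#' @export
computeFeatures <- function(mask, atlas, codeTable, icv, age, sexCode,
                            scaleDet = 1, ySplit = -12) {
  stopifnot(icv > 0, scaleDet > 0)
  vv <- voxelVolume(mask) / scaleDet
  ap <- splitAnteriorPosterior(mask, ySplit)
  antVol <- sum(ap$anterior@data) * vv
  postVol <- sum(ap$posterior@data) * vv
  totalVol <- sum(mask@data > 0) * vv
  if (!(postVol > 0))
    stop("undefined feature: posterior compartment is empty",
         call. = FALSE)
  vols <- parcellateVolumes(mask, atlas, codeTable) / scaleDet
  fr <- vols[grep("^frontal", names(vols))]
  te <- vols[grep("^temporal", names(vols))]
  frL <- fr[grep("_L$", names(fr))]; frR <- fr[grep("_R$", names(fr))]
  teL <- te[grep("_L$", names(te))]; teR <- te[grep("_R$", names(te))]
  if (!(frR > 0) || !(frL > 0))
    stop("undefined feature: empty frontal compartment", call. = FALSE)
  if (!(teR > 0) || !(teL > 0))
    stop("undefined feature: empty temporal compartment", call. = FALSE)
  apr <- computeAPR(antVol, postVol)
  new("VentricleFeatures",
      compartmentVols = vols, anteriorVol = antVol, posteriorVol = postVol,
      totalVol = totalVol, apr = apr$apr, aprLog = apr$aprLog,
      lrFrontalLog = log(unname(frL / frR)),
      lrTemporalLog = log(unname(teL / teR)),
      totalVolNorm = totalVol / icv, icv = icv,
      age = age, sexCode = sexCode)
}

#' Quality-control thresholds
#'
#' @param minDice minimum Dice overlap with the template ventricle prior.
#' @param volRange admissible total-volume range (template-space mm^3).
#' @param maxComponents maximum number of sizeable 6-connected components.
#' @param minComponentSize voxel count above which a component counts
#'   towards \code{maxComponents}.
#' @return list of class \code{QCThresholds}.
#' @export
qcThresholds <- function(minDice = 0.3, volRange = c(5000, 250000),
                         maxComponents = 4, minComponentSize = 50) {
  structure(list(minDice = minDice, volRange = volRange,
                 maxComponents = maxComponents,
                 minComponentSize = minComponentSize),
            class = "QCThresholds")
}

#' Automated segmentation quality control
#'
#' Automated surrogate for visual QC: a segmentation fails if its Dice
#' overlap with the template ventricle prior is below threshold, its total
#' volume falls outside the admissible range, it fragments into too many
#' sizeable 6-connected components, or (when an atlas is supplied) its
#' posterior, right-frontal or right-temporal compartment is empty.
#'
#' @param mask template-space binary [LabelVolume-class].
#' @param prior template ventricle prior [LabelVolume-class].
#' @param atlas optional [LabelVolume-class] lobar atlas for the
#'   compartment-emptiness checks.
#' @param codeTable atlas code table (required with \code{atlas}).
#' @param thresholds a [qcThresholds()] list.
#' @param ySplit coronal split plane for the posterior check.
#' @return list with \code{status} ("pass"/"fail"), \code{reasons}
#'   (character), \code{overlapWithPrior} (Dice) and
#'   \code{componentCount}.
#' @export
qcSegmentation <- function(mask, prior, atlas = NULL, codeTable = NULL,
                           thresholds = qcThresholds(), ySplit = -12) {
  if (!identical(dim(mask@data), dim(prior@data)))
    stop("mask and prior grids differ", call. = FALSE)
  reasons <- character()
  dsc <- diceCoefficient(mask, prior)
  if (dsc < thresholds$minDice) reasons <- c(reasons, "low_overlap")
  vol <- segmentationVolume(mask)
  if (vol < thresholds$volRange[1] || vol > thresholds$volRange[2])
    reasons <- c(reasons, "volume_out_of_range")
  lab <- .cpp_label6(as.logical(mask@data > 0), dim(mask@data))
  ncomp <- attr(lab, "ncomp")
  big <- if (ncomp > 0)
    sum(tabulate(lab[lab > 0], nbins = ncomp) >=
          thresholds$minComponentSize) else 0L
  if (big > thresholds$maxComponents)
    reasons <- c(reasons, "fragmented")
  if (!is.null(atlas)) {
    ap <- splitAnteriorPosterior(mask, ySplit)
    if (sum(ap$posterior@data) == 0)
      reasons <- c(reasons, "empty_posterior")
    vols <- parcellateVolumes(mask, atlas, codeTable)
    if (vols[["frontal_R"]] == 0) reasons <- c(reasons, "empty_frontal_R")
    if (vols[["temporal_R"]] == 0) reasons <- c(reasons, "empty_temporal_R")
  }
  list(status = if (length(reasons)) "fail" else "pass",
       reasons = reasons, overlapWithPrior = dsc, componentCount = big)
}
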