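#' Patch-based label fusion parameter set
#'
#' @param patchRadius patch half-width in voxels (1 gives 3^3 patches).
#' @param searchRadius search-window half-width in voxels (4 gives 9^3).
#' @param preselectionThreshold minimum luminance-contrast structural
#'   similarity between the target and a library patch for the latter to
#'   enter the weighted vote.
#' @param bandwidthFloor small positive constant added to the minimum patch
#'   distance when forming the adaptive kernel bandwidth h^2.
#' @param dilation ball radius (voxels) used when building the candidate
#'   mask from the union of library labels.
#' @param decisionThreshold fused-vote cutoff; a vote exactly at the
#'   threshold counts as foreground.
#' @return list of class \code{FusionParams}.
#' @export
fusionParams <- function(patchRadius = 1, searchRadius = 4,
                         preselectionThreshold = 0.95,
                         bandwidthFloor = 1e-4, dilation = 3,
                         decisionThreshold = 0.5) {
  stopifnot(patchRadius >= 1, searchRadius >= patchRadius,
            decisionThreshold > 0, decisionThreshold < 1,
            bandwidthFloor > 0, dilation >= 0)
  structure(list(patchRadius = as.integer(patchRadius),
                 searchRadius = as.integer(searchRadius),
                 preselectionThreshold = preselectionThreshold,
                 bandwidthFloor = bandwidthFloor,
                 dilation = dilation,
                 decisionThreshold = decisionThreshold),
            class = "FusionParams")
}

#' Build a patch library from labelled template-space pairs
#'
#' @param pairs list of \code{list(image =, label =)} entries, all on the
#'   template grid and intensity-normalized the same way the targets will
#'   be.
#' @param d dilation radius (voxels) for the candidate mask: the union of
#'   all library labels dilated by a Euclidean ball of radius \code{d}.
#' @return A [PatchLibrary-class].
#' @export
buildLibrary <- function(pairs, d = 3) {
  if (length(pairs) < 2) stop("need at least 2 labelled pairs",
                              call. = FALSE)
  ref <- dim(pairs[[1]]$image@data)
  imgs <- vector("list", length(pairs))
  labs <- vector("list", length(pairs))
  uni <- array(FALSE, ref)
  for (i in seq_along(pairs)) {
    im <- pairs[[i]]$image
    lb <- pairs[[i]]$label
    if (!identical(dim(im@data), ref) || !identical(dim(lb@data), ref))
      stop(sprintf("library entry %d is not on the template grid", i),
           call. = FALSE)
    imgs[[i]] <- im
    labs[[i]] <- lb
    uni <- uni | (lb@data > 0)
  }
  cand <- .cpp_dilate_ball(as.logical(uni), ref, d)
  new("PatchLibrary", images = imgs, labels = labs,
      candidateMask = labelVolume(array(as.numeric(cand), ref),
                                  pairs[[1]]$image@affine),
      dilation = d)
}

#' Segment the lateral ventricles by patch-based label fusion
#'
#' For every voxel inside the candidate mask, library patches within the
#' search window are compared against the patch around the target voxel.
#' Patches failing the luminance-contrast similarity preselection are
#' discarded; surviving patches are weighted
#' \eqn{w_i = \exp(-d_i / h^2)} with the squared intensity patch distance
#' \eqn{d_i} and the adaptive bandwidth \eqn{h^2 = \min_i d_i + \epsilon}.
#' The fused vote is the weighted mean of the library centre-voxel labels;
#' if every patch is rejected the vote falls back to the unweighted mean of
#' the window's centre labels. Voxels outside the candidate mask get label
#' 0 and confidence 0.
#'
#' @param target intensity-normalized [BrainVolume-class] on the template
#'   grid.
#' @param lib a [PatchLibrary-class].
#' @param params a [fusionParams()] list.
#' @return list with \code{mask} ([LabelVolume-class], vote >= decision
#'   threshold) and \code{confidence} ([BrainVolume-class], the fused vote
#'   in [0, 1]).
#' @export
segmentVentricles <- function(target, lib, params = fusionParams()) {
  stopifnot(inherits(params, "FusionParams"))
  if (length(lib@images) == 0) stop("empty patch library", call. = FALSE)
  d <- dim(target@data)
  if (!identical(d, dim(lib@candidateMask@data)))
    stop("target is not on the library's template grid", call. = FALSE)
  vote <- .cpp_patch_fusion(
    as.numeric(target@data),
    lapply(lib@images, function(v) as.numeric(v@data)),
    lapply(lib@labels, function(v) as.numeric(v@data)),
    d, as.logical(lib@candidateMask@data > 0),
    params$patchRadius, params$searchRadius,
    params$preselectionThreshold, params$bandwidthFloor)
  vote <- array(vote, d)
  vote[lib@candidateMask@data == 0] <- 0
  mask <- (vote >= params$decisionThreshold) & (lib@candidateMask@data > 0)
  list(mask = labelVolume(mask, target@affine),
       confidence = brainVolume(vote, target@affine))
}

#' Volume of a binary mask in mm^3
#'
#' @param mask binary [LabelVolume-class].
#' @return number of foreground voxels times the voxel volume.
#' @export
segmentationVolume <- function(mask) {
  if (any(!mask@data %in% c(0, 1)))
    stop("mask must be binary", call. = FALSE)
  sum(mask@data) * voxelVolume(mask)
}
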