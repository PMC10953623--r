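#' Construct a BrainVolume
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-index (0-based) to world-mm matrix; default is an
#'   identity grid with the origin at the array centre.
#' @return A [BrainVolume-class].
#' @export
brainVolume <- function(data, affine = NULL) {
  if (is.null(affine)) affine <- centredAffine(dim(data))
  new("BrainVolume", data = data, affine = affine)
}

#' Construct a LabelVolume
#'
#' @param data 3D array of non-negative integers (coerced from logical).
#' @param affine as [brainVolume()].
#' @return A [LabelVolume-class].
#' @export
labelVolume <- function(data, affine = NULL) {
  if (is.logical(data)) {
    d <- dim(data)
    data <- array(as.numeric(data), dim = d)
  }
  if (is.null(affine)) affine <- centredAffine(dim(data))
  new("LabelVolume", data = data, affine = affine)
}

# identity-spacing affine with the world origin at the grid centre
centredAffine <- function(dims, spacing = c(1, 1, 1)) {
  a <- diag(4)
  diag(a)[1:3] <- spacing
  a[1:3, 4] <- -spacing * (dims - 1) / 2
  a
}

# world coordinate of every voxel along one axis (1 = x, 2 = y, 3 = z);
# returns an array of the grid's shape
worldAxis <- function(vol, axis) {
  d <- dim(vol@data)
  a <- vol@affine
  i <- a[axis, 1] * (seq_len(d[1]) - 1)
  j <- a[axis, 2] * (seq_len(d[2]) - 1)
  k <- a[axis, 3] * (seq_len(d[3]) - 1)
  arr <- array(0, d)
  arr <- arr + i
  arr <- arr + rep(j, each = d[1])
  arr <- arr + rep(k, each = d[1] * d[2])
  arr + a[axis, 4]
}

# world coordinates (mm) of a matrix of 0-based voxel indices (n x 3)
voxelToWorld <- function(affine, idx) {
  idx <- rbind(t(idx), 1)
  t(affine %*% idx)[, 1:3, drop = FALSE]
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file and reorients it internally to the canonical
#' right-anterior-superior (RAS) axis order; world-space geometry is
#' unchanged by the reorientation.
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @return A [BrainVolume-class].
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (nd != 3L)
    stop(sprintf("expected a 3D volume, got %dD: %s", nd, path),
         call. = FALSE)
  RNifti::orientation(img) <- "RAS"
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  brainVolume(array(as.numeric(img), dim = dim(img)), aff)
}

#' Write a volume as NIfTI
#'
#' @param vol a [BrainVolume-class] or [LabelVolume-class].
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return The path, invisibly.
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@data)
  RNifti::qform(img) <- structure(vol@affine, code = 2L)
  RNifti::sform(img) <- structure(vol@affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a subject table
#'
#' Parses a comma-separated subject table with required columns
#' \code{id}, \code{image_path}, \code{age}, \code{sex} (an optional
#' \code{true_label} column and any extra columns are preserved).
#' Sex is parsed case-insensitively from M/F/male/female/1/0 and recoded
#' to \code{sex_code} (male = 1, female = 0).
#'
#' @param path CSV file path.
#' @return data.frame, one row per subject, with an added \code{sex_code}
#'   column.
#' @export
readSubjectTable <- function(path) {
  if (!file.exists(path)) stop("subject table not found: ", path,
                               call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "image_path", "age", "sex")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("subject table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$id))
    stop("subject ids are not unique", call. = FALSE)
  age <- suppressWarnings(as.numeric(tab$age))
  bad <- which(is.na(age))
  if (length(bad))
    stop("non-numeric age in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- which(!(age > 0 & age < 120))
  if (length(bad))
    stop("age out of range (0, 120) in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  tab$age <- age
  tab$sex_code <- parseSex(tab$sex)
  tab
}

parseSex <- function(sex) {
  s <- tolower(trimws(as.character(sex)))
  code <- ifelse(s %in% c("m", "male", "1"), 1,
                 ifelse(s %in% c("f", "female", "0"), 0, NA))
  bad <- which(is.na(code))
  if (length(bad))
    stop("unparseable sex value in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  code
}

#' Write the per-subject feature table
#'
#' One row per subject with id, age, sex, ICV, the ventricular features,
#' per-compartment volumes, QC status and the classifier diagnosis.
#' Missing feature values (QC-failed subjects) are written as empty fields.
#'
#' @param rows data.frame as assembled by [runPipeline()] (or rbind of
#'   [as.data.frame.VentricleFeatures()] rows plus id/qc/diagnosis columns).
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeFeatureTable <- function(rows, path) {
  write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a feature table written by [writeFeatureTable()]
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readFeatureTable <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
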