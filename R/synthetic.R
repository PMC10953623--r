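#' Phantom specification
#'
#' Parameters of one synthetic T1-like head phantom: grid geometry, tissue
#' contrast, ventricular shape factors, and scanner-like corruption
#' (noise, multiplicative bias, grey/white contrast shift, affine jitter).
#' Scale factors act on compartment volumes: \code{aprFactor} scales the
#' ventricle anterior to the y = -12 mm plane, \code{lrFrontalFactor} /
#' \code{lrTemporalFactor} scale the left frontal / temporal horns, and
#' \code{totalScale} scales the whole ventricular system.
#'
#' @param gridSize voxels per axis (isotropic 1 mm grid).
#' @param icvSemiAxes ICV ellipsoid semi-axes in mm.
#' @param aprFactor,lrFrontalFactor,lrTemporalFactor,totalScale positive
#'   volume scale factors (1 = neutral).
#' @param tissueMeans intensities for white matter, grey matter and CSF on
#'   the [0, 100] scale.
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param biasAmplitude peak relative amplitude of the multiplicative
#'   linear bias field.
#' @param contrastShift grey/white contrast multiplier (1 = nominal; a
#'   field-strength-like acquisition difference).
#' @param affinePerturbation list with \code{trans} (mm), \code{rot}
#'   (radians) and \code{scale} (relative) jitter half-ranges for the
#'   native pose.
#' @param seed RNG seed; generation is bit-reproducible.
#' @return list of class \code{PhantomSpec}.
#' @export
phantomSpec <- function(gridSize = 96, icvSemiAxes = c(38, 44, 40),
                        aprFactor = 1, lrFrontalFactor = 1,
                        lrTemporalFactor = 1, totalScale = 1,
                        tissueMeans = c(white = 70, grey = 50, csf = 10),
                        noiseSd = 3, biasAmplitude = 0.1,
                        contrastShift = 1,
                        affinePerturbation = list(trans = 5, rot = 0.05,
                                                  scale = 0.05),
                        seed = 1L) {
  stopifnot(gridSize >= 64, aprFactor > 0, lrFrontalFactor > 0,
            lrTemporalFactor > 0, totalScale > 0, noiseSd >= 0,
            biasAmplitude >= 0, contrastShift > 0)
  structure(list(gridSize = as.integer(gridSize), icvSemiAxes = icvSemiAxes,
                 aprFactor = aprFactor, lrFrontalFactor = lrFrontalFactor,
                 lrTemporalFactor = lrTemporalFactor,
                 totalScale = totalScale, tissueMeans = tissueMeans,
                 noiseSd = noiseSd, biasAmplitude = biasAmplitude,
                 contrastShift = contrastShift,
                 affinePerturbation = affinePerturbation,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

# ICV ellipsoid centre in template world mm
icvCentre <- c(0, -2, 0)

# lateral-ventricle component geometry (right hemisphere; mirrored in x for
# the left). Columns: centre, semi-axes, kind (which asymmetry factor
# applies). All world mm.
ventricleComponents <- function() {
  data.frame(
    kind = c("body", "frontal", "temporal", "occipital"),
    cx = c(9, 11, 16, 10), cy = c(-9, 16, -20, -34),
    cz = c(12, 8, 2, 8),
    rx = c(4.5, 5, 4, 4), ry = c(24, 8, 11, 7), rz = c(6, 5, 5, 4))
}

# evaluate the ventricle mask on world-coordinate arrays. The spatial scale
# factor applied to a component's semi-axes is the cube root of the product
# of the volume factors active at each point: totalScale everywhere,
# aprFactor anterior to ySplit, and the left-hemisphere frontal / temporal
# factors for those horns.
ventricleMaskArray <- function(wx, wy, wz, spec, ySplit = -12) {
  comps <- ventricleComponents()
  m <- array(FALSE, dim(wx))
  # global bounding box over all components at the largest active factor,
  # to confine the (vectorized) membership evaluation
  fTop <- (spec$totalScale * max(1, spec$aprFactor, spec$lrFrontalFactor,
                                 spec$lrTemporalFactor))^(1 / 3) *
    max(1, spec$aprFactor * spec$totalScale)^(1 / 3)
  xmax <- max(abs(comps$cx) + comps$rx * fTop)
  yr <- range(comps$cy - comps$ry * fTop, comps$cy + comps$ry * fTop)
  zr <- range(comps$cz - comps$rz * fTop, comps$cz + comps$rz * fTop)
  box <- which(abs(wx) <= xmax & wy >= yr[1] & wy <= yr[2] &
                 wz >= zr[1] & wz <= zr[2])
  bx <- wx[box]; by <- wy[box]; bz <- wz[box]
  inside <- logical(length(box))
  ant <- by > ySplit
  for (hemi in c(1, -1)) {          # +1 right, -1 left
    for (r in seq_len(nrow(comps))) {
      co <- comps[r, ]
      lr <- 1
      if (hemi == -1 && co$kind == "frontal") lr <- spec$lrFrontalFactor
      if (hemi == -1 && co$kind == "temporal") lr <- spec$lrTemporalFactor
      fPost <- (spec$totalScale * lr)^(1 / 3)
      fAnt <- (spec$totalScale * lr * spec$aprFactor)^(1 / 3)
      cx <- hemi * co$cx
      f <- ifelse(ant, fAnt, fPost)
      u <- ((bx - cx) / (co$rx * f))^2 + ((by - co$cy) / (co$ry * f))^2 +
        ((bz - co$cz) / (co$rz * f))^2
      inside <- inside | u <= 1
    }
  }
  m[box[inside]] <- TRUE
  m
}

#' Build the synthetic stereotaxic template space
#'
#' Noise-free, bias-free head phantom at the identity pose: an ellipsoidal
#' ICV with a white-matter core, a grey-matter shell and CSF-filled
#' lateral ventricles (body plus frontal, temporal and occipital horns per
#' hemisphere, mirror-symmetric in x). The lobar atlas partitions the ICV
#' by world-coordinate rules (frontal: y > 10; parietal: y in [-40, 10],
#' z > 10; temporal: y in [-40, 10], z <= 10; occipital: y < -40;
#' hemisphere by the sign of x, x > 0 right). The ventricle prior is the
#' template's own ventricle mask.
#'
#' @param spec a [phantomSpec()] with neutral factors.
#' @return A [TemplateSpace-class].
#' @export
makeTemplate <- function(spec = phantomSpec()) {
  n <- spec$gridSize
  aff <- centredAffine(c(n, n, n))
  ref <- brainVolume(array(0, c(n, n, n)), aff)
  wx <- worldAxis(ref, 1); wy <- worldAxis(ref, 2); wz <- worldAxis(ref, 3)
  u <- ((wx - icvCentre[1]) / spec$icvSemiAxes[1])^2 +
    ((wy - icvCentre[2]) / spec$icvSemiAxes[2])^2 +
    ((wz - icvCentre[3]) / spec$icvSemiAxes[3])^2
  icv <- u <= 1
  white <- u <= 0.85^2
  vent <- ventricleMaskArray(wx, wy, wz, spec)
  tm <- spec$tissueMeans
  img <- array(0, c(n, n, n))
  img[icv] <- tm[["grey"]]
  img[white] <- tm[["white"]]
  img[vent] <- tm[["csf"]]
  atlas <- array(0L, c(n, n, n))
  lobe <- ifelse(wy > 10, 1L,
                 ifelse(wy < -40, 4L, ifelse(wz > 10, 2L, 3L)))
  hemi <- ifelse(wx > 0, 1L, 0L)     # 1 right, 0 left
  atlas[icv] <- ((lobe - 1L) * 2L + hemi + 1L)[icv]
  codeTable <- data.frame(
    code = 1:8,
    lobe = rep(c("frontal", "parietal", "temporal", "occipital"),
               each = 2),
    hemisphere = rep(c("left", "right"), 4))
  codeTable$name <- compartmentNames(codeTable)
  new("TemplateSpace",
      template = brainVolume(img, aff),
      icvMask = labelVolume(icv, aff),
      atlas = labelVolume(atlas, aff),
      codeTable = codeTable,
      ventriclePrior = labelVolume(vent, aff))
}

# sample a native-pose perturbation (native -> template world transform)
samplePerturbation <- function(pert, centre) {
  t <- runif(3, -pert$trans, pert$trans)
  r <- runif(3, -pert$rot, pert$rot)
  s <- log(1 + runif(3, -pert$scale, pert$scale))
  paramsToMatrix(c(t, r, s, 0, 0, 0), centre)
}

#' Generate one native-space phantom with ground truth
#'
#' Builds the subject's template-space ventricle anatomy from the spec's
#' shape factors, fills tissue intensities (with the grey/white contrast
#' shift), applies a random within-range rigid+scale pose to produce the
#' "native" image, then adds a smooth multiplicative bias field and
#' Gaussian noise. Ground truth records the template-space mask, the true
#' native-to-template transform, and the feature values measured on the
#' truth mask.
#'
#' @param spec a [phantomSpec()].
#' @param tspace the [TemplateSpace-class] from [makeTemplate()].
#' @param pose optional fixed 4x4 native-to-template matrix overriding the
#'   random pose draw — e.g. to simulate a same-session rescan with new
#'   noise or contrast but identical anatomy and positioning.
#' @return list with \code{native} ([BrainVolume-class]),
#'   \code{truthMaskNative}, \code{truthMaskTemplate}
#'   ([LabelVolume-class]), \code{truthTransform}
#'   ([AffineTransform-class], native to template) and
#'   \code{truthFeatures} (list of ground-truth feature values).
#' @export
makePhantom <- function(spec, tspace, pose = NULL) {
  withSeed(spec$seed, {
    n <- spec$gridSize
    aff <- tspace@template@affine
    ref <- tspace@template
    wx <- worldAxis(ref, 1); wy <- worldAxis(ref, 2); wz <- worldAxis(ref, 3)
    vent <- ventricleMaskArray(wx, wy, wz, spec)
    u <- ((wx - icvCentre[1]) / spec$icvSemiAxes[1])^2 +
      ((wy - icvCentre[2]) / spec$icvSemiAxes[2])^2 +
      ((wz - icvCentre[3]) / spec$icvSemiAxes[3])^2
    icv <- u <= 1
    if (any(vent & !icv))
      stop("generation error: ventricle exits the ICV (factors too extreme)",
           call. = FALSE)
    tm <- spec$tissueMeans
    grey <- tm[["white"]] - (tm[["white"]] - tm[["grey"]]) *
      spec$contrastShift
    img <- array(0, c(n, n, n))
    img[icv] <- grey
    img[u <= 0.85^2] <- tm[["white"]]
    img[vent] <- tm[["csf"]]
    tmplImg <- brainVolume(img, aff)
    tmplMask <- labelVolume(vent, aff)

    Ttrue <- if (is.null(pose))
      samplePerturbation(spec$affinePerturbation, icvCentre) else pose
    trans <- new("AffineTransform", matrix = Ttrue)
    # native voxel v -> world -> template world -> template voxel
    M <- solve(aff) %*% Ttrue %*% aff
    nat <- array(.cpp_resample(as.numeric(img), c(n, n, n), M, c(n, n, n),
                               0L), c(n, n, n))
    natMask <- array(.cpp_resample(as.numeric(vent), c(n, n, n), M,
                                   c(n, n, n), 1L), c(n, n, n))
    if (spec$biasAmplitude > 0) {
      dir <- rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      half <- (n - 1) / 2
      bias <- 1 + spec$biasAmplitude *
        (dir[1] * wx + dir[2] * wy + dir[3] * wz) / half
      nat <- nat * bias
    }
    if (spec$noiseSd > 0)
      nat <- nat + array(rnorm(n^3, sd = spec$noiseSd), c(n, n, n))

    icvTemplateVol <- sum(icv) * voxelVolume(ref)
    sdet <- scaleDet(trans)
    truthFeatures <- withCallingHandlers(
      computeFeatures(tmplMask, tspace@atlas, tspace@codeTable,
                      icv = icvTemplateVol / sdet,
                      age = NA_real_, sexCode = NA_real_,
                      scaleDet = sdet),
      warning = function(w) invokeRestart("muffleWarning"))
    list(native = brainVolume(nat, aff),
         truthMaskNative = labelVolume(natMask, aff),
         truthMaskTemplate = tmplMask,
         truthTransform = trans,
         truthFeatures = truthFeatures)
  })
}

#' Cohort specification
#'
#' Group-level distributions emulating a bvFTD-like cohort (larger
#' ventricles, larger anterior-posterior ratio, younger), a psychiatric
#' (PPD)-like cohort, and an optional other-dementia-like cohort. Values
#' are means and standard deviations of the per-subject phantom factors.
#'
#' @param n integer vector \code{c(bvftd, ppd, other)} group sizes.
#' @param aprFactor,totalScale,age per-group \code{list(mean =, sd =)} of
#'   length-3 vectors in group order.
#' @param sexRatio probability of male.
#' @param noiseSd,biasAmplitude,contrastShift passed to each phantom.
#' @param seed cohort seed.
#' @return list of class \code{CohortSpec}.
#' @export
cohortSpec <- function(n = c(bvftd = 10, ppd = 10, other = 0),
                       aprFactor = list(mean = c(1.30, 1.00, 1.05),
                                        sd = c(0.15, 0.15, 0.15)),
                       totalScale = list(mean = c(1.3, 1.0, 1.15),
                                         sd = c(0.15, 0.15, 0.15)),
                       age = list(mean = c(63, 69, 74),
                                  sd = c(8, 10, 8)),
                       sexRatio = 0.5, noiseSd = 3, biasAmplitude = 0.1,
                       contrastShift = 1, seed = 1L) {
  stopifnot(length(n) == 3, all(n >= 0), sum(n) > 0)
  structure(list(n = n, aprFactor = aprFactor, totalScale = totalScale,
                 age = age, sexRatio = sexRatio, noiseSd = noiseSd,
                 biasAmplitude = biasAmplitude,
                 contrastShift = contrastShift, seed = as.integer(seed)),
            class = "CohortSpec")
}

groupLabels <- c("bvFTD", "PPD", "other_dementia")

# draw per-subject generation parameters for a cohort (deterministic given
# the cohort seed); factors are truncated away from zero
drawCohortParams <- function(spec) {
  withSeed(spec$seed, {
    rows <- list()
    idx <- 0
    for (g in 1:3) {
      ng <- spec$n[g]
      if (ng == 0) next
      for (i in seq_len(ng)) {
        idx <- idx + 1
        rows[[idx]] <- data.frame(
          id = sprintf("sub-%03d", idx),
          group = groupLabels[g],
          true_label = if (g == 1) "bvFTD" else "other",
          apr_factor = max(0.3, rnorm(1, spec$aprFactor$mean[g],
                                      spec$aprFactor$sd[g])),
          total_scale = max(0.3, rnorm(1, spec$totalScale$mean[g],
                                       spec$totalScale$sd[g])),
          age = min(115, max(30, rnorm(1, spec$age$mean[g],
                                       spec$age$sd[g]))),
          sex = ifelse(runif(1) < spec$sexRatio, "M", "F"),
          seed = (spec$seed %% 20000L) * 100000L + idx)
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a synthetic cohort
#'
#' Draws per-subject ventricular shape factors and demographics from the
#' cohort spec's group distributions, builds each phantom, and (when
#' \code{writeImages = TRUE}) writes per-subject NIfTI volumes plus a
#' subject table and a ground-truth feature table to \code{outputDir}.
#' With \code{writeImages = FALSE} only the template-space truth features
#' are computed (no native simulation), which is cheap enough for large
#' classifier cohorts.
#'
#' @param spec a [cohortSpec()].
#' @param outputDir output directory (created if needed); required when
#'   \code{writeImages = TRUE}.
#' @param tspace a [TemplateSpace-class] (built with [makeTemplate()] if
#'   omitted).
#' @param writeImages write native NIfTI phantoms and truth masks.
#' @return list with \code{subjects} (data.frame: id, image_path, age,
#'   sex, true_label), \code{truth} (data.frame of ground-truth features)
#'   and the paths of the written tables (when writing).
#' @export
makeCohort <- function(spec, outputDir = NULL, tspace = NULL,
                       writeImages = TRUE) {
  if (is.null(tspace)) tspace <- makeTemplate(phantomSpec())
  params <- drawCohortParams(spec)
  if (writeImages) {
    stopifnot(!is.null(outputDir))
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  }
  ref <- tspace@template
  wx <- worldAxis(ref, 1); wy <- worldAxis(ref, 2); wz <- worldAxis(ref, 3)
  subjects <- list()
  truth <- list()
  for (i in seq_len(nrow(params))) {
    pr <- params[i, ]
    ps <- phantomSpec(gridSize = dim(ref@data)[1],
                      aprFactor = pr$apr_factor,
                      totalScale = pr$total_scale,
                      noiseSd = spec$noiseSd,
                      biasAmplitude = spec$biasAmplitude,
                      contrastShift = spec$contrastShift,
                      seed = pr$seed)
    if (writeImages) {
      ph <- makePhantom(ps, tspace)
      imgPath <- file.path(outputDir, sprintf("%s_T1.nii.gz", pr$id))
      mskPath <- file.path(outputDir, sprintf("%s_truthmask.nii.gz", pr$id))
      writeVolume(ph$native, imgPath)
      writeVolume(ph$truthMaskNative, mskPath)
      tf <- ph$truthFeatures
    } else {
      imgPath <- NA_character_
      vent <- ventricleMaskArray(wx, wy, wz, ps)
      tmplMask <- labelVolume(vent, ref@affine)
      icvVol <- sum(tspace@icvMask@data) * voxelVolume(ref)
      tf <- computeFeatures(tmplMask, tspace@atlas, tspace@codeTable,
                            icv = icvVol, age = pr$age,
                            sexCode = as.numeric(pr$sex == "M"))
    }
    subjects[[i]] <- data.frame(id = pr$id, image_path = imgPath,
                                age = pr$age, sex = pr$sex,
                                true_label = pr$true_label)
    fd <- as.data.frame(tf)
    fd$age <- pr$age
    fd$sex <- as.numeric(pr$sex == "M")
    truth[[i]] <- cbind(data.frame(id = pr$id, group = pr$group,
                                   true_label = pr$true_label,
                                   apr_factor = pr$apr_factor,
                                   total_scale = pr$total_scale), fd)
  }
  subjects <- do.call(rbind, subjects)
  truth <- do.call(rbind, truth)
  res <- list(subjects = subjects, truth = truth)
  if (writeImages) {
    res$subjectsPath <- file.path(outputDir, "subjects.csv")
    res$truthPath <- file.path(outputDir, "truth.csv")
    write.csv(subjects, res$subjectsPath, row.names = FALSE)
    write.csv(truth, res$truthPath, row.names = FALSE)
  }
  res
}

#' Build the labelled fusion library from jittered phantoms
#'
#' Generates \code{k} template-space phantoms (no pose perturbation),
#' normalizes their intensities, and pairs them with their ground-truth
#' ventricle masks. As in real expert-labelled libraries, the entries span
#' the anatomical range the tool must segment: total ventricle size and
#' anterior-posterior balance are spread across the atrophy spectrum seen
#' in the dementia cohorts (with mild per-entry jitter), rather than
#' clustered around a single healthy anatomy.
#'
#' @param tspace a [TemplateSpace-class].
#' @param k number of library entries.
#' @param totalRange,aprRange ranges of the total-volume and
#'   anterior-posterior factors the entries are spread over.
#' @param jitterSd standard deviation of the per-entry factor jitter.
#' @param noiseSd additive noise in the library images.
#' @param d candidate-mask dilation radius (voxels).
#' @param seed RNG seed.
#' @return A [PatchLibrary-class].
#' @export
makeLibrary <- function(tspace, k = 5, totalRange = c(0.8, 1.8),
                        aprRange = c(0.85, 1.6), jitterSd = 0.05,
                        noiseSd = 2, d = 3, seed = 100L) {
  n <- dim(tspace@template@data)[1]
  totals <- seq(totalRange[1], totalRange[2], length.out = k)
  # decouple size from shape: APR grid traversed in a fixed shuffled order
  aprs <- seq(aprRange[1], aprRange[2],
              length.out = k)[(seq_len(k) * 2 - 1) %% k + 1]
  jit <- withSeed(seed, matrix(rnorm(4 * k, 0, jitterSd), k, 4))
  pairs <- lapply(seq_len(k), function(i) {
    ps <- phantomSpec(gridSize = n,
                      aprFactor = aprs[i] * exp(jit[i, 1]),
                      totalScale = totals[i] * exp(jit[i, 2]),
                      lrFrontalFactor = exp(jit[i, 3]),
                      lrTemporalFactor = exp(jit[i, 4]),
                      noiseSd = noiseSd, biasAmplitude = 0,
                      affinePerturbation = list(trans = 2, rot = 0.02,
                                                scale = 0.02),
                      seed = seed + i)
    # library images travel the same native -> template interpolation path
    # as pipeline targets, so patch statistics are commensurable
    ph <- makePhantom(ps, tspace)
    img <- resampleToTemplate(normalizeIntensity(ph$native),
                              ph$truthTransform, tspace@template)
    list(image = img, label = ph$truthMaskTemplate)
  })
  buildLibrary(pairs, d = d)
}
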