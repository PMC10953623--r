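test_that("anterior/posterior split partitions the mask at y = -12", {
  ts <- fxTemplate()
  aff <- ts@template@affine
  d <- dim(ts@template@data)

  # mask entirely anterior of the plane
  wy <- ventmorph:::worldAxis(ts@template, 2)
  m <- array(0, d); m[wy > 0] <- 1
  ap <- splitAnteriorPosterior(labelVolume(m, aff))
  expect_equal(sum(ap$posterior@data), 0)
  expect_equal(sum(ap$anterior@data), sum(m))

  # symmetric mask about the plane: equal counts
  m <- array(0, d)
  m[abs(wy - (-12)) <= 6 & abs(ventmorph:::worldAxis(ts@template, 1)) < 10 &
      abs(ventmorph:::worldAxis(ts@template, 3)) < 10] <- 1
  ap <- splitAnteriorPosterior(labelVolume(m, aff))
  expect_equal(sum(ap$anterior@data), sum(ap$posterior@data))
  # partition: union disjoint and complete
  expect_equal(ap$anterior@data + ap$posterior@data, m)
})

test_that("split counts match the per-voxel world-coordinate oracle", {
  withr::local_seed(31)
  d <- c(32, 32, 32)
  aff <- diag(4); aff[1:3, 4] <- c(-20, -25, -15)
  aff[2, 2] <- 1.3                      # anisotropic y spacing
  m <- array(as.numeric(runif(prod(d)) < 0.1), d)
  ap <- splitAnteriorPosterior(labelVolume(m, aff))
  oracle <- bruteSplitCounts(m, aff)
  expect_equal(sum(ap$anterior@data), unname(oracle["anterior"]))
  expect_equal(sum(ap$posterior@data), unname(oracle["posterior"]))
})

test_that("APR arithmetic and error handling follow the definition", {
  r <- computeAPR(300, 200)
  expect_equal(r$apr, 1.5)
  expect_equal(r$aprLog, log(1.5), tolerance = 1e-12)
  expect_equal(computeAPR(250, 250)$aprLog, 0)
  expect_error(computeAPR(100, 0), "posterior")
  # antisymmetry under swapping anterior/posterior
  expect_equal(computeAPR(320, 180)$aprLog, -computeAPR(180, 320)$aprLog)
})

test_that("parcellation assigns volumes per compartment and conserves mass", {
  ts <- fxTemplate()
  aff <- ts@template@affine
  d <- dim(ts@template@data)
  wx <- ventmorph:::worldAxis(ts@template, 1)
  wy <- ventmorph:::worldAxis(ts@template, 2)
  wz <- ventmorph:::worldAxis(ts@template, 3)

  m <- array(0, d)
  m[wx < -5 & wy > 15 & wy < 25 & abs(wz) < 8 & ts@atlas@data > 0] <- 1
  vols <- parcellateVolumes(labelVolume(m, aff), ts@atlas, ts@codeTable)
  expect_gt(vols[["frontal_L"]], 0)
  expect_equal(sum(vols[names(vols) != "frontal_L"]), 0)

  # mirror in x swaps left/right exactly (atlas is mirror-symmetric)
  m2 <- m[d[1]:1, , ]
  vols2 <- parcellateVolumes(labelVolume(m2, aff), ts@atlas, ts@codeTable)
  expect_equal(vols2[["frontal_R"]], vols[["frontal_L"]])
  expect_equal(vols2[["frontal_L"]], vols[["frontal_R"]])

  # conservation on a random mask spilling outside the atlas
  withr::local_seed(33)
  idx <- sample(which(ts@icvMask@data > 0), 4000)
  m3 <- array(0, d); m3[idx] <- 1
  m3[1:3, 1:3, 1:3] <- 1                # voxels with background atlas code
  lv <- labelVolume(m3, aff)
  vols3 <- parcellateVolumes(lv, ts@atlas, ts@codeTable)
  expect_equal(sum(vols3), segmentationVolume(lv))
})

test_that("features on a symmetric phantom have zero log-ratios", {
  ts <- fxTemplate()
  icv <- sum(ts@icvMask@data) * voxelVolume(ts@icvMask)
  f <- computeFeatures(ts@ventriclePrior, ts@atlas, ts@codeTable,
                       icv = icv, age = 60, sexCode = 1)
  expect_equal(f@lrFrontalLog, 0)
  expect_equal(f@lrTemporalLog, 0)
  expect_lt(abs(f@aprLog), 0.05)
  # conservation invariants
  expect_equal(f@anteriorVol + f@posteriorVol, f@totalVol)
  expect_equal(sum(f@compartmentVols), f@totalVol)
  expect_equal(f@totalVolNorm, f@totalVol / icv)
})

test_that("feature volumes are reported in native mm^3 via scaleDet", {
  ts <- fxTemplate()
  icvT <- sum(ts@icvMask@data) * voxelVolume(ts@icvMask)
  sdet <- 1.2
  f <- computeFeatures(ts@ventriclePrior, ts@atlas, ts@codeTable,
                       icv = icvT / sdet, age = 60, sexCode = 0,
                       scaleDet = sdet)
  f1 <- computeFeatures(ts@ventriclePrior, ts@atlas, ts@codeTable,
                        icv = icvT, age = 60, sexCode = 0)
  expect_equal(f@totalVol, f1@totalVol / sdet)
  # normalized volume is invariant to the registration scaling
  expect_equal(f@totalVolNorm, f1@totalVolNorm, tolerance = 1e-12)
  expect_equal(f@aprLog, f1@aprLog, tolerance = 1e-12)
})

test_that("generator ground truth matches features measured on the truth mask", {
  ts <- fxTemplate()
  ph <- makePhantom(phantomSpec(aprFactor = 1.4, totalScale = 1.3,
                                lrFrontalFactor = 1.2, seed = 55), ts)
  tf <- ph$truthFeatures
  # independent voxel-count check of the recorded total volume
  nativeVox <- sum(ph$truthMaskTemplate@data) /
    scaleDet(ph$truthTransform)
  expect_equal(tf@totalVol, nativeVox * voxelVolume(ph$truthMaskTemplate),
               tolerance = 1e-10)
  expect_gt(tf@lrFrontalLog, 0)      # left frontal enlarged by the factor
  f2 <- computeFeatures(ph$truthMaskTemplate, ts@atlas, ts@codeTable,
                        icv = tf@icv, age = 60, sexCode = 1,
                        scaleDet = scaleDet(ph$truthTransform))
  expect_equal(f2@apr, tf@apr, tolerance = 1e-10)
})

test_that("zero compartments raise undefined-feature errors", {
  ts <- fxTemplate()
  d <- dim(ts@template@data)
  aff <- ts@template@affine
  wy <- ventmorph:::worldAxis(ts@template, 2)
  m <- array(0, d)
  m[wy > 0 & ts@ventriclePrior@data > 0] <- 1   # anterior-only mask
  expect_error(computeFeatures(labelVolume(m, aff), ts@atlas,
                               ts@codeTable, icv = 1e6, age = 60,
                               sexCode = 1),
               "posterior")
})

test_that("automated QC passes faithful masks and fails broken ones", {
  ts <- fxTemplate()
  prior <- ts@ventriclePrior
  qc <- qcSegmentation(prior, prior, ts@atlas, ts@codeTable)
  expect_equal(qc$status, "pass")
  expect_equal(qc$overlapWithPrior, 1.0)

  empty <- labelVolume(array(0, dim(prior@data)), prior@affine)
  qc <- qcSegmentation(empty, prior)
  expect_equal(qc$status, "fail")
  expect_setequal(qc$reasons, c("low_overlap", "volume_out_of_range"))

  # prior translated 40 mm has (near-)zero overlap with itself
  shifted <- labelVolume(ventmorph:::shiftArray(prior@data, c(40, 0, 0)),
                         prior@affine)
  qc <- qcSegmentation(shifted, prior)
  expect_true("low_overlap" %in% qc$reasons)

  # fragmentation check: >4 sizeable 6-connected components
  d <- dim(prior@data)
  frag <- array(0, d)
  for (cx in list(c(10, 10), c(10, 80), c(80, 10), c(80, 80), c(45, 45)))
    frag[cx[1]:(cx[1] + 4), cx[2]:(cx[2] + 4), 40:47] <- 1
  frag <- frag + prior@data
  frag[frag > 1] <- 1
  qc <- qcSegmentation(labelVolume(frag, prior@affine), prior)
  expect_true("fragmented" %in% qc$reasons)
})
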