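toAff <- function(d) ventmorph:::centredAffine(d)

# wrap raw arrays into a PatchLibrary on an identity-spacing grid
wrapLibrary <- function(imgs, labs, d = 1) {
  aff <- toAff(dim(imgs[[1]]))
  pairs <- lapply(seq_along(imgs), function(i)
    list(image = brainVolume(imgs[[i]], aff),
         label = labelVolume(labs[[i]], aff)))
  buildLibrary(pairs, d = d)
}

test_that("candidate mask is the dilated union of library labels", {
  d <- c(9, 9, 9)
  lab1 <- array(0, d); lab1[4, 4, 4] <- 1
  lab2 <- array(0, d); lab2[7, 7, 7] <- 1
  img <- array(rnorm(prod(d)), d)

  lib0 <- wrapLibrary(list(img, img), list(lab1, lab2), d = 0)
  expect_equal(lib0@candidateMask@data, lab1 + lab2)  # exact union, d = 0

  lib1 <- wrapLibrary(list(img, img), list(lab1, lab1), d = 1)
  expect_equal(sum(lib1@candidateMask@data), 7)       # 6-ball around centre
  expect_true(all(lib1@candidateMask@data[lab1 == 1] == 1))

  bad <- list(list(image = brainVolume(img, toAff(d)),
                   label = labelVolume(lab1, toAff(d))),
              list(image = brainVolume(array(0, c(5, 5, 5))),
                   label = labelVolume(array(0, c(5, 5, 5)))))
  expect_error(buildLibrary(bad), "entry 2")
  expect_error(buildLibrary(list(list(image = 1, label = 1))), "at least 2")
})

test_that("unanimous library labels fuse to the candidate mask exactly", {
  withr::local_seed(7)
  d <- c(10, 10, 10)
  labs <- list(array(1, d), array(1, d))
  imgs <- list(array(rnorm(prod(d), 50, 10), d),
               array(rnorm(prod(d), 50, 10), d))
  lib <- wrapLibrary(imgs, labs, d = 0)
  target <- brainVolume(array(rnorm(prod(d), 50, 10), d), toAff(d))
  seg <- segmentVentricles(target, lib, fusionParams(searchRadius = 1))
  expect_equal(seg$mask@data, lib@candidateMask@data)
  expect_true(all(seg$confidence@data == 1))
})

test_that("fusion matches the brute-force oracle voxel-for-voxel", {
  withr::local_seed(11)
  for (case in list(list(d = c(7, 7, 7), sr = 1, sigma = 0.95),
                    list(d = c(9, 8, 7), sr = 2, sigma = 0.95),
                    list(d = c(8, 8, 8), sr = 2, sigma = 0))) {
    toy <- makeToyLibrary(case$d, k = 2, seed = sample.int(100, 1))
    lib <- wrapLibrary(toy$images, toy$labels, d = 2)
    target <- brainVolume(
      toy$images[[1]] + array(rnorm(prod(case$d), sd = 2), case$d),
      toAff(case$d))
    params <- fusionParams(searchRadius = case$sr,
                           preselectionThreshold = case$sigma)
    seg <- segmentVentricles(target, lib, params)
    oracle <- bruteFusion(target@data, toy$images, toy$labels,
                          lib@candidateMask@data > 0,
                          pr = 1, sr = case$sr, sigma = case$sigma)
    expect_equal(seg$confidence@data, oracle, tolerance = 1e-10)
    expect_equal(seg$mask@data,
                 array(as.numeric(oracle >= 0.5 &
                                    lib@candidateMask@data > 0), case$d))
  }
})

test_that("the closest library patch dominates via the adaptive bandwidth", {
  d <- c(32, 32, 32)
  toy <- makeToyLibrary(d, k = 3, seed = 9)
  # entries 2 and 3 heavily corrupted; entry 1 is the target itself
  withr::local_seed(10)
  toy$images[[2]] <- toy$images[[2]] + array(rnorm(prod(d), sd = 40), d)
  toy$images[[3]] <- toy$images[[3]] + array(rnorm(prod(d), sd = 40), d)
  toy$labels[[2]] <- array(0, d)
  toy$labels[[3]] <- array(0, d)
  lib <- wrapLibrary(toy$images, toy$labels, d = 2)
  target <- brainVolume(toy$images[[1]], toAff(d))
  seg <- segmentVentricles(target, lib, fusionParams(searchRadius = 2))
  expect_gte(diceCoefficient(seg$mask@data, toy$labels[[1]]), 0.95)
})

test_that("fusion is invariant to library entry order", {
  d <- c(8, 8, 8)
  toy <- makeToyLibrary(d, k = 3, seed = 13)
  target <- brainVolume(toy$images[[2]], toAff(d))
  a <- segmentVentricles(target,
                         wrapLibrary(toy$images, toy$labels, d = 1),
                         fusionParams(searchRadius = 1))
  b <- segmentVentricles(target,
                         wrapLibrary(rev(toy$images), rev(toy$labels),
                                     d = 1),
                         fusionParams(searchRadius = 1))
  expect_equal(a$confidence@data, b$confidence@data, tolerance = 1e-12)
  expect_identical(a$mask@data, b$mask@data)
})

test_that("raising the decision threshold never adds voxels", {
  d <- c(9, 9, 9)
  toy <- makeToyLibrary(d, k = 2, seed = 17)
  target <- brainVolume(toy$images[[1]] +
                          array(rnorm(prod(d), sd = 3), d), toAff(d))
  lib <- wrapLibrary(toy$images, toy$labels, d = 2)
  prev <- NULL
  for (thr in c(0.3, 0.5, 0.7, 0.9)) {
    seg <- segmentVentricles(target, lib,
                             fusionParams(searchRadius = 1,
                                          decisionThreshold = thr))
    if (!is.null(prev)) expect_true(all(prev[seg$mask@data == 1] == 1))
    prev <- seg$mask@data
  }
})

test_that("fused votes are convex combinations of the labels", {
  d <- c(8, 8, 8)
  toy <- makeToyLibrary(d, k = 2, seed = 19)
  target <- brainVolume(toy$images[[1]], toAff(d))
  lib <- wrapLibrary(toy$images, toy$labels, d = 3)
  seg <- segmentVentricles(target, lib, fusionParams(searchRadius = 2))
  expect_true(all(seg$confidence@data >= 0 & seg$confidence@data <= 1))
})

test_that("segmentation volume respects voxel geometry", {
  d <- c(10, 10, 10)
  arr <- array(0, d); arr[1:10, 1:10, 1] <- 1           # 100 voxels
  expect_equal(segmentationVolume(labelVolume(arr)), 100)
  aff <- diag(c(1, 1, 2, 1))
  expect_equal(segmentationVolume(labelVolume(arr, aff)), 200)
  expect_equal(segmentationVolume(labelVolume(array(0, d))), 0)
  bad <- labelVolume(array(2, d))
  expect_error(segmentationVolume(bad), "binary")
})

test_that("fusion rejects targets on the wrong grid", {
  d <- c(8, 8, 8)
  toy <- makeToyLibrary(d, k = 2, seed = 23)
  lib <- wrapLibrary(toy$images, toy$labels, d = 1)
  target <- brainVolume(array(0, c(6, 6, 6)) + rnorm(216))
  expect_error(segmentVentricles(target, lib), "grid")
})
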