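# small flat-tissue head phantom for normalization tests
flatPhantom <- function(n = 48, value = 50) {
  vol <- brainVolume(array(0, c(n, n, n)))
  w1 <- ventmorph:::worldAxis(vol, 1)
  w2 <- ventmorph:::worldAxis(vol, 2)
  w3 <- ventmorph:::worldAxis(vol, 3)
  r <- n / 2 - 4
  inside <- (w1^2 + w2^2 + w3^2) <= r^2
  vol@data[inside] <- value
  list(vol = vol, inside = inside, wx = w1)
}

test_that("normalization is idempotent on clean full-range images", {
  # two-tissue head already spanning [0, 100], no bias field
  ph <- flatPhantom(value = 100)
  img <- ph$vol
  shell <- ph$inside & (ph$wx^2 > 100)
  img@data[shell] <- 60
  out <- normalizeIntensity(img)
  expect_lt(max(abs(out@data - img@data)), 1)   # within 1% of range
})

test_that("normalization is invariant to global intensity scaling", {
  ph <- flatPhantom()
  noisy <- ph$vol
  withr::local_seed(2)
  noisy@data <- noisy@data + array(rnorm(length(noisy@data)),
                                   dim(noisy@data))
  a <- normalizeIntensity(noisy)
  scaled <- noisy
  scaled@data <- scaled@data * 1000
  b <- normalizeIntensity(scaled)
  expect_equal(a@data, b@data, tolerance = 1e-10)
})

test_that("a known linear bias field is removed to under 5%", {
  ph <- flatPhantom()
  biased <- ph$vol
  half <- (dim(biased@data)[1] - 1) / 2
  bias <- 1 + 0.2 * ph$wx / half              # +-20% along x
  biased@data <- biased@data * bias
  out <- normalizeIntensity(biased)
  v <- out@data[ph$inside]
  x <- ph$wx[ph$inside]
  slope <- coef(lm(v ~ x))[2]
  relResidual <- abs(slope) * (max(x) - min(x)) / mean(v)
  expect_lt(relResidual, 0.05)
})

test_that("constant images are rejected by normalization", {
  expect_error(normalizeIntensity(brainVolume(array(7, c(8, 8, 8)))),
               "constant")
})

test_that("self-registration returns a near-identity transform", {
  ts <- fxTemplate()
  tr <- suppressWarnings(registerAffine(ts@template, ts@template))
  expect_lt(sqrt(sum(tr@matrix[1:3, 4]^2)), 0.5)
  expect_lt(abs(scaleDet(tr) - 1), 0.01)
})

test_that("known translations and scalings are recovered", {
  ts <- fxTemplate()
  tmpl <- ts@template
  aff <- tmpl@affine
  apply_known <- function(Tknown) {
    M <- solve(aff) %*% Tknown %*% aff
    arr <- array(ventmorph:::.cpp_resample(
      as.numeric(tmpl@data), dim(tmpl@data), M, dim(tmpl@data), 0L),
      dim(tmpl@data))
    brainVolume(arr, aff)
  }
  Tt <- diag(4); Tt[1:3, 4] <- c(5, -3, 2)
  moving <- apply_known(Tt)
  tr <- suppressWarnings(registerAffine(moving, tmpl))
  expect_lt(max(abs(tr@matrix[1:3, 4] - c(5, -3, 2))), 1)

  Ts <- diag(c(0.9, 0.9, 0.9, 1))
  moving <- apply_known(Ts)
  tr <- suppressWarnings(registerAffine(moving, tmpl))
  expect_lt(abs(scaleDet(tr) / 0.9^3 - 1), 0.03)
})

test_that("registration is self-consistent under inversion", {
  ts <- fxTemplate()
  ph <- makePhantom(phantomSpec(seed = 77, noiseSd = 1), ts)
  nrm <- normalizeIntensity(ph$native)
  tmplN <- normalizeIntensity(ts@template)
  ab <- suppressWarnings(registerAffine(nrm, tmplN))
  ba <- suppressWarnings(registerAffine(tmplN, nrm))
  comp <- ab@matrix %*% ba@matrix
  expect_lt(sqrt(sum(comp[1:3, 4]^2)), 1.5)
  expect_lt(abs(abs(det(comp[1:3, 1:3]))^(1 / 3) - 1), 0.02)
})

test_that("resampling is exact for identity and lattice-aligned shifts", {
  withr::local_seed(4)
  vol <- brainVolume(array(rnorm(14^3), c(14, 14, 14)))
  ident <- new("AffineTransform", matrix = diag(4))
  out <- resampleToTemplate(vol, ident, vol)
  expect_equal(out@data, vol@data, tolerance = 1e-12)

  Tt <- diag(4); Tt[1:3, 4] <- c(2, -1, 3)   # integer mm = integer voxels
  tr <- new("AffineTransform", matrix = Tt)
  out <- resampleToTemplate(vol, tr, vol)
  # voxel v in output samples the input at v shifted by -(2,-1,3)
  expect_equal(out@data[4:10, 4:10, 4:10],
               vol@data[4:10 - 2, 4:10 + 1, 4:10 - 3], tolerance = 1e-12)
})

test_that("small affines preserve regional mean intensity", {
  ts <- fxTemplate()
  tmpl <- ts@template
  Tt <- ventmorph:::paramsToMatrix(c(1.5, -1, 0.5, 0.01, -0.01, 0.02,
                                     0.01, 0.01, 0.01, 0, 0, 0),
                                   c(0, -2, 0))
  tr <- new("AffineTransform", matrix = solve(Tt))
  out <- resampleToTemplate(tmpl, tr, tmpl)
  # deep interior region whose boundary sits in uniform white matter, so
  # the small pose change only moves content within the region
  wx <- ventmorph:::worldAxis(tmpl, 1)
  wy <- ventmorph:::worldAxis(tmpl, 2)
  wz <- ventmorph:::worldAxis(tmpl, 3)
  u <- (wx / 38)^2 + ((wy + 2) / 44)^2 + (wz / 40)^2
  core <- u <= 0.49
  expect_lt(abs(mean(out@data[core]) / mean(tmpl@data[core]) - 1), 0.02)
})

test_that("ICV estimation follows the transform determinant exactly", {
  mask <- labelVolume(array(1, c(10, 10, 10)))   # 1000 mm^3
  ident <- new("AffineTransform", matrix = diag(4))
  expect_equal(estimateICV(ident, mask), 1000)
  sc <- new("AffineTransform", matrix = diag(c(1.1, 1.1, 1.1, 1)))
  expect_equal(estimateICV(sc, mask), 1000 / 1.331, tolerance = 1e-12)
  # exact homogeneity over random determinants
  withr::local_seed(5)
  for (i in 1:5) {
    s <- runif(3, 0.7, 1.4)
    t1 <- new("AffineTransform", matrix = diag(c(s, 1)))
    t2 <- new("AffineTransform", matrix = diag(c(s * 2^(1 / 3), 1)))
    expect_equal(estimateICV(t1, mask) / 2, estimateICV(t2, mask),
                 tolerance = 1e-12)
  }
})

test_that("phantom ICV estimated via registration matches ground truth", {
  ts <- fxTemplate()
  ph <- makePhantom(phantomSpec(seed = 42), ts)
  nrm <- normalizeIntensity(ph$native)
  tr <- suppressWarnings(registerAffine(nrm, ts@template))
  icv <- estimateICV(tr, ts@icvMask)
  truthIcv <- sum(ts@icvMask@data) * voxelVolume(ts@icvMask) /
    scaleDet(ph$truthTransform)
  expect_lt(abs(icv / truthIcv - 1), 0.05)
})

test_that("transforms round-trip through the text format", {
  tr <- new("AffineTransform",
            matrix = ventmorph:::paramsToMatrix(
              c(1, 2, 3, 0.01, 0.02, 0.03, 0.05, 0, -0.05, 0.01, 0, 0),
              c(0, -2, 0)),
            converged = FALSE, metric = 0.87)
  path <- withr::local_tempfile(fileext = ".txt")
  saveTransform(tr, path)
  back <- loadTransform(path)
  expect_equal(back@matrix, tr@matrix)
  expect_false(back@converged)
  expect_equal(back@metric, 0.87)
})
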