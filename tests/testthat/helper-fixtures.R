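# Session-cached heavy fixtures: the synthetic template space, the fusion
# library, a 10-phantom segmentation study with contrast-shifted rescans,
# generator cohorts for the classifier, and a demo-cohort pipeline run.
# Everything is seeded, so caching only avoids recomputation.

.fx <- new.env(parent = emptyenv())

fxTemplate <- function() {
  if (is.null(.fx$tspace)) .fx$tspace <- makeTemplate(phantomSpec())
  .fx$tspace
}

fxLibrary <- function() {
  if (is.null(.fx$lib)) .fx$lib <- makeLibrary(fxTemplate())
  .fx$lib
}

# run one native phantom through the full template-space pipeline
segmentOnePhantom <- function(ph, tspace, lib) {
  nrm <- normalizeIntensity(ph$native)
  tr <- suppressWarnings(registerAffine(nrm, tspace@template))
  res <- resampleToTemplate(nrm, tr, tspace@template)
  seg <- segmentVentricles(res, lib)
  qc <- qcSegmentation(seg$mask, tspace@ventriclePrior, tspace@atlas,
                       tspace@codeTable)
  list(transform = tr, seg = seg, qc = qc,
       dice = diceCoefficient(seg$mask, ph$truthMaskTemplate),
       vol = segmentationVolume(seg$mask))
}

# 10-phantom segmentation study (5 bvFTD-like + 5 PPD-like) plus a
# contrast-shifted, re-noised rescan of each phantom at the same pose
fxStudy <- function() {
  if (!is.null(.fx$study)) return(.fx$study)
  tspace <- fxTemplate()
  lib <- fxLibrary()
  params <- ventmorph:::drawCohortParams(cohortSpec(n = c(5, 5, 0),
                                                    seed = 11))
  res <- lapply(seq_len(nrow(params)), function(i) {
    pr <- params[i, ]
    spec1 <- phantomSpec(aprFactor = pr$apr_factor,
                         totalScale = pr$total_scale, seed = pr$seed)
    ph1 <- makePhantom(spec1, tspace)
    spec2 <- phantomSpec(aprFactor = pr$apr_factor,
                         totalScale = pr$total_scale,
                         contrastShift = 1.15, seed = pr$seed + 5000L)
    ph2 <- makePhantom(spec2, tspace, pose = ph1$truthTransform@matrix)
    r1 <- segmentOnePhantom(ph1, tspace, lib)
    r2 <- segmentOnePhantom(ph2, tspace, lib)
    list(truth = ph1$truthMaskTemplate, truthFeatures = ph1$truthFeatures,
         truthSame = identical(ph1$truthMaskTemplate@data,
                               ph2$truthMaskTemplate@data),
         scan1 = r1, scan2 = r2,
         repeatDice = diceCoefficient(r1$seg$mask, r2$seg$mask))
  })
  .fx$study <- res
  res
}

# generator cohorts used for classifier training / independent evaluation
fxCohort <- function(which = c("train", "test")) {
  which <- match.arg(which)
  key <- paste0("cohort_", which)
  if (is.null(.fx[[key]])) {
    seed <- if (which == "train") 21L else 99L
    .fx[[key]] <- makeCohort(cohortSpec(n = c(200, 200, 0), seed = seed),
                             tspace = fxTemplate(), writeImages = FALSE)
  }
  .fx[[key]]
}

# demo cohort on disk plus two independent pipeline runs over it
fxDemoRun <- function() {
  if (!is.null(.fx$demo)) return(.fx$demo)
  tspace <- fxTemplate()
  lib <- fxLibrary()
  train <- fxCohort("train")
  model <- trainClassifier(train$truth[, classifierFeatures()],
                           train$truth$true_label, seed = 1)
  dir <- file.path(tempdir(), "ventmorph-demo")
  cohort <- makeCohort(cohortSpec(n = c(3, 3, 0), seed = 31),
                       outputDir = file.path(dir, "cohort"),
                       tspace = tspace)
  fixtures <- list(tspace = tspace, library = lib, model = model)
  run1 <- suppressWarnings(
    runPipeline(cohort$subjectsPath, file.path(dir, "run1"), fixtures,
                seed = 1))
  run2 <- suppressWarnings(
    runPipeline(cohort$subjectsPath, file.path(dir, "run2"), fixtures,
                seed = 1))
  .fx$demo <- list(dir = dir, cohort = cohort, fixtures = fixtures,
                   run1 = run1, run2 = run2)
  .fx$demo
}
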