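#' Save / load a world-to-world transform as text
#'
#' Small plain-text format: a header line identifying the direction
#' (\code{native_to_template}) followed by the four matrix rows.
#'
#' @param t an [AffineTransform-class].
#' @param path file path.
#' @return \code{saveTransform}: the path, invisibly; \code{loadTransform}:
#'   an [AffineTransform-class].
#' @export
saveTransform <- function(t, path) {
  lines <- c("direction: native_to_template",
             sprintf("converged: %s", t@converged),
             sprintf("metric: %.17g", t@metric),
             apply(t@matrix, 1, function(r)
               paste(sprintf("%.17g", r), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname saveTransform
#' @export
loadTransform <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^direction: native_to_template", lines[1]))
    stop("not a native_to_template transform file: ", path, call. = FALSE)
  conv <- as.logical(sub("^converged: ", "", lines[2]))
  metric <- as.numeric(sub("^metric: ", "", lines[3]))
  m <- do.call(rbind, lapply(lines[4:7], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  new("AffineTransform", matrix = m, converged = conv, metric = metric)
}

#' Materialize template, library, model and demo-cohort fixtures
#'
#' Writes the synthetic template space (template image, ICV mask, lobar
#' atlas + code table, ventricle prior), a labelled fusion library with a
#' manifest, a reference classifier model trained on a generator cohort,
#' and a small demo cohort of native phantoms.
#'
#' @param dir output directory.
#' @param nLibrary library entries.
#' @param nDemo integer vector \code{c(bvftd, ppd, other)} demo-cohort
#'   sizes.
#' @param nTrain per-group size of the model-training cohort (features
#'   only, no images).
#' @param seed base seed.
#' @return list of created paths (invisibly usable with
#'   [loadFixtures()]).
#' @export
makeFixtures <- function(dir, nLibrary = 5, nDemo = c(3, 3, 0),
                         nTrain = 100, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tspace <- makeTemplate(phantomSpec())
  writeVolume(tspace@template, file.path(dir, "template.nii.gz"))
  writeVolume(tspace@icvMask, file.path(dir, "icv_mask.nii.gz"))
  writeVolume(tspace@atlas, file.path(dir, "atlas.nii.gz"))
  writeVolume(tspace@ventriclePrior,
              file.path(dir, "ventricle_prior.nii.gz"))
  write.csv(tspace@codeTable, file.path(dir, "atlas_codes.csv"),
            row.names = FALSE)
  libDir <- file.path(dir, "library")
  dir.create(libDir, showWarnings = FALSE)
  lib <- makeLibrary(tspace, k = nLibrary, seed = seed + 100L)
  manifest <- data.frame(image_path = character(), label_path = character())
  for (i in seq_along(lib@images)) {
    ip <- file.path(libDir, sprintf("lib_%02d_image.nii.gz", i))
    lp <- file.path(libDir, sprintf("lib_%02d_label.nii.gz", i))
    writeVolume(lib@images[[i]], ip)
    writeVolume(lib@labels[[i]], lp)
    manifest[i, ] <- c(ip, lp)
  }
  write.csv(manifest, file.path(dir, "library_manifest.csv"),
            row.names = FALSE)
  train <- makeCohort(cohortSpec(n = c(nTrain, nTrain, 0),
                                 seed = seed + 200L),
                      tspace = tspace, writeImages = FALSE)
  model <- trainClassifier(train$truth[, classifierFeatures()],
                           train$truth$true_label, seed = seed)
  saveModel(model, file.path(dir, "model.txt"))
  demoDir <- file.path(dir, "cohort")
  if (sum(nDemo) > 0)
    makeCohort(cohortSpec(n = nDemo, seed = seed + 300L),
               outputDir = demoDir, tspace = tspace)
  invisible(list(dir = dir, subjects = file.path(demoDir, "subjects.csv"),
                 model = file.path(dir, "model.txt")))
}

#' Load pipeline fixtures from a directory written by [makeFixtures()]
#'
#' @param dir fixtures directory.
#' @return list with \code{tspace}, \code{library}, \code{model}.
#' @export
loadFixtures <- function(dir) {
  codeTable <- read.csv(file.path(dir, "atlas_codes.csv"),
                        stringsAsFactors = FALSE)
  asLabel <- function(p) {
    v <- readVolume(p)
    labelVolume(round(v@data), v@affine)
  }
  tspace <- new("TemplateSpace",
                template = readVolume(file.path(dir, "template.nii.gz")),
                icvMask = asLabel(file.path(dir, "icv_mask.nii.gz")),
                atlas = asLabel(file.path(dir, "atlas.nii.gz")),
                codeTable = codeTable,
                ventriclePrior = asLabel(file.path(dir,
                                                   "ventricle_prior.nii.gz")))
  manifest <- read.csv(file.path(dir, "library_manifest.csv"),
                       stringsAsFactors = FALSE)
  pairs <- lapply(seq_len(nrow(manifest)), function(i)
    list(image = readVolume(manifest$image_path[i]),
         label = asLabel(manifest$label_path[i])))
  list(tspace = tspace,
       library = buildLibrary(pairs, d = fusionParams()$dilation),
       model = loadModel(file.path(dir, "model.txt")))
}

#' Pipeline configuration
#'
#' @param registration a [registrationParams()] list.
#' @param fusion a [fusionParams()] list.
#' @param qc a [qcThresholds()] list.
#' @param ySplit anterior/posterior split plane (template world mm).
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(registration = registrationParams(),
                           fusion = fusionParams(),
                           qc = qcThresholds(), ySplit = -12) {
  structure(list(registration = registration, fusion = fusion, qc = qc,
                 ySplit = ySplit), class = "PipelineConfig")
}

validateConfig <- function(config) {
  if (inherits(config, "PipelineConfig")) return(config)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipelineConfig, config)
}

#' Read a pipeline configuration from a plain key-value file
#'
#' Lines of the form \code{section.key = value} (\code{#} comments and
#' blank lines ignored), e.g. \code{registration.dof = 9} or
#' \code{fusion.search_radius = 3}. Every parameter defaults to the
#' package default, so an empty file is a valid configuration; unknown
#' keys are rejected with an error listing them.
#'
#' @param path config file path.
#' @return A [pipelineConfig()] list.
#' @export
readConfigFile <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  keymap <- list(
    "registration.levels" = c("registration", "levels"),
    "registration.dof" = c("registration", "dof"),
    "registration.max_iter" = c("registration", "maxIter"),
    "registration.tol" = c("registration", "tol"),
    "fusion.patch_radius" = c("fusion", "patchRadius"),
    "fusion.search_radius" = c("fusion", "searchRadius"),
    "fusion.preselection_threshold" = c("fusion",
                                        "preselectionThreshold"),
    "fusion.bandwidth_floor" = c("fusion", "bandwidthFloor"),
    "fusion.dilation" = c("fusion", "dilation"),
    "fusion.decision_threshold" = c("fusion", "decisionThreshold"),
    "qc.min_dice" = c("qc", "minDice"),
    "qc.vol_min" = c("qc", "volMin"),
    "qc.vol_max" = c("qc", "volMax"),
    "qc.max_components" = c("qc", "maxComponents"),
    "qc.min_component_size" = c("qc", "minComponentSize"),
    "y_split" = c("ySplit"))
  args <- list(registration = list(), fusion = list(), qc = list())
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("cannot parse config line: ", l, call. = FALSE)
    key <- trimws(kv[1])
    val <- as.numeric(trimws(kv[2]))
    if (is.na(val)) stop("non-numeric config value for ", key,
                         call. = FALSE)
    if (!key %in% names(keymap))
      stop("unknown config key(s): ", key, call. = FALSE)
    dest <- keymap[[key]]
    if (length(dest) == 1) args[[dest]] <- val
    else args[[dest[1]]][[dest[2]]] <- val
  }
  vol <- qcThresholds()$volRange
  if (!is.null(args$qc$volMin)) vol[1] <- args$qc$volMin
  if (!is.null(args$qc$volMax)) vol[2] <- args$qc$volMax
  args$qc$volMin <- NULL; args$qc$volMax <- NULL
  args$qc$volRange <- vol
  pipelineConfig(
    registration = do.call(registrationParams, args$registration),
    fusion = do.call(fusionParams, args$fusion),
    qc = do.call(qcThresholds, args$qc),
    ySplit = if (is.null(args$ySplit)) -12 else args$ySplit)
}

# full processing of one subject record; any error is propagated to the
# caller, which marks the subject QC_FAIL without aborting the batch
processSubject <- function(record, tspace, lib, model, config) {
  img <- readVolume(record$image_path)
  norm <- normalizeIntensity(img)
  t <- registerAffine(norm, tspace@template, config$registration)
  resampled <- resampleToTemplate(norm, t, tspace@template)
  seg <- segmentVentricles(resampled, lib, config$fusion)
  qc <- qcSegmentation(seg$mask, tspace@ventriclePrior, tspace@atlas,
                       tspace@codeTable, config$qc, config$ySplit)
  icv <- estimateICV(t, tspace@icvMask)
  feats <- NULL
  diagnosis <- "QC_FAIL"
  if (qc$status == "pass") {
    feats <- computeFeatures(seg$mask, tspace@atlas, tspace@codeTable,
                             icv = icv, age = record$age,
                             sexCode = record$sex_code,
                             scaleDet = scaleDet(t),
                             ySplit = config$ySplit)
    fv <- as.data.frame(feats)[, classifierFeatures()[1:4]]
    x <- c(as.numeric(fv), record$age, record$sex_code)
    diagnosis <- predictClassifier(model, x)$label
  }
  list(transform = t, resampled = resampled, seg = seg, qc = qc,
       icv = icv, features = feats, diagnosis = diagnosis)
}

emptyFeatureRow <- function(codeTable) {
  vols <- setNames(rep(NA_real_, nrow(codeTable)),
                   paste0("vol_", compartmentNames(codeTable)))
  data.frame(icv_mm3 = NA_real_, total_vv_norm = NA_real_, apr = NA_real_,
             apr_log = NA_real_, lr_frontal_log = NA_real_,
             lr_temporal_log = NA_real_, total_vol_mm3 = NA_real_,
             anterior_vol_mm3 = NA_real_, posterior_vol_mm3 = NA_real_,
             as.list(vols), check.names = FALSE)
}

#' Run the full segmentation-to-diagnosis pipeline on a subject table
#'
#' Per subject: read, normalize, register to the template, resample,
#' segment by patch-based label fusion, QC, extract ventricular features
#' and classify. Writes per-subject template-space image, segmentation,
#' confidence map, transform and QC record under \code{outDir/<id>/},
#' plus one \code{features.csv} and a run log. Subject-level failures are
#' recorded as diagnosis \code{QC_FAIL} and never abort the batch.
#'
#' @param subjects subject table path (see [readSubjectTable()]) or
#'   data.frame.
#' @param outDir output directory.
#' @param fixtures list with \code{tspace}, \code{library}, \code{model},
#'   or a directory written by [makeFixtures()].
#' @param config a [pipelineConfig()] (or plain list of its arguments).
#' @param resume skip subjects whose outputs already exist.
#' @param seed recorded in the log (the pipeline itself is deterministic).
#' @return invisible list with \code{features} (data.frame),
#'   \code{featuresPath}, \code{nFail}.
#' @export
runPipeline <- function(subjects, outDir, fixtures, config = list(),
                        resume = FALSE, seed = NULL) {
  config <- validateConfig(config)
  if (is.character(fixtures)) fixtures <- loadFixtures(fixtures)
  stopifnot(all(c("tspace", "library", "model") %in% names(fixtures)))
  tab <- if (is.character(subjects)) readSubjectTable(subjects) else subjects
  if (!"sex_code" %in% names(tab)) tab$sex_code <- parseSex(tab$sex)
  if (nrow(tab) < 1) stop("no subjects to process", call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run.log")
  logLine <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = logPath, append = TRUE)
  cat(sprintf("pipeline run %s\nseed: %s\n", format(Sys.time()),
              if (is.null(seed)) "none" else seed),
      file = logPath)
  logLine("config: registration dof=%d levels=%d maxIter=%d | fusion pr=%d sr=%d sigma=%.2f | ySplit=%g",
          config$registration$dof, config$registration$levels,
          config$registration$maxIter, config$fusion$patchRadius,
          config$fusion$searchRadius, config$fusion$preselectionThreshold,
          config$ySplit)
  ct <- fixtures$tspace@codeTable
  rows <- list()
  nFail <- 0
  for (i in seq_len(nrow(tab))) {
    rec <- tab[i, ]
    subDir <- file.path(outDir, rec$id)
    rowPath <- file.path(subDir, "row.csv")
    if (resume && file.exists(rowPath)) {
      rows[[i]] <- read.csv(rowPath, stringsAsFactors = FALSE)
      logLine("subject %s: resumed from existing outputs", rec$id)
      next
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      processSubject(rec, fixtures$tspace, fixtures$library,
                     fixtures$model, config),
      error = function(e) e)
    dir.create(subDir, showWarnings = FALSE)
    if (inherits(res, "error")) {
      nFail <- nFail + 1
      row <- cbind(data.frame(id = rec$id, age = rec$age,
                              sex = rec$sex_code),
                   emptyFeatureRow(ct),
                   data.frame(qc_status = "fail",
                              qc_reasons = "processing_error",
                              diagnosis = "QC_FAIL"))
      logLine("subject %s: ERROR %s", rec$id, conditionMessage(res))
    } else {
      writeVolume(res$resampled, file.path(subDir, "t1_template.nii.gz"))
      writeVolume(res$seg$mask, file.path(subDir, "segmentation.nii.gz"))
      writeVolume(res$seg$confidence,
                  file.path(subDir, "confidence.nii.gz"))
      saveTransform(res$transform, file.path(subDir, "transform.txt"))
      writeLines(c(sprintf("status: %s", res$qc$status),
                   sprintf("reasons: %s",
                           paste(res$qc$reasons, collapse = ";")),
                   sprintf("dice_vs_prior: %.4f", res$qc$overlapWithPrior),
                   sprintf("components: %d", res$qc$componentCount)),
                 file.path(subDir, "qc.txt"))
      featRow <- if (is.null(res$features)) emptyFeatureRow(ct)
        else {
          fd <- as.data.frame(res$features)
          fd$age <- NULL; fd$sex <- NULL
          fd
        }
      if (res$qc$status != "pass") nFail <- nFail + 1
      row <- cbind(data.frame(id = rec$id, age = rec$age,
                              sex = rec$sex_code),
                   featRow,
                   data.frame(qc_status = res$qc$status,
                              qc_reasons = paste(res$qc$reasons,
                                                 collapse = ";"),
                              diagnosis = res$diagnosis))
      logLine("subject %s: %s (dice_vs_prior %.3f, %.1f s)", rec$id,
              res$diagnosis, res$qc$overlapWithPrior,
              proc.time()[["elapsed"]] - t0)
    }
    if ("true_label" %in% names(tab)) row$true_label <- rec$true_label
    write.csv(row, rowPath, row.names = FALSE)
    rows[[i]] <- row
  }
  features <- do.call(rbind, rows)
  featuresPath <- file.path(outDir, "features.csv")
  writeFeatureTable(features, featuresPath)
  logLine("done: %d subjects, %d QC failures", nrow(tab), nFail)
  invisible(list(features = features, featuresPath = featuresPath,
                 nFail = nFail))
}

#' Train a classifier from a feature table
#'
#' @param features feature table path or data.frame with the
#'   [classifierFeatures()] columns and \code{true_label}.
#' @param modelPath where to save the model (optional).
#' @param cost,classWeights,seed passed to [trainClassifier()].
#' @return the trained [SVMModel-class], invisibly.
#' @export
trainCommand <- function(features, modelPath = NULL, cost = 1,
                         classWeights = TRUE, seed = 1L) {
  tab <- if (is.character(features)) readFeatureTable(features)
    else features
  if (!"true_label" %in% names(tab))
    stop("feature table has no true_label column", call. = FALSE)
  keep <- stats::complete.cases(tab[, classifierFeatures()])
  model <- trainClassifier(tab[keep, classifierFeatures()],
                           tab$true_label[keep], cost = cost,
                           classWeights = classWeights, seed = seed)
  p <- predictClassifier(model, tab[keep, classifierFeatures()])
  acc <- mean((p$label == "bvFTD_compatible") ==
                asPositive(tab$true_label[keep]))
  message(sprintf("trained on %d subjects (%d positive); training accuracy %.1f%%",
                  sum(keep), model@nPos, 100 * acc))
  if (!is.null(modelPath)) saveModel(model, modelPath)
  invisible(model)
}

#' Evaluate diagnoses against true labels
#'
#' Computes the overall confusion matrix and metrics, per-subgroup
#' specificity (positive class against each negative subgroup separately,
#' when a \code{group} column is present), and the misclassification
#' group-comparison report.
#'
#' @param features feature table path or data.frame with
#'   \code{true_label} and either a \code{diagnosis} column or features
#'   plus \code{model}.
#' @param model optional [SVMModel-class] used to (re)predict.
#' @return list with \code{confusion}, \code{metrics}, \code{perGroup}
#'   and \code{misclassification}.
#' @export
evaluateCommand <- function(features, model = NULL) {
  tab <- if (is.character(features)) readFeatureTable(features)
    else features
  if (!"true_label" %in% names(tab))
    stop("feature table has no true_label column", call. = FALSE)
  if (!is.null(model)) {
    keep <- stats::complete.cases(tab[, model@featureNames])
    tab <- tab[keep, ]
    tab$diagnosis <- predictClassifier(model,
                                       tab[, model@featureNames])$label
  }
  if (!"diagnosis" %in% names(tab))
    stop("feature table has no diagnosis column (and no model given)",
         call. = FALSE)
  tab <- tab[tab$diagnosis != "QC_FAIL", ]
  truth <- asPositive(tab$true_label)
  pred <- asPositive(tab$diagnosis)
  cm <- confusionCounts(truth, pred)
  metrics <- classificationMetrics(cm)
  perGroup <- list()
  grp <- if ("group" %in% names(tab)) tab$group else tab$true_label
  for (g in unique(grp[!truth])) {
    sel <- truth | grp == g
    if (sum(!truth & grp == g) == 0) {
      warning("subgroup ", g, " has no subjects; skipped", call. = FALSE)
      next
    }
    perGroup[[g]] <- classificationMetrics(
      confusionCounts(truth[sel], pred[sel]))
  }
  numCols <- intersect(c("age", "sex", "apr", "apr_log", "total_vv_norm",
                         "lr_frontal_log", "lr_temporal_log",
                         "total_vol_mm3"), names(tab))
  mis <- withCallingHandlers(
    misclassificationReport(tab, truth, pred, featureCols = numCols),
    warning = function(w) invokeRestart("muffleWarning"))
  list(confusion = cm, metrics = metrics, perGroup = perGroup,
       misclassification = mis)
}
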