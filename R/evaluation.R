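#' Build a confusion matrix from labels
#'
#' Positive class is "compatible with bvFTD". Labels may be logical,
#' 0/1, or strings (\code{"bvFTD"}, \code{"bvFTD_compatible"} count as
#' positive).
#'
#' @param truth,predicted equal-length binary label vectors.
#' @return A [ConfusionMatrix-class].
#' @export
confusionCounts <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted labels differ in length", call. = FALSE)
  t <- asPositive(truth)
  p <- asPositive(predicted)
  new("ConfusionMatrix",
      tp = sum(t & p), fn = sum(t & !p), fp = sum(!t & p),
      tn = sum(!t & !p))
}

#' Construct a confusion matrix from counts
#'
#' @param tp,fn,fp,tn non-negative counts.
#' @return A [ConfusionMatrix-class].
#' @export
confusionMatrix <- function(tp, fn, fp, tn) {
  new("ConfusionMatrix", tp = as.integer(tp), fn = as.integer(fn),
      fp = as.integer(fp), tn = as.integer(tn))
}

#' Diagnostic metrics from a confusion matrix
#'
#' Sensitivity, specificity, accuracy, false-negative and false-positive
#' rates, and the positive/negative likelihood ratios
#' LR+ = sensitivity / (1 - specificity) and
#' LR- = (1 - sensitivity) / specificity. With no false positives LR+ is
#' reported as \code{Inf} and flagged rather than raising an error.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return list with the metric fields plus \code{flags}.
#' @export
classificationMetrics <- function(cm) {
  if (cm@tp + cm@fn == 0)
    stop("undefined metric: sensitivity (no positive subjects)",
         call. = FALSE)
  if (cm@fp + cm@tn == 0)
    stop("undefined metric: specificity (no negative subjects)",
         call. = FALSE)
  sens <- cm@tp / (cm@tp + cm@fn)
  spec <- cm@tn / (cm@fp + cm@tn)
  total <- cm@tp + cm@fn + cm@fp + cm@tn
  flags <- character()
  lrPos <- if (spec == 1) { flags <- c(flags, "lr_pos_infinite"); Inf }
    else sens / (1 - spec)
  lrNeg <- (1 - sens) / spec
  list(sensitivity = sens, specificity = spec,
       accuracy = (cm@tp + cm@tn) / total,
       fnRate = 1 - sens, fpRate = 1 - spec,
       lrPos = lrPos, lrNeg = lrNeg, flags = flags)
}

#' Format a metrics report for printing
#'
#' Percentages to the nearest integer, likelihood ratios to two decimals.
#'
#' @param m output of [classificationMetrics()].
#' @return named character vector.
#' @export
formatMetrics <- function(m) {
  pc <- function(x) sprintf("%d%%", round(100 * x))
  c(sensitivity = pc(m$sensitivity), specificity = pc(m$specificity),
    accuracy = pc(m$accuracy), fn_rate = pc(m$fnRate),
    fp_rate = pc(m$fpRate),
    lr_pos = if (is.infinite(m$lrPos)) "Inf" else sprintf("%.2f", m$lrPos),
    lr_neg = sprintf("%.2f", m$lrNeg))
}

#' Dice similarity coefficient of two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; two empty masks are defined to agree
#' perfectly (Dice 1).
#'
#' @param a,b binary [LabelVolume-class] masks on the same grid, or
#'   logical/0-1 arrays.
#' @return Dice in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  if (is(a, "BrainVolume")) a <- a@data
  if (is(b, "BrainVolume")) b <- b@data
  if (!identical(dim(a), dim(b)))
    stop("mask grids differ", call. = FALSE)
  a <- a > 0; b <- b > 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Pearson correlation of paired volume measurements
#'
#' @param volsA,volsB equal-length numeric vectors (n >= 3) with nonzero
#'   variance.
#' @return Pearson r.
#' @export
volumeCorrelation <- function(volsA, volsB) {
  if (length(volsA) != length(volsB) || length(volsA) < 3)
    stop("need at least 3 paired volumes", call. = FALSE)
  if (sd(volsA) == 0 || sd(volsB) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  cor(volsA, volsB)
}

#' Two-group comparison with Bonferroni correction
#'
#' Welch two-sample t-test by default (set \code{varEqual = TRUE} for the
#' pooled-variance version); the corrected p-value is
#' \code{min(1, nComparisons * p)}.
#'
#' @param x,y numeric samples (each n >= 2).
#' @param nComparisons number of comparisons in the family.
#' @param varEqual pool the variances.
#' @return list with \code{t}, \code{pRaw}, \code{pBonferroni},
#'   \code{meanX}, \code{meanY}, \code{flags}.
#' @export
groupCompare <- function(x, y, nComparisons = 1, varEqual = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2, nComparisons >= 1)
  flags <- character()
  if (sd(x) == 0 && sd(y) == 0) {
    flags <- "degenerate_variance"
    if (mean(x) == mean(y))
      return(list(t = 0, pRaw = 1, pBonferroni = 1,
                  meanX = mean(x), meanY = mean(y), flags = flags))
    return(list(t = sign(mean(x) - mean(y)) * Inf, pRaw = 0,
                pBonferroni = 0, meanX = mean(x), meanY = mean(y),
                flags = flags))
  }
  tt <- t.test(x, y, var.equal = varEqual)
  list(t = unname(tt$statistic), pRaw = tt$p.value,
       pBonferroni = min(1, nComparisons * tt$p.value),
       meanX = mean(x), meanY = mean(y), flags = flags)
}

#' Compare misclassified against correctly classified subjects
#'
#' For the TP-vs-FN stratum (within true positives) and the FP-vs-TN
#' stratum (within true negatives), reports per-feature group means,
#' standard deviations and Bonferroni-corrected Welch t-tests. Strata with
#' fewer than two subjects in either cell are skipped with a warning.
#'
#' @param features data.frame of per-subject features.
#' @param truth,predictions binary label vectors (see
#'   [confusionCounts()]).
#' @param featureCols feature columns to compare (default: all numeric).
#' @return data.frame with one row per stratum x feature.
#' @export
misclassificationReport <- function(features, truth, predictions,
                                    featureCols = NULL) {
  t <- asPositive(truth)
  p <- asPositive(predictions)
  if (is.null(featureCols))
    featureCols <- names(features)[vapply(features, is.numeric, TRUE)]
  m <- length(featureCols)
  strata <- list(
    TP_vs_FN = list(a = t & p, b = t & !p),
    FP_vs_TN = list(a = !t & p, b = !t & !p))
  out <- list()
  for (s in names(strata)) {
    ia <- strata[[s]]$a; ib <- strata[[s]]$b
    if (sum(ia) < 2 || sum(ib) < 2) {
      warning(sprintf("stratum %s skipped: fewer than 2 subjects per cell",
                      s), call. = FALSE)
      next
    }
    for (f in featureCols) {
      a <- features[[f]][ia]; b <- features[[f]][ib]
      gc <- groupCompare(a, b, nComparisons = m)
      out[[length(out) + 1]] <- data.frame(
        stratum = s, feature = f, n_a = sum(ia), n_b = sum(ib),
        mean_a = mean(a), sd_a = sd(a), mean_b = mean(b), sd_b = sd(b),
        t = gc$t, p_raw = gc$pRaw, p_bonferroni = gc$pBonferroni)
    }
  }
  if (!length(out))
    return(data.frame(stratum = character(), feature = character()))
  do.call(rbind, out)
}
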