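#' Canonical feature order of the classifier
#'
#' @return character vector naming the six features in their fixed order.
#' @export
classifierFeatures <- function() {
  c("apr_log", "total_vv_norm", "lr_frontal_log", "lr_temporal_log",
    "age", "sex")
}

# coerce a data.frame / matrix to the fixed-order feature matrix
asFeatureMatrix <- function(X, featureNames = classifierFeatures()) {
  if (is.data.frame(X)) {
    missing <- setdiff(featureNames, names(X))
    if (length(missing))
      stop("feature table is missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    X <- as.matrix(X[, featureNames, drop = FALSE])
  } else {
    X <- as.matrix(X)
    if (ncol(X) != length(featureNames))
      stop(sprintf("expected %d features, got %d", length(featureNames),
                   ncol(X)), call. = FALSE)
    colnames(X) <- featureNames
  }
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  X
}

#' Train the linear support-vector classifier
#'
#' Features are z-scored with training statistics, then a soft-margin
#' linear SVM is fitted (hinge loss, penalty \code{cost}); the linear
#' decision function is extracted so that prediction is a plain
#' \eqn{w \cdot z(x) + b}. With \code{classWeights = TRUE} classes are
#' weighted inversely to their frequency, which matters for the heavily
#' imbalanced clinical cohorts this screens.
#'
#' @param X feature matrix or data.frame (columns per
#'   [classifierFeatures()]).
#' @param y binary labels; \code{TRUE}/\code{"bvFTD"} is the positive
#'   class.
#' @param cost soft-margin penalty C.
#' @param classWeights use inverse-frequency class weights.
#' @param seed stored in the model metadata (the fit itself is
#'   deterministic).
#' @return An [SVMModel-class].
#' @export
trainClassifier <- function(X, y, cost = 1, classWeights = TRUE, seed = 1L) {
  X <- asFeatureMatrix(X)
  y <- asPositive(y)
  if (nrow(X) < 4) stop("insufficient data: need at least 4 samples",
                        call. = FALSE)
  if (length(unique(y)) < 2)
    stop("training requires both classes", call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl <= 0] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  cw <- if (classWeights) {
    n <- table(yf)
    w <- length(yf) / (2 * n)
    setNames(as.numeric(w), names(n))
  } else NULL
  fit <- e1071::svm(Z, yf, kernel = "linear", cost = cost, scale = FALSE,
                    class.weights = cw)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # orient the decision function so positive scores mean the positive class
  sc <- Z %*% w + b
  if (mean(sc[y]) < mean(sc[!y])) { w <- -w; b <- -b }
  new("SVMModel", featureNames = colnames(X), center = ctr, scale = scl,
      weights = as.numeric(w), bias = b, cost = cost,
      classWeights = classWeights,
      nPos = sum(y), nNeg = sum(!y), seed = as.integer(seed))
}

# normalize assorted label encodings to logical (positive = bvFTD)
asPositive <- function(y) {
  if (is.logical(y)) return(y)
  if (is.factor(y)) y <- as.character(y)
  if (is.numeric(y)) return(y > 0)
  tolower(y) %in% c("bvftd", "bvftd_compatible", "pos", "positive", "1",
                    "true")
}

#' Predict with a trained classifier
#'
#' @param model an [SVMModel-class].
#' @param x feature matrix, data.frame or single numeric vector in the
#'   model's feature order.
#' @return data.frame with \code{score} (signed margin surrogate
#'   \eqn{w \cdot z(x) + b}) and \code{label}
#'   (\code{"bvFTD_compatible"} iff score >= 0; ties are positive).
#' @export
predictClassifier <- function(model, x) {
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, nrow = 1)
  X <- asFeatureMatrix(x, model@featureNames)
  Z <- sweep(sweep(X, 2, model@center), 2, model@scale, "/")
  score <- drop(Z %*% model@weights) + model@bias
  data.frame(score = score,
             label = ifelse(score >= 0, "bvFTD_compatible",
                            "not_compatible"))
}

#' Deterministic k-fold cross-validated accuracy
#'
#' @param X,y as [trainClassifier()].
#' @param folds number of folds.
#' @param seed fold-assignment seed.
#' @param ... passed to [trainClassifier()].
#' @return mean held-out accuracy across folds.
#' @export
crossValidate <- function(X, y, folds = 5, seed = 1, ...) {
  X <- asFeatureMatrix(X)
  y <- asPositive(y)
  n <- nrow(X)
  assign <- withSeed(seed, sample(rep_len(seq_len(folds), n)))
  acc <- vapply(seq_len(folds), function(f) {
    tr <- assign != f
    if (length(unique(y[tr])) < 2) return(NA_real_)
    m <- trainClassifier(X[tr, , drop = FALSE], y[tr], ...)
    p <- predictClassifier(m, X[!tr, , drop = FALSE])
    mean((p$label == "bvFTD_compatible") == y[!tr])
  }, numeric(1))
  mean(acc, na.rm = TRUE)
}

modelFormatVersion <- 1L

#' Save / load a classifier model as portable text
#'
#' The format is a human-readable key-value file with a format-version
#' header; round-tripping preserves predictions bit-for-bit. Unknown keys
#' load with a warning; a missing required key or an unsupported version is
#' an error.
#'
#' @param model an [SVMModel-class].
#' @param path model file path.
#' @return \code{saveModel}: the path, invisibly. \code{loadModel}: an
#'   [SVMModel-class].
#' @export
saveModel <- function(model, path) {
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    sprintf("format_version: %d", modelFormatVersion),
    sprintf("feature_names: %s", paste(model@featureNames, collapse = ",")),
    sprintf("center: %s", paste(num(model@center), collapse = ",")),
    sprintf("scale: %s", paste(num(model@scale), collapse = ",")),
    sprintf("weights: %s", paste(num(model@weights), collapse = ",")),
    sprintf("bias: %s", num(model@bias)),
    sprintf("cost: %s", num(model@cost)),
    sprintf("class_weights: %s", model@classWeights),
    sprintf("n_pos: %d", model@nPos),
    sprintf("n_neg: %d", model@nNeg),
    sprintf("seed: %d", model@seed))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+):\\s*(.*)$", lines))
  if (any(lengths(kv) != 3))
    stop("cannot parse model file (malformed line)", call. = FALSE)
  keys <- vapply(kv, `[`, "", 2)
  vals <- vapply(kv, `[`, "", 3)
  required <- c("format_version", "feature_names", "center", "scale",
                "weights", "bias")
  missing <- setdiff(required, keys)
  if (length(missing))
    stop("truncated or invalid model file; missing key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(keys, c(required, "cost", "class_weights", "n_pos",
                           "n_neg", "seed"))
  if (length(extra))
    warning("ignoring unknown model file key(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  get <- function(k, default = NA) if (k %in% keys) vals[match(k, keys)]
    else default
  ver <- as.integer(get("format_version"))
  if (is.na(ver) || ver != modelFormatVersion)
    stop(sprintf("unsupported model format version: %s",
                 get("format_version")), call. = FALSE)
  nums <- function(k) as.numeric(strsplit(get(k), ",")[[1]])
  fn <- strsplit(get("feature_names"), ",")[[1]]
  ctr <- nums("center"); scl <- nums("scale"); w <- nums("weights")
  if (anyNA(ctr) || anyNA(scl) || anyNA(w) ||
      length(ctr) != length(fn) || length(scl) != length(fn) ||
      length(w) != length(fn))
    stop("corrupt model file: numeric blocks do not match feature names",
         call. = FALSE)
  new("SVMModel", featureNames = fn, center = setNames(ctr, fn),
      scale = setNames(scl, fn), weights = w,
      bias = as.numeric(get("bias")),
      cost = as.numeric(get("cost", "1")),
      classWeights = as.logical(get("class_weights", "TRUE")),
      nPos = as.integer(get("n_pos", "0")),
      nNeg = as.integer(get("n_neg", "0")),
      seed = as.integer(get("seed", "0")))
}

# evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
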