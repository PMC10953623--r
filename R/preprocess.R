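#' Registration parameter set
#'
#' @param levels multiresolution pyramid depth.
#' @param dof degrees of freedom: 6 (rigid), 9 (rigid + anisotropic scale)
#'   or 12 (full affine).
#' @param maxIter optimizer iteration cap per pyramid level.
#' @param tol relative convergence tolerance on the similarity metric.
#' @return list of class \code{RegistrationParams}.
#' @export
registrationParams <- function(levels = 3, dof = 12, maxIter = 200,
                               tol = 1e-5) {
  stopifnot(levels >= 1, dof %in% c(6, 9, 12), maxIter >= 1, tol > 0)
  structure(list(levels = levels, dof = dof, maxIter = maxIter, tol = tol),
            class = "RegistrationParams")
}

#' Intensity normalization with polynomial bias-field removal
#'
#' Estimates a multiplicative low-order polynomial bias field on
#' brain-intensity voxels (a band around the modal brain intensity, fitted
#' on the log scale), divides it out, then clamps at the 0.1 and 99.9
#' percentiles and linearly rescales to \code{[0, 100]}. The result is
#' invariant to global intensity scaling of the input.
#'
#' @param img a [BrainVolume-class] with non-constant intensities.
#' @param biasDegree polynomial degree of the bias model (0 disables
#'   correction; maximum 2).
#' @return A [BrainVolume-class] on the same grid, intensities in [0, 100].
#' @export
normalizeIntensity <- function(img, biasDegree = 2) {
  x <- img@data
  rng <- range(x)
  if (diff(rng) <= 0)
    stop("constant image: cannot normalize", call. = FALSE)
  stopifnot(biasDegree %in% 0:2)
  if (biasDegree > 0) {
    p999 <- quantile(x, 0.999, names = FALSE)
    brain <- which(x > 0.2 * p999)
    if (length(brain) > 100) {
      # modal brain intensity from a coarse histogram; fit the bias on the
      # +-25% band around it so one tissue class dominates the regression
      b <- x[brain]
      h <- hist(b, breaks = 64, plot = FALSE)
      mode <- h$mids[which.max(h$counts)]
      band <- brain[b > 0.75 * mode & b < 1.25 * mode & b > 0]
      if (length(band) > 200) {
        sel <- band[seq(1, length(band),
                        length.out = min(length(band), 50000))]
        d <- dim(x)
        ijk <- arrayInd(sel, d) - 1
        w <- voxelToWorld(img@affine, ijk)
        sc <- max(abs(w)) + 1e-9
        u <- w[, 1] / sc; v <- w[, 2] / sc; t <- w[, 3] / sc
        X <- cbind(1, u, v, t)
        if (biasDegree == 2)
          X <- cbind(X, u * u, v * v, t * t, u * v, u * t, v * t)
        fit <- lm.fit(X, log(x[sel]))
        cf <- fit$coefficients
        cf[is.na(cf)] <- 0
        # evaluate the fitted log-bias on the full grid
        wa <- worldAxis(img, 1) / sc
        wb <- worldAxis(img, 2) / sc
        wc <- worldAxis(img, 3) / sc
        lb <- cf[1] + cf[2] * wa + cf[3] * wb + cf[4] * wc
        if (biasDegree == 2)
          lb <- lb + cf[5] * wa^2 + cf[6] * wb^2 + cf[7] * wc^2 +
            cf[8] * wa * wb + cf[9] * wa * wc + cf[10] * wb * wc
        lb <- lb - mean(lb[sel])          # unit mean bias over the fit set
        x <- x / exp(lb)
      }
    }
  }
  q <- quantile(x, c(0.001, 0.999), names = FALSE)
  if (q[2] <= q[1]) q <- range(x)
  x <- pmin(pmax(x, q[1]), q[2])
  x <- (x - q[1]) / (q[2] - q[1]) * 100
  brainVolume(array(x, dim = dim(img@data)), img@affine)
}

# block-mean downsampling by integer factor f, with the affine updated so
# voxel centres keep their world positions
downsampleVolume <- function(vol, f) {
  if (f == 1) return(vol)
  d <- dim(vol@data)
  nd <- d %/% f
  x <- vol@data[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f)]
  dim(x) <- c(f, nd[1], f, nd[2], f, nd[3])
  x <- apply(x, c(2, 4, 6), mean)
  a <- vol@affine
  a2 <- a
  a2[1:3, 1:3] <- a[1:3, 1:3] * f
  a2[1:3, 4] <- a[1:3, 4] + a[1:3, 1:3] %*% rep((f - 1) / 2, 3)
  brainVolume(x, a2)
}

# 12-parameter vector -> 4x4 world transform about centre c:
# p = (tx ty tz, rx ry rz [rad], log sx sy sz, hxy hxz hyz)
paramsToMatrix <- function(p, centre) {
  t <- p[1:3]; r <- p[4:6]; s <- exp(p[7:9]); h <- p[10:12]
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Sh <- rbind(c(1, h[1], h[2]), c(0, 1, h[3]), c(0, 0, 1))
  M3 <- Rz %*% Ry %*% Rx %*% diag(s) %*% Sh
  M <- diag(4)
  M[1:3, 1:3] <- M3
  M[1:3, 4] <- centre + t - M3 %*% centre
  M
}

# intensity-weighted first and second spatial moments in world mm
imageMoments <- function(vol) {
  x <- vol@data
  x <- pmax(x - quantile(x, 0.5, names = FALSE), 0)
  if (sum(x) <= 0) x <- array(1, dim(vol@data))
  w <- sum(x)
  com <- numeric(3); spread <- numeric(3)
  for (ax in 1:3) {
    wa <- worldAxis(vol, ax)
    com[ax] <- sum(wa * x) / w
    spread[ax] <- sqrt(sum((wa - com[ax])^2 * x) / w)
  }
  list(com = com, spread = spread)
}

centreOfMass <- function(vol) imageMoments(vol)$com

#' Affine registration to the stereotaxic template
#'
#' Coarse-to-fine maximization of the normalized cross-correlation between
#' the template and the resampled moving image, over a rigid (6), similarity
#' (9) or full affine (12 dof) world transform. Initialization aligns the
#' intensity centres of mass. Deterministic given identical inputs and
#' parameters.
#'
#' @param moving,template intensity-normalized [BrainVolume-class] objects.
#' @param params a [registrationParams()] list.
#' @return An [AffineTransform-class] mapping native world to template
#'   world; \code{converged = FALSE} (with a warning) flags a
#'   low-confidence result.
#' @export
registerAffine <- function(moving, template, params = registrationParams()) {
  stopifnot(inherits(params, "RegistrationParams"))
  mT <- imageMoments(template)
  mM <- imageMoments(moving)
  centre <- mT$com
  p <- numeric(12)
  p[1:3] <- mT$com - mM$com
  # moment-based scale initialization (refined by the optimizer)
  if (params$dof >= 9) p[7:9] <- log(mT$spread / mM$spread)
  nAct <- c(`6` = 6L, `9` = 9L, `12` = 12L)[as.character(params$dof)]
  act <- seq_len(nAct)
  parscale <- c(rep(5, 3), rep(0.05, 3), rep(0.05, 3), rep(0.02, 3))
  movA <- moving@affine
  conv <- TRUE
  metric <- NA_real_
  for (lev in seq_len(params$levels)) {
    f <- 2^(params$levels - lev)
    tl <- downsampleVolume(template, f)
    ml <- downsampleVolume(moving, f)
    td <- tl@data
    mask <- which(td > 0.02 * max(td))
    tRef <- td[mask]
    mlA <- ml@affine
    tlA <- tl@affine
    obj <- function(q) {
      pp <- p
      pp[act] <- q
      Tm <- paramsToMatrix(pp, centre)
      M <- solve(mlA) %*% solve(Tm) %*% tlA
      res <- .cpp_resample(as.numeric(ml@data), dim(ml@data), M,
                           dim(td), 0L)
      v <- res[mask]
      if (sd(v) < 1e-12) return(1)
      -cor(v, tRef)
    }
    opt <- optim(p[act], obj, method = "Nelder-Mead",
                 control = list(maxit = params$maxIter, reltol = params$tol,
                                parscale = parscale[act]))
    p[act] <- opt$par
    metric <- -opt$value
    if (lev == params$levels && opt$convergence != 0) {
      # iteration cap hit: a short simplex restart tests whether the
      # optimum is stationary to within tol before flagging low confidence
      re <- optim(p[act], obj, method = "Nelder-Mead",
                  control = list(maxit = 50, reltol = params$tol,
                                 parscale = parscale[act]))
      improvement <- (opt$value - re$value) / max(abs(opt$value), 1e-12)
      p[act] <- re$par
      metric <- -re$value
      if (improvement > 10 * params$tol) {
        conv <- FALSE
        warning("registration did not converge at the finest level; ",
                "returning best-found transform (low confidence)",
                call. = FALSE)
      }
    }
  }
  new("AffineTransform", matrix = paramsToMatrix(p, centre),
      converged = conv, metric = metric)
}

#' Resample a native volume onto the template grid
#'
#' @param img a [BrainVolume-class] (trilinear interpolation) or
#'   [LabelVolume-class] (nearest-neighbour).
#' @param t native-to-template [AffineTransform-class].
#' @param template [BrainVolume-class] defining the output grid.
#' @param nearest force nearest-neighbour interpolation.
#' @return Volume of the same class as \code{img} on the template grid;
#'   out-of-field voxels are 0.
#' @export
resampleToTemplate <- function(img, t, template, nearest = NULL) {
  if (is.null(nearest)) nearest <- is(img, "LabelVolume")
  M <- solve(img@affine) %*% solve(t@matrix) %*% template@affine
  res <- .cpp_resample(as.numeric(img@data), dim(img@data), M,
                       dim(template@data), as.integer(nearest))
  arr <- array(res, dim(template@data))
  if (is(img, "LabelVolume")) labelVolume(arr, template@affine)
  else brainVolume(arr, template@affine)
}

#' Estimate subject intracranial volume from the registration transform
#'
#' The native-space ICV is the template ICV mask volume divided by the
#' transform's volume scaling factor (the back-projected template mask).
#' Exactly homogeneous: doubling \code{scaleDet} halves the ICV.
#'
#' @param t native-to-template [AffineTransform-class].
#' @param templateIcvMask template-space binary [LabelVolume-class].
#' @return ICV in mm^3.
#' @export
estimateICV <- function(t, templateIcvMask) {
  sdet <- scaleDet(t)
  if (!(sdet > 0)) stop("invalid transform: |det| must be > 0",
                        call. = FALSE)
  sum(templateIcvMask@data > 0) * voxelVolume(templateIcvMask) / sdet
}
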