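# Independent brute-force oracles, deliberately written as plain per-voxel
# loops so they share no code path with the package implementation.

# patch-based label fusion by exhaustive triple loop over candidates
bruteFusion <- function(target, libImgs, libLabs, cand, pr, sr,
                        sigma = 0.95, eps = 1e-4) {
  d <- dim(target)
  patchRange <- function(c, lim) max(1, c - pr):min(lim, c + pr)
  stats <- function(arr, i, j, k) {
    v <- arr[patchRange(i, d[1]), patchRange(j, d[2]), patchRange(k, d[3])]
    m <- mean(v)
    va <- mean(v^2) - m^2
    c(m, if (va > 0) sqrt(va) else 0)
  }
  vote <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!cand[i, j, k]) next
    st <- stats(target, i, j, k)
    dists <- c(); labs <- c(); allLabs <- c()
    for (l in seq_along(libImgs)) {
      A <- libImgs[[l]]; L <- libLabs[[l]]
      for (oz in -sr:sr) for (oy in -sr:sr) for (ox in -sr:sr) {
        ci <- i + ox; cj <- j + oy; ck <- k + oz
        if (ci < 1 || ci > d[1] || cj < 1 || cj > d[2] ||
            ck < 1 || ck > d[3]) next
        allLabs <- c(allLabs, L[ci, cj, ck])
        sl <- stats(A, ci, cj, ck)
        c1 <- 1e-6; c2 <- 1e-6
        ss <- ((2 * st[1] * sl[1] + c1) / (st[1]^2 + sl[1]^2 + c1)) *
          ((2 * st[2] * sl[2] + c2) / (st[2]^2 + sl[2]^2 + c2))
        if (ss < sigma) next
        dd <- 0
        for (qz in -pr:pr) for (qy in -pr:pr) for (qx in -pr:pr) {
          ti <- i + qx; tj <- j + qy; tk <- k + qz
          li <- ci + qx; lj <- cj + qy; lk <- ck + qz
          if (ti < 1 || ti > d[1] || tj < 1 || tj > d[2] ||
              tk < 1 || tk > d[3]) next
          if (li < 1 || li > d[1] || lj < 1 || lj > d[2] ||
              lk < 1 || lk > d[3]) next
          dd <- dd + (target[ti, tj, tk] - A[li, lj, lk])^2
        }
        dists <- c(dists, dd)
        labs <- c(labs, L[ci, cj, ck])
      }
    }
    if (length(dists) == 0) {
      vote[i, j, k] <- if (length(allLabs)) mean(allLabs) else 0
    } else {
      h2 <- min(dists) + eps
      w <- exp(-dists / h2)
      vote[i, j, k] <- sum(w * labs) / sum(w)
    }
  }
  vote
}

# anterior/posterior voxel counts by per-voxel world-coordinate check
bruteSplitCounts <- function(maskArr, affine, ySplit = -12) {
  d <- dim(maskArr)
  ant <- 0; post <- 0
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (maskArr[i, j, k] == 0) next
    w <- affine %*% c(i - 1, j - 1, k - 1, 1)
    if (w[2] > ySplit) ant <- ant + 1 else post <- post + 1
  }
  c(anterior = ant, posterior = post)
}

# confusion counts by a hand loop
bruteConfusion <- function(truth, pred) {
  tp <- fn <- fp <- tn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] && pred[i]) tp <- tp + 1
    else if (truth[i] && !pred[i]) fn <- fn + 1
    else if (!truth[i] && pred[i]) fp <- fp + 1
    else tn <- tn + 1
  }
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

# small toy library on an arbitrary grid: blob labels + structured noise
makeToyLibrary <- function(d, k = 2, seed = 5) {
  withr::with_seed(seed, {
    centre <- (d - 1) / 2
    imgs <- list(); labs <- list()
    for (l in seq_len(k)) {
      lab <- array(0, d)
      r <- min(d) / 3 + (l - 1) * 0.5
      for (kk in seq_len(d[3])) for (jj in seq_len(d[2]))
        for (ii in seq_len(d[1]))
          if (sum((c(ii, jj, kk) - 1 - centre)^2) <= r^2)
            lab[ii, jj, kk] <- 1
      img <- 20 + 60 * lab + array(rnorm(prod(d), sd = 4), d)
      imgs[[l]] <- img
      labs[[l]] <- lab
    }
    list(images = imgs, labels = labs)
  })
}
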