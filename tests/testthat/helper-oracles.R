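# Independent brute-force oracles used to freeze expected values.

# type-7 quantile by hand: linear interpolation between order statistics
quantileOracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- pmin(lo + 1, n)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# bias-corrected Fisher-Pearson sample skewness by definition
skewnessOracle <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  g1 <- m3 / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# definitional 3x3x3 erosion: voxel kept iff its whole neighbourhood
# (including out-of-bounds treated as background) is inside the mask
erodeOracle <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    keep <- TRUE
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || jj < 1 || kk < 1 ||
          ii > d[1] || jj > d[2] || kk > d[3] || !mask[ii, jj, kk]) {
        keep <- FALSE
      }
    }
    out[i, j, k] <- keep && mask[i, j, k]
  }
  out
}

# Welch statistic from the textbook formulae
welchOracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  dof <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  c(t = t, dof = dof, p = 2 * pt(-abs(t), dof))
}

# BH step-up by definition: largest i with p(i) <= i*q/m is the cut;
# adjusted p by the min-over-larger-ranks rule
bhOracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  cand <- which(ps <= seq_len(m) * q / m)
  reject <- rep(FALSE, m)
  if (length(cand)) reject[ord[seq_len(max(cand))]] <- TRUE
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  list(adjusted = adj[order(ord)], reject = reject)
}

# dense-matrix GP posterior by direct solve(), independent of the
# Cholesky path used in the package
gpOracle <- function(model, newAges) {
  h <- kernelHyperparameters(model)
  x <- model@xTrain; y <- model@yTrain
  kern <- function(a, b) {
    h[["sigma2_se"]] * exp(-0.5 * outer(a, b, `-`)^2 / h[["lengthscale"]]^2) +
      h[["sigma2_lin"]] * outer(a, b)
  }
  K <- kern(x, x) + (h[["sigma2_noise"]] + 1e-10) * diag(length(x))
  xs <- (newAges - model@xMean) / model@xSd
  Ks <- kern(x, xs)
  Kinv <- solve(K)
  mu <- drop(t(Ks) %*% Kinv %*% y)
  varp <- h[["sigma2_se"]] + h[["sigma2_lin"]] * xs^2 -
    diag(t(Ks) %*% Kinv %*% Ks) + h[["sigma2_noise"]]
  list(mean = mu * model@ySd + model@yMean, sd = sqrt(varp) * model@ySd)
}

# unit-scale two-network trajectory table used by network-recovery tests
unitNetworkSpecs <- function(noiseSd = 1, loading = 1) {
  roisA <- c("Cau", "Pu")
  roisB <- c("GPe", "GPi", "SNc", "SNr", "RN", "STN", "VP")
  trajectorySpec(roi = c(roisA, roisB), metric = "R2star",
                 intercept = 0, betaAge = 0.02,
                 noiseSd0 = noiseSd,
                 networkId = rep(c("A", "B"), c(length(roisA), length(roisB))),
                 networkLoading = loading)
}
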