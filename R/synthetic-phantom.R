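#' Specification of an ellipsoidal voxel phantom
#'
#' Defines a 3D grid with one or more non-overlapping ellipsoidal ROIs,
#' each carrying a planted first-order spatial field
#' `p0 + p1 (x - x0) + p2 (y - y0) + p3 (z - z0)` (mm coordinates) plus
#' optional Gaussian noise. Used as the test bed for spatial-gradient
#' fitting.
#'
#' @param gridShape integer length-3 voxel grid dimensions.
#' @param voxelSize voxel edge length in mm (scalar or length 3).
#' @param roiCentres k x 3 matrix of ellipsoid centres (mm).
#' @param roiSemiaxes k x 3 matrix of semi-axes (mm); each semi-axis must
#'   span at least 3 voxels so a one-voxel erosion leaves a core.
#' @param gradientTruth k x 3 matrix of planted gradients (units/mm).
#' @param meanTruth length-k constant terms (units).
#' @param noiseSd additive Gaussian noise SD (units).
#' @return a list of class `"VoxelPhantomSpec"`.
#' @export
voxelPhantomSpec <- function(gridShape = c(40, 40, 40), voxelSize = 1,
                             roiCentres, roiSemiaxes, gradientTruth,
                             meanTruth, noiseSd = 0) {
  roiCentres <- rbind(roiCentres)
  roiSemiaxes <- rbind(roiSemiaxes)
  gradientTruth <- rbind(gradientTruth)
  k <- nrow(roiCentres)
  stopifnot(length(gridShape) == 3, nrow(roiSemiaxes) == k,
            nrow(gradientTruth) == k, length(meanTruth) == k, noiseSd >= 0)
  vs <- rep_len(voxelSize, 3)
  if (any(sweep(roiSemiaxes, 2, 3 * vs, `<`)))
    stop("each semi-axis must span at least 3 voxels")
  lo <- roiCentres - roiSemiaxes
  hi <- roiCentres + roiSemiaxes
  ext <- (gridShape - 1) * vs
  if (any(lo < 0) || any(sweep(hi, 2, ext, `>`)))
    stop("ellipsoids must fit inside the grid")
  structure(list(gridShape = as.integer(gridShape), voxelSize = vs,
                 roiCentres = roiCentres, roiSemiaxes = roiSemiaxes,
                 gradientTruth = gradientTruth, meanTruth = meanTruth,
                 noiseSd = noiseSd),
            class = "VoxelPhantomSpec")
}

#' Generate a voxel phantom with planted spatial gradients
#'
#' Builds the label map and quantitative map described by a
#' [voxelPhantomSpec()]. Inside ROI `k` the value is
#' `p0 + p . (r - r0) + noise`, where `r` is the voxel position in mm (via
#' the RAS affine) and `r0` the ROI's voxel centre of mass; the background
#' is 0 and labels are the integers `1..k`.
#'
#' @param spec a [voxelPhantomSpec()].
#' @param seed RNG seed for the noise draw.
#' @return a list with `map` (numeric 3D array), `labels` (integer 3D
#'   array) and `affine` (4 x 4 voxel-to-mm matrix, RAS, 0-based indices).
#' @examples
#' spec <- voxelPhantomSpec(c(20, 20, 20), 1, c(9, 9, 9), c(5, 5, 5),
#'                          c(2, 0, 0), meanTruth = 10)
#' ph <- generateVoxelPhantom(spec, seed = 1)
#' table(ph$labels)
#' @export
generateVoxelPhantom <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "VoxelPhantomSpec"))
  set.seed(seed)
  d <- spec$gridShape
  vs <- spec$voxelSize
  affine <- diag(c(vs, 1))
  # mm coordinates of every voxel (0-based indices)
  ix <- (seq_len(d[1]) - 1) * vs[1]
  iy <- (seq_len(d[2]) - 1) * vs[2]
  iz <- (seq_len(d[3]) - 1) * vs[3]
  X <- array(rep(ix, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(iy, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(iz, each = d[1] * d[2]), dim = d)

  labels <- array(0L, dim = d)
  map <- array(0, dim = d)
  for (k in seq_len(nrow(spec$roiCentres))) {
    c0 <- spec$roiCentres[k, ]; ax <- spec$roiSemiaxes[k, ]
    inside <- ((X - c0[1]) / ax[1])^2 + ((Y - c0[2]) / ax[2])^2 +
      ((Z - c0[3]) / ax[3])^2 <= 1
    if (any(labels[inside] != 0L))
      stop("ellipsoidal ROIs overlap (labels ", k, " and ",
           labels[inside][labels[inside] != 0L][1], ")")
    labels[inside] <- k
    com <- c(mean(X[inside]), mean(Y[inside]), mean(Z[inside]))
    g <- spec$gradientTruth[k, ]
    map[inside] <- spec$meanTruth[k] +
      g[1] * (X[inside] - com[1]) + g[2] * (Y[inside] - com[2]) +
      g[3] * (Z[inside] - com[3])
  }
  if (spec$noiseSd > 0) {
    roiVox <- labels != 0L
    map[roiVox] <- map[roiVox] + rnorm(sum(roiVox), 0, spec$noiseSd)
  }
  list(map = map, labels = labels, affine = affine)
}

#' Simulate MP2RAGE inversion images from ground-truth R1 and B1
#'
#' Forward counterpart of the dictionary-matching estimator: per voxel,
#' the complex-valued signal pair (S_TI1, S_TI2) is evaluated with the
#' steady-state model at the protocol timing, flip angles scaled by the
#' true B1 fraction, plus independent complex Gaussian noise of SD
#' `noiseSd` per real/imaginary channel. `m0` is fixed to 1 by default
#' since the matching removes the overall scale.
#'
#' @param r1Truth ground-truth R1 values (1/s), any shape.
#' @param b1Truth ground-truth B1 fractions (recycled).
#' @param protocol an [MP2RAGEProtocol-class].
#' @param noiseSd complex-channel noise SD.
#' @param seed RNG seed.
#' @param m0 overall signal scale.
#' @return list with complex vectors/arrays `S1`, `S2` shaped like
#'   `r1Truth`.
#' @export
generateMP2RAGESignals <- function(r1Truth, b1Truth = 1,
                                   protocol = mp2rageProtocol(),
                                   noiseSd = 0, seed = 1, m0 = 1) {
  if (any(r1Truth <= 0)) stop("r1Truth must be positive")
  if (any(b1Truth <= 0)) stop("b1Truth must be positive")
  dm <- dim(r1Truth)
  s <- mp2rageForward(as.vector(r1Truth), as.vector(b1Truth), protocol,
                      m0 = m0)
  S1 <- as.complex(s$S1); S2 <- as.complex(s$S2)
  if (noiseSd > 0) {
    set.seed(seed)
    n <- length(S1)
    S1 <- S1 + complex(real = rnorm(n, 0, noiseSd),
                       imaginary = rnorm(n, 0, noiseSd))
    S2 <- S2 + complex(real = rnorm(n, 0, noiseSd),
                       imaginary = rnorm(n, 0, noiseSd))
  }
  if (!is.null(dm)) { dim(S1) <- dm; dim(S2) <- dm }
  list(S1 = S1, S2 = S2)
}
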