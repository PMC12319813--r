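#' MP2RAGE acquisition protocol
#'
#' Timing and flip-angle parameters of a double-inversion MP2RAGE sequence,
#' required by the steady-state signal model. Times are in milliseconds,
#' flip angles in degrees.
#'
#' @slot TI1,TI2 inversion times of the two GRE blocks (ms).
#' @slot TR repetition time of one full MP2RAGE cycle (ms).
#' @slot alpha1,alpha2 nominal excitation flip angles of the two blocks (deg).
#' @slot readoutTR repetition time of one excitation within a GRE block (ms).
#' @slot nReadout number of excitations per GRE block.
#' @slot inversionEfficiency longitudinal inversion efficiency (fraction).
#'
#' @seealso [mp2rageProtocol()], [mp2rageForward()]
#' @export
setClass("MP2RAGEProtocol",
  representation(
    TI1 = "numeric", TI2 = "numeric", TR = "numeric",
    alpha1 = "numeric", alpha2 = "numeric",
    readoutTR = "numeric", nReadout = "numeric",
    inversionEfficiency = "numeric"
  )
)

setValidity("MP2RAGEProtocol", function(object) {
  msg <- character(0)
  if (!(object@TI1 > 0 && object@TI1 < object@TI2 && object@TI2 < object@TR))
    msg <- c(msg, "timing must satisfy 0 < TI1 < TI2 < TR")
  if (!(object@alpha1 > 0 && object@alpha1 < 90 &&
        object@alpha2 > 0 && object@alpha2 < 90))
    msg <- c(msg, "flip angles must lie in (0, 90) degrees")
  if (object@readoutTR <= 0 || object@nReadout < 1)
    msg <- c(msg, "readoutTR must be > 0 and nReadout >= 1")
  if (object@inversionEfficiency <= 0 || object@inversionEfficiency > 1)
    msg <- c(msg, "inversionEfficiency must lie in (0, 1]")
  # the two GRE blocks plus recovery periods must fit within one cycle
  blk <- object@nReadout * object@readoutTR
  ta <- object@TI1 - blk / 2
  tb <- object@TI2 - object@TI1 - blk
  tc <- object@TR - object@TI2 - blk / 2
  if (length(msg) == 0 && (ta < 0 || tb < 0 || tc < 0))
    msg <- c(msg, "GRE blocks do not fit between the inversion times (check nReadout * readoutTR)")
  if (length(msg)) msg else TRUE
})

#' MP2RAGE signal dictionary
#'
#' Unit-normalised simulated signal pairs (S_TI1, S_TI2) over a grid of R1
#' values and nominal transmit-field (B1) fractions, used for
#' maximum-inner-product R1 estimation.
#'
#' @slot r1Grid strictly increasing R1 grid (1/s).
#' @slot b1Grid strictly increasing B1 fraction grid.
#' @slot entries numeric array of dimension `c(2, length(r1Grid),
#'   length(b1Grid))`; each 2-vector has unit Euclidean norm.
#' @slot protocol the [MP2RAGEProtocol-class] used to simulate the entries.
#'
#' @seealso [buildDictionary()], [dictionaryMatch()]
#' @export
setClass("SignalDictionary",
  representation(
    r1Grid = "numeric", b1Grid = "numeric",
    entries = "array", protocol = "MP2RAGEProtocol"
  )
)

setValidity("SignalDictionary", function(object) {
  msg <- character(0)
  if (any(diff(object@r1Grid) <= 0)) msg <- c(msg, "r1Grid must be strictly increasing")
  if (any(diff(object@b1Grid) < 0)) msg <- c(msg, "b1Grid must be non-decreasing")
  d <- dim(object@entries)
  if (length(d) != 3 || d[1] != 2 || d[2] != length(object@r1Grid) ||
      d[3] != length(object@b1Grid))
    msg <- c(msg, "entries must be a 2 x length(r1Grid) x length(b1Grid) array")
  else {
    nrm <- sqrt(colSums(object@entries^2, dims = 1))
    if (any(abs(nrm - 1) > 1e-8)) msg <- c(msg, "entries must be unit-normalised")
  }
  if (length(msg)) msg else TRUE
})

#' Ordinary-least-squares fit of the covariate model
#'
#' Result of fitting the per-ROI covariate model
#' `value ~ 1 + age + age^2 + sex + hemisphere` with classical standard
#' errors, t-statistics and their z-equivalents.
#'
#' @slot beta named coefficient estimates.
#' @slot se classical OLS standard errors.
#' @slot t t-statistics (`beta / se`).
#' @slot z z-statistics via the sign-preserving quantile transform.
#' @slot dof residual degrees of freedom.
#' @slot sigma2 residual variance.
#' @slot nDropped number of non-finite response rows dropped before fitting.
#'
#' @seealso [fitGLM()], [tToZ()]
#' @export
setClass("GLMFit",
  representation(
    beta = "numeric", se = "numeric", t = "numeric", z = "numeric",
    dof = "numeric", sigma2 = "numeric", nDropped = "numeric"
  )
)

setValidity("GLMFit", function(object) {
  msg <- character(0)
  k <- length(object@beta)
  if (length(object@se) != k || length(object@t) != k || length(object@z) != k)
    msg <- c(msg, "beta, se, t and z must have equal length")
  ok <- is.finite(object@t) & is.finite(object@z)
  if (any(sign(object@z[ok]) != sign(object@t[ok])))
    msg <- c(msg, "z must preserve the sign of t")
  if (object@dof < 1) msg <- c(msg, "dof must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Gaussian-process normative model
#'
#' A frozen exact-GP regression of (sex- and hemisphere-corrected) metric
#' values on age, with a linear + squared-exponential + white-noise kernel
#' fitted by marginal-likelihood maximisation on standardised inputs.
#' Prediction returns a posterior mean and a predictive standard deviation
#' that includes the noise term, so deviation z-scores are calibrated for
#' new observations.
#'
#' @slot roi,metric,statistic identifiers of the modelled quantity.
#' @slot hyper named kernel hyperparameters on the standardised scale:
#'   `sigma2_se`, `lengthscale`, `sigma2_lin`, `sigma2_noise`.
#' @slot xTrain,yTrain standardised training ages and values.
#' @slot xMean,xSd,yMean,ySd standardisation constants (native units).
#' @slot alpha precomputed `solve(K, yTrain)` for fast prediction.
#' @slot L lower Cholesky factor of the training kernel matrix.
#' @slot logML maximised log marginal likelihood.
#' @slot correctionBetas named `c(sex, hemisphere)` betas (native units)
#'   used to correct values before scoring; `NA` when not attached.
#' @slot cvFolds,cvSeed cross-validation specification used for in-sample
#'   deviation scores.
#'
#' @seealso [fitGPR()], [predict,NormativeModel-method], [zscoreApply()]
#' @export
setClass("NormativeModel",
  representation(
    roi = "character", metric = "character", statistic = "character",
    hyper = "numeric",
    xTrain = "numeric", yTrain = "numeric",
    xMean = "numeric", xSd = "numeric", yMean = "numeric", ySd = "numeric",
    alpha = "numeric", L = "matrix", logML = "numeric",
    correctionBetas = "numeric", cvFolds = "numeric", cvSeed = "numeric"
  )
)

setValidity("NormativeModel", function(object) {
  msg <- character(0)
  h <- object@hyper
  need <- c("sigma2_se", "lengthscale", "sigma2_lin", "sigma2_noise")
  if (!all(need %in% names(h)))
    msg <- c(msg, "hyper must contain sigma2_se, lengthscale, sigma2_lin, sigma2_noise")
  else if (h[["sigma2_noise"]] <= 0)
    msg <- c(msg, "noise variance must be positive")
  if (object@xSd <= 0 || object@ySd <= 0)
    msg <- c(msg, "standardisation must be invertible (sd > 0)")
  if (length(object@xTrain) != length(object@yTrain))
    msg <- c(msg, "xTrain and yTrain must have equal length")
  if (length(msg)) msg else TRUE
})

#' First-order 3D spatial-gradient fit
#'
#' Coefficients of the model
#' `qMRI(x, y, z) = p0 + p1 (x - x0) + p2 (y - y0) + p3 (z - z0)` fitted by
#' OLS over an (eroded) ROI mask, with coordinates in mm and
#' `(x0, y0, z0)` the mask centre of mass. `p1`, `p2`, `p3` are the
#' gradients along the lateral-medial, posterior-anterior and
#' inferior-superior axes; right-hemisphere masks are sign-flipped along x
#' before fitting so `p1` runs lateral-to-medial in both hemispheres.
#'
#' @slot p0 constant term (ROI mean level, native units).
#' @slot gradient named `c(LM, PA, IS)` gradients (units/mm); a direction
#'   with degenerate geometry is `NA`.
#' @slot centre centre of mass `(x0, y0, z0)` in mm.
#' @slot nVoxels number of voxels used.
#' @slot rmse residual root-mean-square error.
#' @slot hemisphere `"left"`, `"right"` or `"pooled"` convention applied.
#'
#' @seealso [fitSpatialGradient()]
#' @export
setClass("SpatialGradientFit",
  representation(
    p0 = "numeric", gradient = "numeric", centre = "numeric",
    nVoxels = "numeric", rmse = "numeric", hemisphere = "character"
  )
)

setValidity("SpatialGradientFit", function(object) {
  msg <- character(0)
  if (object@nVoxels < 8) msg <- c(msg, "fit requires at least 8 voxels")
  if (length(object@gradient) != 3 ||
      !identical(names(object@gradient), c("LM", "PA", "IS")))
    msg <- c(msg, "gradient must be named c(LM, PA, IS)")
  if (length(object@centre) != 3) msg <- c(msg, "centre must have length 3")
  if (length(msg)) msg else TRUE
})
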