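#' Rescale an R1 map to 0-255 within a brain mask
#'
#' Maps the 1st and 99th percentile of in-mask values linearly to 0 and
#' 255, clipping values outside that range, and sets out-of-mask voxels to
#' 0. Percentiles use linear interpolation between order statistics.
#'
#' @param r1Map numeric array.
#' @param mask logical array of the same shape (brain mask).
#' @return numeric array of normalised values in `[0, 255]`.
#' @export
normalizeR1 <- function(r1Map, mask) {
  if (!identical(dim(r1Map), dim(mask))) stop("map and mask grids differ")
  vals <- r1Map[mask]
  if (!length(vals)) stop("mask is empty")
  q <- quantile(vals, c(0.01, 0.99), type = 7, names = FALSE, na.rm = TRUE)
  if (q[1] == q[2])
    stop("degenerate histogram: 1st and 99th percentile coincide")
  out <- (r1Map - q[1]) / (q[2] - q[1]) * 255
  out <- pmin(pmax(out, 0), 255)
  out[!mask] <- 0
  out
}

#' Hybrid-image coefficients
#'
#' The weights of the hybrid image `mu0 + mu1 * chi + mu2 * R1norm`.
#' Defaults `(0, 400, 1)` give susceptibility (in ppm) and the 0-255
#' normalised R1 comparable dynamic ranges.
#'
#' @param mu0 offset.
#' @param mu1 weight of the susceptibility map (per ppm).
#' @param mu2 weight of the normalised R1 map.
#' @return a named numeric vector of class `"HybridCoefficients"`.
#' @export
hybridCoefficients <- function(mu0 = 0, mu1 = 400, mu2 = 1) {
  stopifnot(is.finite(mu0), is.finite(mu1), is.finite(mu2))
  structure(c(mu0 = mu0, mu1 = mu1, mu2 = mu2),
            class = "HybridCoefficients")
}

#' Compute the R1-susceptibility hybrid image
#'
#' Voxelwise `mu0 + mu1 * chi + mu2 * R1norm`; the joint contrast sharpens
#' the delineation of iron-rich subcortical nuclei for registration.
#'
#' @param chiMap susceptibility map (ppm).
#' @param r1normMap normalised R1 map (0-255), same grid.
#' @param coeffs a [hybridCoefficients()] vector.
#' @return numeric array.
#' @examples
#' computeHybrid(array(0.1, c(2, 2, 2)), array(100, c(2, 2, 2)))
#' @export
computeHybrid <- function(chiMap, r1normMap, coeffs = hybridCoefficients()) {
  if (!identical(dim(chiMap), dim(r1normMap)))
    stop("chi and R1norm maps are on different grids")
  coeffs[["mu0"]] + coeffs[["mu1"]] * chiMap + coeffs[["mu2"]] * r1normMap
}

#' Polynomial contrast matching of ROI medians
#'
#' Least-squares polynomial mapping subject ROI medians to template ROI
#' medians: second order for R1 (whose contrast differs non-linearly from a
#' T1-weighted template), first order for susceptibility. Labels are
#' matched by name when both vectors are named.
#'
#' @param subjectMedians,templateMedians numeric vectors of per-ROI
#'   medians.
#' @param metric `"R1"` (order 2) or `"chi"` (order 1).
#' @return a list of class `"ContrastMatch"` with elements `coefficients`
#'   (ascending powers), `order`, `residuals`, `roiLabels`, `metric`.
#' @export
contrastMatch <- function(subjectMedians, templateMedians,
                          metric = c("R1", "chi")) {
  metric <- match.arg(metric)
  ord <- if (metric == "R1") 2L else 1L
  if (!is.null(names(subjectMedians)) && !is.null(names(templateMedians))) {
    common <- intersect(names(subjectMedians), names(templateMedians))
    subjectMedians <- subjectMedians[common]
    templateMedians <- templateMedians[common]
    labels <- common
  } else {
    if (length(subjectMedians) != length(templateMedians))
      stop("unnamed median vectors must have equal length")
    labels <- as.character(seq_along(subjectMedians))
  }
  if (length(subjectMedians) < ord + 1)
    stop("need at least ", ord + 1, " common ROIs for an order-", ord, " fit")
  X <- outer(as.numeric(subjectMedians), 0:ord, `^`)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient polynomial fit (degenerate ROI medians)")
  beta <- qr.coef(qrX, as.numeric(templateMedians))
  res <- as.numeric(templateMedians) - X %*% beta
  structure(list(coefficients = setNames(beta, paste0("c", 0:ord)),
                 order = ord, residuals = as.numeric(res),
                 roiLabels = labels, metric = metric),
            class = "ContrastMatch")
}

#' Apply a fitted contrast match to new values
#'
#' @param match a [contrastMatch()] result.
#' @param x numeric values (e.g. a map or medians) on the subject scale.
#' @return values mapped to the template scale.
#' @export
applyContrastMatch <- function(match, x) {
  stopifnot(inherits(match, "ContrastMatch"))
  drop(outer(as.numeric(x), 0:match$order, `^`) %*% match$coefficients)
}

#' Derive hybrid coefficients from a template
#'
#' OLS fit of the hybrid weights `(mu0, mu1, mu2)` so that
#' `mu0 + mu1 * chi + mu2 * R1norm` reproduces the template's hybrid ROI
#' medians given the subject's contrast-matched medians.
#'
#' @param templateHybridMedians per-ROI medians of the template hybrid
#'   image.
#' @param r1Medians,chiMedians matched subject per-ROI medians.
#' @return a [hybridCoefficients()] vector.
#' @export
deriveHybridCoefficients <- function(templateHybridMedians, r1Medians,
                                     chiMedians) {
  y <- as.numeric(templateHybridMedians)
  if (length(y) < 3) stop("need at least 3 ROIs")
  X <- cbind(1, as.numeric(chiMedians), as.numeric(r1Medians))
  qrX <- qr(X)
  if (qrX$rank < 3)
    stop("collinear regressors: hybrid coefficients are unidentifiable")
  b <- qr.coef(qrX, y)
  hybridCoefficients(mu0 = b[1], mu1 = b[2], mu2 = b[3])
}
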