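#' Per-ROI summary statistics
#'
#' Median, interquartile range (Q75 - Q25, linearly interpolated
#' quantiles) and bias-corrected Fisher-Pearson sample skewness of the
#' voxel values within an ROI. Non-finite voxels are excluded and counted;
#' skewness is `NA` for fewer than 3 valid voxels.
#'
#' @param map numeric array of quantitative values.
#' @param labels integer array (same grid) of parcellation labels.
#' @param roi the label value defining the ROI.
#' @return named numeric `c(median, iqr, skewness)` with attribute
#'   `nInvalid`.
#' @examples
#' lab <- array(1L, c(2, 2, 1))
#' roiStatistics(array(c(1, 2, 3, 4), c(2, 2, 1)), lab, 1)
#' @export
roiStatistics <- function(map, labels, roi) {
  if (!identical(dim(map), dim(labels))) stop("map and labels grids differ")
  vals <- map[labels == roi]
  if (!length(vals)) stop("ROI ", roi, " is empty on this grid")
  bad <- !is.finite(vals)
  vals <- vals[!bad]
  if (!length(vals)) stop("ROI ", roi, " contains no valid voxels")
  q <- quantile(vals, c(0.25, 0.75), type = 7, names = FALSE)
  sk <- if (length(vals) >= 3 && sd(vals) > 0)
    e1071::skewness(vals, type = 2) else NA_real_
  out <- c(median = median(vals), iqr = q[2] - q[1], skewness = sk)
  attr(out, "nInvalid") <- sum(bad)
  out
}

#' Morphological erosion with a 3x3x3 box element
#'
#' Erodes a binary mask by one voxel "in all directions": a voxel survives
#' iff its full 26-neighbourhood (plus itself) lies inside the mask.
#' Voxels on the grid boundary are always removed. Applied `n` times.
#'
#' @param mask logical (or 0/1) 3D array.
#' @param n number of erosion passes.
#' @param roi optional label used in the error message when erosion
#'   empties the mask.
#' @return logical array of the eroded mask.
#' @export
erodeMask <- function(mask, n = 1, roi = NULL) {
  m <- mask != 0
  if (length(dim(m)) != 3) stop("mask must be a 3D array")
  d <- dim(m)
  for (pass in seq_len(n)) {
    padded <- array(FALSE, d + 2)
    padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
    out <- array(TRUE, d)
    for (dx in 0:2) for (dy in 0:2) for (dz in 0:2) {
      out <- out & padded[dx + 1:d[1], dy + 1:d[2], dz + 1:d[3]]
    }
    m <- out
    if (!any(m))
      stop("erosion emptied the mask",
           if (!is.null(roi)) paste0(" of ROI ", roi) else "")
  }
  m
}

#' Fit a first-order 3D spatial gradient over an ROI
#'
#' OLS fit of `value = p0 + p1 (x - x0) + p2 (y - y0) + p3 (z - z0)` over
#' the mask voxels, with coordinates in mm obtained through the affine
#' (RAS orientation assumed) and `(x0, y0, z0)` the unweighted centre of
#' mass of the mask. For right-hemisphere masks the x offsets are
#' sign-flipped before fitting so that `p1` points lateral-to-medial in
#' both hemispheres and left/right fits are poolable. Degenerate (planar)
#' geometry triggers a warning and flags the unidentifiable direction(s)
#' as `NA`.
#'
#' @param map numeric 3D array.
#' @param mask logical 3D array (typically eroded with [erodeMask()]);
#'   at least 8 voxels.
#' @param affine 4 x 4 voxel-to-mm matrix (0-based voxel indices).
#' @param hemisphere `"auto"` (decide from the sign of the centre-of-mass
#'   x coordinate), `"left"`, or `"right"`.
#' @return a [SpatialGradientFit-class].
#' @export
fitSpatialGradient <- function(map, mask, affine,
                               hemisphere = c("auto", "left", "right")) {
  hemisphere <- match.arg(hemisphere)
  if (!identical(dim(map), dim(mask))) stop("map and mask grids differ")
  vox <- which(mask != 0, arr.ind = TRUE) - 1   # 0-based
  if (nrow(vox) < 8)
    stop("spatial-gradient fit requires at least 8 voxels (got ",
         nrow(vox), ")")
  mm <- t(affine %*% t(cbind(vox, 1)))[, 1:3, drop = FALSE]
  centre <- colMeans(mm)
  if (hemisphere == "auto")
    hemisphere <- if (centre[1] > 0) "right" else "left"
  X <- sweep(mm, 2, centre)
  if (hemisphere == "right") X[, 1] <- -X[, 1]
  y <- map[mask != 0]

  keep <- apply(X, 2, function(col) sd(col) > 1e-9)
  if (!all(keep))
    warning("degenerate mask geometry: no spatial extent along ",
            paste(c("LM", "PA", "IS")[!keep], collapse = ", "),
            "; coefficient(s) flagged NA")
  fit <- lm.fit(cbind(1, X[, keep, drop = FALSE]), y)
  grad <- rep(NA_real_, 3)
  grad[keep] <- fit$coefficients[-1]
  names(grad) <- c("LM", "PA", "IS")
  rmse <- sqrt(mean(fit$residuals^2))
  new("SpatialGradientFit", p0 = unname(fit$coefficients[1]),
      gradient = grad, centre = unname(centre), nVoxels = nrow(vox),
      rmse = rmse, hemisphere = hemisphere)
}

#' ROI volume metrics normalised by intracranial volume
#'
#' The raw ROI volume (voxel count times voxel volume) is normalised by
#' the intracranial volume; when a population of normalised volumes is
#' supplied, the percentage change relative to the population mean is also
#' computed: `100 * (V - Vbar) / Vbar`.
#'
#' @param labels integer 3D label array.
#' @param roi label defining the ROI.
#' @param icvMask logical array of the intracranial volume (same grid), or
#'   a single number giving the ICV in mm^3.
#' @param voxelVolume voxel volume in mm^3.
#' @param populationValues optional numeric vector of normalised ROI
#'   volume fractions across the cohort (used for the population mean).
#' @return list of class `"VolumeMetrics"` with `vRoiRaw` (mm^3), `icv`
#'   (mm^3), `vRoi` (fraction), `vMean`, `vPct`.
#' @seealso [volumePercentChange()] for the cohort-level vectorised form.
#' @export
volumeMetrics <- function(labels, roi, icvMask, voxelVolume = 1,
                          populationValues = NULL) {
  count <- sum(labels == roi)
  if (count == 0) stop("ROI ", roi, " absent from the label map")
  icv <- if (is.array(icvMask)) sum(icvMask != 0) * voxelVolume
         else as.numeric(icvMask)
  if (icv <= 0) stop("intracranial volume must be positive")
  vRoi <- count * voxelVolume / icv
  vMean <- if (is.null(populationValues)) NA_real_
           else mean(populationValues)
  vPct <- if (is.na(vMean)) NA_real_ else 100 * (vRoi - vMean) / vMean
  structure(list(vRoiRaw = count * voxelVolume, icv = icv, vRoi = vRoi,
                 vMean = vMean, vPct = vPct),
            class = "VolumeMetrics")
}

#' Percentage volume change relative to the population mean
#'
#' `100 * (v - mean(v)) / mean(v)` per subject; by construction the cohort
#' mean of the result is 0.
#'
#' @param v normalised ROI volumes across the cohort.
#' @param vBar population mean (defaults to `mean(v)`).
#' @return numeric vector of percentages.
#' @export
volumePercentChange <- function(v, vBar = mean(v)) {
  100 * (v - vBar) / vBar
}

#' Merge a set of parcellation labels into one
#'
#' Rewrites every label in `labelSet` to `newLabel` (e.g. combining all
#' thalamic sub-nucleus labels into a whole-thalamus ROI); all other
#' labels are untouched.
#'
#' @param labels integer 3D label array.
#' @param labelSet labels to merge (at least one must be present).
#' @param newLabel replacement label; must not collide with an existing
#'   label outside `labelSet`.
#' @return relabelled integer array.
#' @export
combineLabels <- function(labels, labelSet, newLabel) {
  if (!length(labelSet)) stop("labelSet is empty")
  present <- unique(labels[labels != 0])
  if (!any(labelSet %in% present))
    stop("none of the labels to combine are present in the map")
  if (newLabel %in% setdiff(present, labelSet))
    stop("new label ", newLabel,
         " collides with an existing label outside the merged set")
  out <- labels
  out[labels %in% labelSet] <- as.integer(newLabel)
  out
}
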