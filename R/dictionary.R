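#' Build an MP2RAGE signal dictionary
#'
#' Simulates unit-normalised (S_TI1, S_TI2) pairs over an R1 x B1 grid with
#' the steady-state forward model. The B1 grid step defaults to 0.005 of the
#' nominal transmit field so that flip-angle deviations are absorbed by the
#' matching rather than biasing R1.
#'
#' @param protocol an [MP2RAGEProtocol-class].
#' @param r1Range,r1Step R1 grid range and step (1/s).
#' @param b1Range,b1Step B1 fraction grid range and step. Use
#'   `b1Range = c(1, 1)` for a B1-blind dictionary.
#' @return a [SignalDictionary-class].
#' @examples
#' d <- buildDictionary(mp2rageProtocol(), r1Range = c(0.25, 4), r1Step = 0.25,
#'                      b1Range = c(1, 1))
#' length(r1Grid(d))
#' @export
buildDictionary <- function(protocol = mp2rageProtocol(),
                            r1Range = c(0.05, 4), r1Step = 0.005,
                            b1Range = c(0.6, 1.4), b1Step = 0.005) {
  if (r1Step <= 0 || b1Step <= 0) stop("grid steps must be positive")
  if (diff(r1Range) <= 0) stop("r1Range must be non-degenerate")
  if (r1Step > diff(r1Range)) stop("r1Step larger than r1Range")
  if (diff(b1Range) < 0) stop("invalid b1Range")
  if (diff(b1Range) > 0 && b1Step > diff(b1Range))
    stop("b1Step larger than b1Range")
  r1g <- seq(r1Range[1], r1Range[2], by = r1Step)
  b1g <- if (diff(b1Range) == 0) b1Range[1] else
    seq(b1Range[1], b1Range[2], by = b1Step)
  entries <- array(0, dim = c(2, length(r1g), length(b1g)))
  for (j in seq_along(b1g)) {
    s <- mp2rageForward(r1g, b1g[j], protocol)
    nrm <- sqrt(s$S1^2 + s$S2^2)
    entries[1, , j] <- s$S1 / nrm
    entries[2, , j] <- s$S2 / nrm
  }
  new("SignalDictionary", r1Grid = r1g, b1Grid = b1g,
      entries = entries, protocol = protocol)
}

#' Estimate R1 by dictionary matching
#'
#' For each voxel, selects the dictionary B1 slice nearest the supplied B1
#' value and returns the grid R1 whose unit-normalised entry maximises the
#' absolute inner product with the measured (S_TI1, S_TI2) pair. The match
#' is invariant to global (complex) scaling of the measured pair; ties
#' resolve to the smaller R1. B1 values outside the dictionary grid are
#' clamped (count reported in the `"nClamped"` attribute); zero-norm signal
#' pairs yield `NA` (count in `"nInvalid"`).
#'
#' @param S1,S2 measured signals at the two inversion times (numeric or
#'   complex vectors/arrays of equal length).
#' @param b1 B1 fraction per voxel (recycled).
#' @param dict a [SignalDictionary-class].
#' @return numeric vector (or array matching `dim(S1)`) of R1 estimates
#'   (1/s), with attributes `nClamped` and `nInvalid`.
#' @examples
#' d <- buildDictionary(mp2rageProtocol(), r1Range = c(0.5, 2), r1Step = 0.1,
#'                      b1Range = c(1, 1))
#' s <- mp2rageForward(1.3, 1, mp2rageProtocol())
#' dictionaryMatch(s$S1, s$S2, 1, d)
#' @export
dictionaryMatch <- function(S1, S2, b1, dict) {
  stopifnot(is(dict, "SignalDictionary"))
  dm <- dim(S1)
  S1 <- as.vector(S1); S2 <- as.vector(S2)
  if (length(S2) != length(S1)) stop("S1 and S2 must have equal length")
  b1 <- rep_len(as.vector(b1), length(S1))

  nClamped <- sum(b1 < min(dict@b1Grid) | b1 > max(dict@b1Grid))
  if (nClamped > 0)
    warning(sprintf("%d B1 value(s) outside the dictionary grid were clamped",
                    nClamped))
  b1 <- pmin(pmax(b1, min(dict@b1Grid)), max(dict@b1Grid))
  slice <- vapply(b1, function(v) which.min(abs(dict@b1Grid - v)), integer(1))

  nrm2 <- Mod(S1)^2 + Mod(S2)^2
  invalid <- !(nrm2 > 0) | !is.finite(nrm2)
  out <- rep(NA_real_, length(S1))
  meas <- rbind(S1, S2)
  for (j in unique(slice)) {
    idx <- which(slice == j & !invalid)
    if (!length(idx)) next
    score <- Mod(crossprod(dict@entries[, , j], meas[, idx, drop = FALSE]))
    best <- max.col(t(score), ties.method = "first")
    out[idx] <- dict@r1Grid[best]
  }
  if (!is.null(dm)) dim(out) <- dm
  attr(out, "nClamped") <- nClamped
  attr(out, "nInvalid") <- sum(invalid)
  out
}

#' Estimate R1 by lookup-table inversion of the UNI image
#'
#' The conventional MP2RAGE approach: the monotone UNI(R1) curve, simulated
#' with the forward model (per B1 slice when a B1 map is supplied), is
#' inverted by linear interpolation. UNI values outside the attainable range
#' clamp to the corresponding grid end; no extrapolation is performed.
#'
#' @param uni UNI values in `[-0.5, 0.5]` (vector or array).
#' @param protocol an [MP2RAGEProtocol-class].
#' @param b1 optional B1 fraction per voxel (recycled); rounded to
#'   `b1Step` slices.
#' @param r1Range,r1Step interpolation grid for the inversion (1/s). The
#'   default range starts at 0.3 1/s because the UNI(R1) curve folds back
#'   at very low R1 (a limitation intrinsic to the lookup-table approach;
#'   dictionary matching does not require monotonicity).
#' @param b1Step discretisation of the B1 map.
#' @return R1 estimates (1/s), same shape as `uni`.
#' @examples
#' p <- mp2rageProtocol()
#' s <- mp2rageForward(1.2, 1, p)
#' lookupTableInvert(uniCombine(s$S1, s$S2), p)
#' @export
lookupTableInvert <- function(uni, protocol = mp2rageProtocol(), b1 = NULL,
                              r1Range = c(0.3, 4), r1Step = 0.001,
                              b1Step = 0.005) {
  if (any(abs(uni) > 0.5 + 1e-9, na.rm = TRUE))
    stop("UNI values must lie in [-0.5, 0.5]")
  dm <- dim(uni)
  uni <- as.vector(uni)
  r1g <- seq(r1Range[1], r1Range[2], by = r1Step)
  if (is.null(b1)) b1 <- 1
  b1 <- rep_len(as.vector(b1), length(uni))
  b1r <- round(b1 / b1Step) * b1Step
  out <- rep(NA_real_, length(uni))
  for (bv in unique(b1r)) {
    s <- mp2rageForward(r1g, bv, protocol)
    curve <- uniCombine(s$S1, s$S2)
    d <- diff(curve)
    if (!(all(d > 0) || all(d < 0)))
      stop(sprintf(paste("UNI(R1) is not monotone over [%g, %g] 1/s at B1 =",
                         "%g; restrict r1Range to a narrower interval"),
                   r1Range[1], r1Range[2], bv))
    idx <- which(b1r == bv)
    out[idx] <- approx(x = curve, y = r1g, xout = uni[idx], rule = 2)$y
  }
  if (!is.null(dm)) dim(out) <- dm
  out
}
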