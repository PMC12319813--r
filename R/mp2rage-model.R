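#' Construct an MP2RAGE protocol
#'
#' Defaults correspond to a 3T whole-brain protocol with equal 6-degree flip
#' angles, inversion times 700/2400 ms and a 6000 ms cycle. The per-block
#' readout structure (`nReadout` excitations spaced `readoutTR` ms) is
#' required by the steady-state signal model; defaults of 176 pulses at 7 ms
#' suit a 1 mm isotropic sagittal readout.
#'
#' @param TI1,TI2 inversion times (ms).
#' @param TR MP2RAGE cycle repetition time (ms).
#' @param alpha1,alpha2 nominal flip angles (degrees).
#' @param readoutTR echo spacing within a GRE block (ms).
#' @param nReadout excitations per GRE block.
#' @param inversionEfficiency inversion efficiency (fraction of full
#'   inversion).
#' @return an [MP2RAGEProtocol-class] object.
#' @examples
#' mp2rageProtocol()
#' @export
mp2rageProtocol <- function(TI1 = 700, TI2 = 2400, TR = 6000,
                            alpha1 = 6, alpha2 = 6,
                            readoutTR = 7, nReadout = 176,
                            inversionEfficiency = 0.96) {
  new("MP2RAGEProtocol", TI1 = TI1, TI2 = TI2, TR = TR,
      alpha1 = alpha1, alpha2 = alpha2, readoutTR = readoutTR,
      nReadout = nReadout, inversionEfficiency = inversionEfficiency)
}

# Affine map of longitudinal magnetisation (m -> A*m + B, in units of M0)
# over one GRE block of n pulses with flip angle a (rad): between pulses the
# magnetisation relaxes for readoutTR, each pulse scales mz by cos(a).
.blockAffine <- function(n, cosA, E1) {
  A <- (cosA * E1)^n
  B <- ifelse(abs(1 - cosA * E1) < 1e-15, n * (1 - E1),
              (1 - E1) * (1 - (cosA * E1)^n) / (1 - cosA * E1))
  list(A = A, B = B)
}

#' MP2RAGE steady-state forward signal model
#'
#' Computes the two mid-block GRE signals (S_TI1, S_TI2) of the periodic
#' MP2RAGE sequence (inversion, relaxation, GRE block at `alpha1 * b1`,
#' relaxation, GRE block at `alpha2 * b1`, relaxation) for given R1 and
#' achieved/nominal transmit-field fraction `b1`. The transmit field scales
#' the excitation flip angles only. Signals are real-valued (the first is
#' typically negative), proportional to `m0`, and evaluated at the centre of
#' each readout block.
#'
#' @param r1 longitudinal relaxation rate(s), 1/s. Vectorised.
#' @param b1 transmit-field fraction(s); recycled against `r1`.
#' @param protocol an [MP2RAGEProtocol-class].
#' @param m0 equilibrium magnetisation scale (default 1; the dictionary
#'   match is invariant to it).
#' @return a list with numeric vectors `S1` and `S2`.
#' @examples
#' s <- mp2rageForward(c(0.5, 1, 2), 1, mp2rageProtocol())
#' uniCombine(s$S1, s$S2)
#' @export
mp2rageForward <- function(r1, b1 = 1, protocol = mp2rageProtocol(), m0 = 1) {
  stopifnot(is(protocol, "MP2RAGEProtocol"))
  validObject(protocol)
  if (any(r1 <= 0)) stop("r1 must be positive")
  if (any(b1 <= 0)) stop("b1 must be positive")
  n <- max(length(r1), length(b1))
  r1 <- rep_len(r1, n); b1 <- rep_len(b1, n)

  t1 <- 1000 / r1                       # ms
  blk <- protocol@nReadout * protocol@readoutTR
  ta <- protocol@TI1 - blk / 2
  tb <- protocol@TI2 - protocol@TI1 - blk
  tc <- protocol@TR - protocol@TI2 - blk / 2
  E1 <- exp(-protocol@readoutTR / t1)
  EA <- exp(-ta / t1); EB <- exp(-tb / t1); EC <- exp(-tc / t1)
  a1 <- protocol@alpha1 * pi / 180 * b1
  a2 <- protocol@alpha2 * pi / 180 * b1
  eff <- protocol@inversionEfficiency

  blk1 <- .blockAffine(protocol@nReadout, cos(a1), E1)
  blk2 <- .blockAffine(protocol@nReadout, cos(a2), E1)

  # compose the affine maps over one full cycle, starting just before
  # inversion: inv -> TA -> block1 -> TB -> block2 -> TC
  A <- -eff; B <- 0
  A <- EA * A; B <- EA * B + (1 - EA)
  A <- blk1$A * A; B <- blk1$A * B + blk1$B
  A <- EB * A; B <- EB * B + (1 - EB)
  A <- blk2$A * A; B <- blk2$A * B + blk2$B
  A <- EC * A; B <- EC * B + (1 - EC)
  mss <- B / (1 - A)                    # steady state before inversion

  half1 <- .blockAffine(protocol@nReadout / 2, cos(a1), E1)
  half2 <- .blockAffine(protocol@nReadout / 2, cos(a2), E1)

  m <- -eff * mss
  m <- EA * m + (1 - EA)
  mMid1 <- half1$A * m + half1$B        # mz at centre of block 1
  m <- blk1$A * m + blk1$B
  m <- EB * m + (1 - EB)
  mMid2 <- half2$A * m + half2$B        # mz at centre of block 2

  list(S1 = m0 * sin(a1) * mMid1, S2 = m0 * sin(a2) * mMid2)
}

#' Combine the two MP2RAGE signals into the UNI image
#'
#' The bias-reduced MP2RAGE ratio `Re(S1 * Conj(S2)) / (|S1|^2 + |S2|^2)`,
#' bounded in `[-0.5, 0.5]`.
#'
#' @param S1,S2 signals at the two inversion times (real or complex).
#' @return numeric UNI values; 0 where both signals vanish.
#' @export
uniCombine <- function(S1, S2) {
  num <- Re(S1 * Conj(S2))
  den <- Mod(S1)^2 + Mod(S2)^2
  out <- ifelse(den > 0, num / den, 0)
  as.numeric(out)
}
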