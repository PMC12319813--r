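protocol <- mp2rageProtocol()

test_that("forward model is deterministic, continuous in r1 and linear in M0", {
  r1 <- seq(0.2, 3, length.out = 50)
  s1 <- mp2rageForward(r1, 1, protocol)
  s2 <- mp2rageForward(r1, 1, protocol)
  expect_identical(s1, s2)
  # small r1 perturbations give small signal changes
  sEps <- mp2rageForward(r1 + 1e-6, 1, protocol)
  expect_lt(max(abs(sEps$S1 - s1$S1)), 1e-4)
  sM0 <- mp2rageForward(r1, 1, protocol, m0 = 2)
  expect_equal(sM0$S1, 2 * s1$S1)
  expect_equal(sM0$S2, 2 * s1$S2)
})

test_that("the UNI combination is bounded in [-0.5, 0.5] and scale-invariant", {
  r1 <- seq(0.05, 4, by = 0.005)
  s <- mp2rageForward(r1, 1, protocol)
  u <- uniCombine(s$S1, s$S2)
  expect_true(all(u >= -0.5 & u <= 0.5))
  expect_equal(uniCombine(3.7 * s$S1, 3.7 * s$S2), u)
})

test_that("non-physical protocols are rejected", {
  expect_error(mp2rageProtocol(TI1 = 700, TI2 = 6500, TR = 6000), "TI1 < TI2")
  expect_error(mp2rageProtocol(TI1 = 2500, TI2 = 2400), "TI1 < TI2")
  expect_error(mp2rageProtocol(alpha1 = 0), "flip angles")
  expect_error(mp2rageProtocol(TI1 = 100), "do not fit")
})

test_that("dictionary construction matches grid arithmetic and is normalised", {
  d <- buildDictionary(protocol, r1Range = c(0.25, 4), r1Step = 0.25,
                       b1Range = c(1, 1))
  expect_length(r1Grid(d), 16)
  nrm <- sqrt(colSums(d@entries^2, dims = 1))
  expect_lt(max(abs(nrm - 1)), 1e-12)
  d2 <- buildDictionary(protocol, r1Range = c(0.25, 4), r1Step = 0.25,
                        b1Range = c(1, 1))
  expect_identical(d, d2)
  expect_error(buildDictionary(protocol, r1Range = c(1, 1.1), r1Step = 0.5),
               "larger than")
})

test_that("dictionary matching is exact on-grid and bracketed off-grid", {
  d <- buildDictionary(protocol, r1Range = c(0.3, 3), r1Step = 0.1,
                       b1Range = c(1, 1))
  # self-match on every grid point
  s <- mp2rageForward(r1Grid(d), 1, protocol)
  est <- dictionaryMatch(s$S1, s$S2, 1, d)
  expect_equal(as.numeric(est), r1Grid(d))
  # off-grid value midway between neighbours matches one of the two
  sMid <- mp2rageForward(1.25, 1, protocol)
  estMid <- dictionaryMatch(sMid$S1, sMid$S2, 1, d)
  expect_true(as.numeric(estMid) %in% c(1.2, 1.3))
  # invariance to global complex scaling
  sc <- complex(real = -2.2, imaginary = 1.3)
  estScaled <- dictionaryMatch(sc * s$S1, sc * s$S2, 1, d)
  expect_equal(as.numeric(estScaled), as.numeric(est))
})

test_that("zero-norm signals flag invalid and out-of-grid B1 is clamped", {
  d <- buildDictionary(protocol, r1Range = c(0.3, 3), r1Step = 0.1,
                       b1Range = c(0.9, 1.1))
  s <- mp2rageForward(c(1, 1.5), 1, protocol)
  est <- suppressWarnings(
    dictionaryMatch(c(0, s$S1), c(0, s$S2), c(1, 1, 2), d))
  expect_true(is.na(est[1]))
  expect_equal(attr(est, "nInvalid"), 1)
  expect_equal(attr(est, "nClamped"), 1)
})

test_that("B1-aware matching beats the B1-blind slice under a planted B1", {
  dAware <- buildDictionary(protocol, r1Range = c(0.3, 3), r1Step = 0.05,
                            b1Range = c(0.6, 1.4), b1Step = 0.005)
  dBlind <- buildDictionary(protocol, r1Range = c(0.3, 3), r1Step = 0.05,
                            b1Range = c(1, 1))
  set.seed(7)
  r1True <- runif(60, 0.5, 2.5)
  b1True <- 1.2
  s <- mp2rageForward(r1True, b1True, protocol)
  errAware <- abs(dictionaryMatch(s$S1, s$S2, b1True, dAware) - r1True)
  errBlind <- abs(dictionaryMatch(s$S1, s$S2, 1, dBlind) - r1True)
  expect_lte(max(errAware), 0.05)
  expect_gt(max(errBlind), max(errAware))
})

test_that("matching error shrinks monotonically with the r1 grid step", {
  set.seed(21)
  r1True <- runif(400, 0.5, 2.5)
  s <- generateMP2RAGESignals(r1True, 1, protocol, noiseSd = 0.0012,
                              seed = 3)   # roughly SNR 50 on |S2|
  med <- vapply(c(0.1, 0.05, 0.005), function(step) {
    d <- buildDictionary(protocol, r1Range = c(0.3, 3), r1Step = step,
                         b1Range = c(1, 1))
    median(abs(dictionaryMatch(s$S1, s$S2, 1, d) - r1True))
  }, numeric(1))
  expect_true(all(diff(med) < 0))
})

test_that("simulated inversion images round-trip through the forward model", {
  r1 <- array(runif(27, 0.5, 2), c(3, 3, 3))
  clean <- generateMP2RAGESignals(r1, 1.1, protocol, noiseSd = 0, seed = 1)
  fwd <- mp2rageForward(as.vector(r1), 1.1, protocol)
  expect_equal(Re(as.vector(clean$S1)), fwd$S1)
  expect_equal(Re(as.vector(clean$S2)), fwd$S2)
  # determinism of the noisy path
  n1 <- generateMP2RAGESignals(r1, 1.1, protocol, noiseSd = 0.01, seed = 5)
  n2 <- generateMP2RAGESignals(r1, 1.1, protocol, noiseSd = 0.01, seed = 5)
  expect_identical(n1, n2)
})

test_that("lookup-table inversion round-trips and clamps", {
  r1True <- c(0.5, 0.8, 1.2, 2, 3.5)
  s <- mp2rageForward(r1True, 1, protocol)
  u <- uniCombine(s$S1, s$S2)
  est <- lookupTableInvert(u, protocol)
  expect_lt(max(abs(est - r1True)), 1e-3)
  # attainable extremes clamp to the grid ends, never extrapolate
  expect_equal(lookupTableInvert(0.5, protocol), 4)
  expect_equal(lookupTableInvert(-0.499, protocol), 0.3, tolerance = 1e-6)
  # constant map -> constant output
  cm <- lookupTableInvert(array(0.2, c(2, 2, 2)), protocol)
  expect_equal(as.vector(cm), rep(cm[1], 8))
  # the non-monotone low-R1 branch is refused with guidance
  expect_error(lookupTableInvert(0.2, protocol, r1Range = c(0.05, 4)),
               "narrower")
})
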