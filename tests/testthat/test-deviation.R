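test_that("correlation matrix matches the definitional oracle", {
  set.seed(1)
  m <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, letters[1:4]))
  r <- corrMatrix(m)
  for (i in 1:4) for (j in 1:4) {
    x <- m[, i]; y <- m[, j]
    ref <- mean((x - mean(x)) * (y - mean(y))) / (sd(x) * sd(y)) *
      length(x) / (length(x) - 1)
    expect_equal(r[i, j], if (i == j) 1 else ref, tolerance = 1e-12)
  }
  expect_equal(r, t(r))
  m2 <- cbind(x = rnorm(10)); m2 <- cbind(m2, y = -m2[, 1])
  expect_equal(corrMatrix(m2)["x", "y"], -1)
  # zero-variance column flagged, not propagated silently
  m3 <- cbind(a = rnorm(6), b = rep(2, 6))
  expect_warning(r3 <- corrMatrix(m3), "undefined")
  expect_true(is.na(r3["a", "b"]))
  expect_equal(diag(r3), c(a = 1, b = 1))
  # full-data correlation matrices are PSD
  set.seed(2)
  big <- matrix(rnorm(600), 60, 10)
  ev <- eigen(corrMatrix(big), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
})

test_that("network thresholding returns blocks and respects bounds", {
  C <- diag(6)
  dimnames(C) <- list(LETTERS[1:6], LETTERS[1:6])
  C[1:3, 1:3] <- 0.8; C[4:6, 4:6] <- 0.8; diag(C) <- 1
  net <- thresholdNetwork(C, 0.4)
  expect_equal(length(net$components), 2)
  expect_setequal(net$components[[1]], c("A", "B", "C"))
  expect_setequal(net$components[[2]], c("D", "E", "F"))
  netNone <- thresholdNetwork(C, 1.01)
  expect_equal(nrow(netNone$edges), 0)
  expect_equal(length(netNone$components), 6)
  # negative correlations never form edges
  C2 <- diag(2); C2[1, 2] <- C2[2, 1] <- -0.9
  dimnames(C2) <- list(c("x", "y"), c("x", "y"))
  expect_equal(nrow(thresholdNetwork(C2, 0.4)$edges), 0)
  expect_error(thresholdNetwork(matrix(c(1, 0.2, 0.5, 1), 2), 0.4),
               "symmetric")
})

test_that("planted two-network structure is recovered at threshold 0.4", {
  hits <- 0
  for (seed in 1:50) {
    co <- generateCohort(cohortDesign(nSubjects = 260, seed = seed),
                         unitNetworkSpecs())
    g <- fitCohortGLM(co)
    corr <- correctCohort(co, g)
    # deviation proxies: age-detrended standardised residuals per ROI
    resid <- lapply(split(corr, corr$roi), function(sub) {
      f <- lm.fit(buildDesign(sub), sub$value)
      f$residuals / sd(f$residuals)
    })
    R <- corrMatrix(do.call(cbind, resid))
    comps <- thresholdNetwork(R, 0.4)$components
    ok <- length(comps) == 2 &&
      setequal(comps[[1]], c("GPe", "GPi", "SNc", "SNr", "RN", "STN", "VP")) &&
      setequal(comps[[2]], c("Cau", "Pu"))
    hits <- hits + ok
  }
  expect_gte(hits, 45)
})

test_that("Welch test matches the closed-form oracle and its conventions", {
  w0 <- welchTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0[["t"]], 0)
  expect_equal(w0[["p"]], 1)
  w <- welchTTest(c(0, 1, 2), c(10, 11, 12))
  ref <- welchOracle(c(0, 1, 2), c(10, 11, 12))
  expect_equal(w[["t"]], ref[["t"]], tolerance = 1e-10)
  expect_equal(w[["dof"]], ref[["dof"]], tolerance = 1e-10)
  expect_equal(w[["p"]], ref[["p"]], tolerance = 1e-10)
  set.seed(3)
  a <- rnorm(15); b <- rnorm(40, 0.5, 2)
  w2 <- welchTTest(a, b); ref2 <- welchOracle(a, b)
  expect_equal(w2[["t"]], ref2[["t"]], tolerance = 1e-10)
  expect_equal(w2[["dof"]], ref2[["dof"]], tolerance = 1e-10)
  # zero variance in both groups with equal means
  wz <- welchTTest(c(2, 2, 2), c(2, 2))
  expect_equal(wz[["p"]], 1)
  expect_error(welchTTest(1, c(1, 2)), "at least 2")
})

test_that("BH step-up equals the brute-force definition", {
  res <- bhFDR(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
  expect_equal(res$reject, c(TRUE, TRUE, TRUE, FALSE))
  resAll1 <- bhFDR(rep(1, 5))
  expect_false(any(resAll1$reject))
  expect_equal(resAll1$adjusted, rep(1, 5))
  set.seed(4)
  for (i in 1:200) {
    p <- round(runif(sample(1:8, 1)), 3)
    got <- bhFDR(p, q = 0.05)
    ora <- bhOracle(p, q = 0.05)
    expect_equal(got$adjusted, ora$adjusted, tolerance = 1e-12)
    expect_identical(got$reject, ora$reject)
  }
  expect_error(bhFDR(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("group comparison adjusts within (metric, statistic) families", {
  set.seed(5)
  mk <- function(group, shiftSNc) {
    n <- if (group == "control") 40 else 60
    do.call(rbind, lapply(c("SNc", "Cau", "Pu"), function(r)
      data.frame(roi = r, metric = "R2star", statistic = "median",
                 group = group,
                 z = rnorm(n) + if (r == "SNc") shiftSNc else 0)))
  }
  cmp <- compareGroups(mk("control", 0), mk("patient", 2), "z", q = 0.05)
  expect_true(all(cmp$p_adjusted >= cmp$p_raw - 1e-15))
  expect_true(cmp$significant[cmp$roi == "SNc"])
  # significance is monotone in adjusted p
  ordP <- order(cmp$p_adjusted)
  expect_true(all(diff(cmp$significant[ordP] * 1) <= 0))
})

test_that("deviation matrices reshape the long table faithfully", {
  z <- expand.grid(subject_id = c("s1", "s2"), hemisphere = c("L", "R"),
                   roi = c("Cau", "Pu"), metric = c("R2star", "chi"),
                   statistic = "median", stringsAsFactors = FALSE)
  z$z <- seq_len(nrow(z))
  m <- deviationMatrix(z, "across_rois_per_metric", metric = "chi")
  expect_equal(dim(m), c(4L, 2L))
  expect_equal(sort(colnames(m)), c("Cau", "Pu"))
  expect_equal(m["s1|L", "Cau"],
               z$z[z$subject_id == "s1" & z$hemisphere == "L" &
                     z$roi == "Cau" & z$metric == "chi"])
  m2 <- deviationMatrix(z, "across_metrics_per_roi", roi = "Pu")
  expect_equal(sort(colnames(m2)), c("R2star", "chi"))
})
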