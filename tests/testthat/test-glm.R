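makeRows <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(age = runif(n, 18, 79),
             sex = sample(rep(c("F", "M"), length.out = n)),
             hemisphere = rep(c("L", "R"), length.out = n))
}

test_that("design matrix has the specified columns and coding", {
  rows <- makeRows(40)
  X <- buildDesign(rows)
  expect_equal(dim(X), c(40L, 5L))
  expect_equal(colnames(X),
               c("intercept", "age", "age2", "sex_c", "hemi_c"))
  expect_equal(X[, "age2"], rows$age^2)
  expect_equal(sum(X[, "sex_c"]), 0)
  expect_true(all(X[, "hemi_c"] %in% c(-0.5, 0.5)))
  rowsOneSex <- rows; rowsOneSex$sex <- "F"
  expect_error(buildDesign(rowsOneSex), "sex_c")
  rowsOneHemi <- rows; rowsOneHemi$hemisphere <- "L"
  expect_error(buildDesign(rowsOneHemi), "hemi_c")
})

test_that("OLS recovers noiseless coefficients and matches a QR oracle", {
  rows <- makeRows(60, seed = 2)
  X <- buildDesign(rows)
  betaTrue <- c(1, 0.004, -4e-5, 0.3, -0.1)
  y <- drop(X %*% betaTrue)
  fit <- fitGLM(y, X)
  expect_equal(unname(coefficients(fit)), betaTrue, tolerance = 1e-10)
  # intercept-only signal
  fit1 <- fitGLM(rep(1, 60), X)
  expect_equal(unname(coefficients(fit1))[-1], rep(0, 4),
               tolerance = 1e-10)
  # independent QR-based solver on random data
  set.seed(3)
  yr <- rnorm(60)
  ref <- qr.solve(X, yr)
  fitR <- fitGLM(yr, X)
  expect_equal(unname(coefficients(fitR)), unname(ref), tolerance = 1e-10)
  resid <- yr - X %*% ref
  s2 <- sum(resid^2) / (60 - 5)
  seRef <- sqrt(diag(solve(t(X) %*% X)) * s2)
  expect_equal(unname(fitR@se), unname(seRef), tolerance = 1e-10)
  expect_equal(fitR@dof, 55)
  # non-finite rows dropped with count
  yd <- yr; yd[c(3, 9)] <- NA
  fitD <- fitGLM(yd, X)
  expect_equal(fitD@nDropped, 2)
  expect_equal(fitD@dof, 53)
})

test_that("t-to-z conversion is exact, odd, monotone and finite", {
  expect_equal(tToZ(0, 7), 0)
  expect_equal(tToZ(1.96, 1e6), 1.96, tolerance = 0.01)
  # quadrature oracle for F_t at t = 2, dof = 10
  Ft <- integrate(function(u) dt(u, 10), -Inf, 2, rel.tol = 1e-12)$value
  expect_equal(tToZ(2, 10), qnorm(Ft), tolerance = 1e-6)
  ts <- seq(-40, 40, by = 0.5)
  zs <- tToZ(ts, 12)
  expect_true(all(diff(zs) > 0))
  expect_equal(zs, -rev(zs))
  expect_true(all(is.finite(tToZ(c(-500, 500), 3))))
})

test_that("residualisation removes exactly the fitted sex/hemisphere effects", {
  rows <- makeRows(80, seed = 4)
  X <- buildDesign(rows)
  set.seed(5)
  y <- drop(X %*% c(1, 0.01, 0, 0.4, -0.2)) + rnorm(80, 0, 0.1)
  fit <- fitGLM(y, X)
  yc <- residualize(y, X[, "sex_c"], X[, "hemi_c"], coefficients(fit))
  expect_true(attr(yc, "corrected"))
  refit <- fitGLM(as.numeric(yc), X)
  expect_lt(abs(coefficients(refit)[["sex_c"]]), 1e-10)
  expect_lt(abs(coefficients(refit)[["hemi_c"]]), 1e-10)
  # zero betas leave y unchanged
  y0 <- residualize(y, X[, "sex_c"], X[, "hemi_c"],
                    c(sex_c = 0, hemi_c = 0))
  expect_equal(as.numeric(y0), y)
  # hand construction: two subjects differing only in sex
  yPair <- c(1 + 0.4 * (-0.5), 1 + 0.4 * 0.5)
  ycPair <- residualize(yPair, c(-0.5, 0.5), c(0, 0),
                        c(sex_c = 0.4, hemi_c = 0))
  expect_equal(as.numeric(ycPair), c(1, 1), tolerance = 1e-10)
})

test_that("cohort-level GLM and correction are consistent", {
  specs <- trajectorySpec(c("Pu", "SNc"), "R2star",
                          intercept = c(18, 30), betaAge = c(0.25, 0.15),
                          betaSex = 0.5, betaHemi = 0.3, noiseSd0 = 2)
  co <- generateCohort(cohortDesign(nSubjects = 120, seed = 6), specs)
  g <- fitCohortGLM(co)
  expect_equal(nrow(g), 2 * 5)
  bAge <- g$beta[g$roi == "Pu" & g$regressor == "age"]
  seAge <- g$se[g$roi == "Pu" & g$regressor == "age"]
  expect_lt(abs(bAge - 0.25), 4 * seAge)
  corr <- correctCohort(co, g)
  g2 <- fitCohortGLM(corr)
  expect_lt(max(abs(g2$beta[g2$regressor %in% c("sex_c", "hemi_c")])),
            1e-10)
  expect_error(correctCohort(
    transform(co, roi = ifelse(roi == "Pu", "GPe", roi)), g), "GPe")
})
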