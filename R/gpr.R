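# Kernel matrix on standardised inputs: linear + squared-exponential +
# white noise. theta is on the log scale in the order
# (sigma2_se, lengthscale, sigma2_lin, sigma2_noise).
.gpKernel <- function(xa, xb, hyper, noise = FALSE) {
  d2 <- outer(xa, xb, `-`)^2
  K <- hyper[["sigma2_se"]] * exp(-0.5 * d2 / hyper[["lengthscale"]]^2) +
    hyper[["sigma2_lin"]] * outer(xa, xb)
  if (noise) K <- K + hyper[["sigma2_noise"]] * diag(length(xa))
  K
}

.gpNegLogML <- function(theta, x, y, d2, xx) {
  s2se <- exp(theta[1]); l <- exp(theta[2])
  s2lin <- exp(theta[3]); s2n <- exp(theta[4])
  n <- length(y)
  K <- s2se * exp(-0.5 * d2 / l^2) + s2lin * xx + (s2n + 1e-10) * diag(n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(list(value = 1e10, grad = rep(0, 4)))
  alpha <- backsolve(L, forwardsolve(t(L), y))
  nll <- 0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(L)
  W <- tcrossprod(alpha) - Kinv          # d logML / dK = W / 2
  Kse <- s2se * exp(-0.5 * d2 / l^2)
  g <- c(-0.5 * sum(W * Kse),
         -0.5 * sum(W * (Kse * (d2 / l^2))),
         -0.5 * sum(W * (s2lin * xx)),
         -0.5 * sum(diag(W)) * s2n)
  list(value = nll, grad = g)
}

#' Fit a Gaussian-process normative trajectory
#'
#' Exact GP regression of (corrected) metric values on age. Ages and
#' values are standardised; the kernel is linear + squared-exponential +
#' white noise, capturing both the linear trends of R2*/susceptibility
#' and the curved (inverted-U) R1 trajectories. Hyperparameters maximise
#' the exact log marginal likelihood by L-BFGS-B with analytic gradients
#' from several seeded restarts.
#'
#' @param ages training ages (years).
#' @param values training metric values (native units), already corrected
#'   for sex/hemisphere when used normatively.
#' @param seed RNG seed for the restart draws.
#' @param nRestarts number of optimiser restarts (first start is a fixed
#'   default; the rest are randomised).
#' @param roi,metric,statistic identifiers stored in the model.
#' @param correctionBetas optional named `c(sex_c, hemi_c)` betas to store
#'   for downstream correction bookkeeping.
#' @return a [NormativeModel-class].
#' @examples
#' set.seed(1)
#' age <- runif(60, 18, 79)
#' m <- fitGPR(age, 0.02 * age + rnorm(60, 0, 0.1), seed = 1, nRestarts = 2)
#' head(predict(m, c(30, 50, 70)))
#' @export
fitGPR <- function(ages, values, seed = 1, nRestarts = 5,
                   roi = "", metric = "", statistic = "",
                   correctionBetas = c(sex_c = NA_real_,
                                       hemi_c = NA_real_)) {
  n <- length(ages)
  if (n < 20) stop("GP normative fit requires at least 20 observations")
  if (length(values) != n) stop("ages and values length mismatch")
  if (!all(is.finite(values)) || !all(is.finite(ages)))
    stop("non-finite inputs")
  if (sd(values) < 1e-12) stop("near-zero value variance")

  xm <- mean(ages); xs <- sd(ages)
  ym <- mean(values); ys <- sd(values)
  x <- (ages - xm) / xs
  y <- (values - ym) / ys
  d2 <- outer(x, x, `-`)^2
  xx <- outer(x, x)

  lower <- log(c(1e-6, 0.05, 1e-8, 1e-6))
  upper <- log(c(1e2, 50, 1e2, 10))
  set.seed(seed)
  starts <- rbind(log(c(0.5, 1, 0.5, 0.1)))
  if (nRestarts > 1)
    starts <- rbind(starts, cbind(
      log(runif(nRestarts - 1, 0.05, 2)),
      log(runif(nRestarts - 1, 0.2, 4)),
      log(runif(nRestarts - 1, 0.01, 2)),
      log(runif(nRestarts - 1, 0.01, 1))))

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    env <- new.env()
    fn <- function(th) {
      r <- .gpNegLogML(th, x, y, d2, xx)
      env$last <- list(theta = th, grad = r$grad)
      r$value
    }
    gr <- function(th) {
      if (!is.null(env$last) && isTRUE(all.equal(env$last$theta, th)))
        return(env$last$grad)
      .gpNegLogML(th, x, y, d2, xx)$grad
    }
    res <- tryCatch(
      optim(starts[i, ], fn, gr, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 100, factr = 1e9)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value))
      best <- res
  }
  if (is.null(best))
    stop("marginal-likelihood optimisation failed on every restart ",
         "(n = ", n, ", sd(y) = ", signif(ys, 3), ")")

  hyper <- setNames(exp(best$par),
                    c("sigma2_se", "lengthscale", "sigma2_lin",
                      "sigma2_noise"))
  K <- .gpKernel(x, x, hyper, noise = TRUE) + 1e-10 * diag(n)
  L <- t(chol(K))
  alpha <- solve(t(L), solve(L, y))
  new("NormativeModel", roi = roi, metric = metric, statistic = statistic,
      hyper = hyper, xTrain = x, yTrain = y,
      xMean = xm, xSd = xs, yMean = ym, ySd = ys,
      alpha = as.numeric(alpha), L = L, logML = -best$value,
      correctionBetas = correctionBetas, cvFolds = NA_real_,
      cvSeed = NA_real_)
}

#' Predict the normative mean and predictive SD at new ages
#'
#' Exact GP posterior mean and standard deviation, de-standardised to
#' native units. The predictive SD includes the fitted noise variance, so
#' `(value - mean) / sd` is a calibrated deviation z-score for a new
#' observation; the 95% normative band is `mean +/- 1.96 * sd`. Ages
#' outside the training range are flagged as extrapolated.
#'
#' @param object a [NormativeModel-class].
#' @param newAges ages (years) at which to evaluate the trajectory.
#' @param ... unused.
#' @return data.frame with columns `age`, `mean`, `sd`, `extrapolated`.
#' @export
setMethod("predict", "NormativeModel", function(object, newAges, ...) {
  xs <- (newAges - object@xMean) / object@xSd
  ks <- .gpKernel(object@xTrain, xs, object@hyper)
  mu <- drop(crossprod(ks, object@alpha))
  v <- forwardsolve(object@L, ks)
  kss <- object@hyper[["sigma2_se"]] + object@hyper[["sigma2_lin"]] * xs^2
  varp <- pmax(kss - colSums(v^2), 0) + object@hyper[["sigma2_noise"]]
  data.frame(
    age = newAges,
    mean = mu * object@ySd + object@yMean,
    sd = sqrt(varp) * object@ySd,
    extrapolated = xs < min(object@xTrain) | xs > max(object@xTrain))
})

# Stratified fold assignment: subjects ordered by age are split into
# consecutive groups of k; within each group fold labels are a random
# permutation, so every fold covers the full age range.
.assignFolds <- function(subjectAges, k, seed) {
  n <- length(subjectAges)
  set.seed(seed)
  ord <- order(subjectAges)
  folds <- integer(n)
  i <- 1
  while (i <= n) {
    grp <- ord[i:min(i + k - 1, n)]
    folds[grp] <- sample(k)[seq_along(grp)]
    i <- i + k
  }
  folds
}

#' Cross-validated deviation z-scores for a reference cohort
#'
#' Subjects are shuffled (seeded, stratified by age so no fold forces
#' age extrapolation) into `k` folds; each subject's z-score comes from
#' the model fitted on the other `k - 1` folds. Both hemisphere rows of a
#' subject share a fold, preventing leakage of subject-level effects.
#'
#' @param ages,values observation-level ages and corrected values.
#' @param subjectIds subject identifier per observation.
#' @param k number of folds (default 10).
#' @param seed fold-shuffle and fit seed.
#' @param nRestarts optimiser restarts per fold model.
#' @return data.frame with `subject_id`, `age`, `value`, `z`,
#'   `predicted_mean`, `predicted_sd`, `fold`, `source = "crossval"`,
#'   in the input row order.
#' @export
zscoreCrossval <- function(ages, values, subjectIds, k = 10, seed = 1,
                           nRestarts = 5) {
  n <- length(ages)
  stopifnot(length(values) == n, length(subjectIds) == n)
  subj <- unique(subjectIds)
  if (length(subj) < 2 * k)
    stop("cross-validation requires at least 2 subjects per fold")
  subjAge <- ages[match(subj, subjectIds)]
  foldOf <- .assignFolds(subjAge, k, seed)
  if (any(tabulate(foldOf, k) < 2))
    stop("a fold received fewer than 2 subjects")
  fold <- foldOf[match(subjectIds, subj)]

  z <- pm <- ps <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    test <- fold == f
    m <- fitGPR(ages[!test], values[!test], seed = seed + f,
                nRestarts = nRestarts)
    pred <- predict(m, ages[test])
    pm[test] <- pred$mean
    ps[test] <- pred$sd
    z[test] <- (values[test] - pred$mean) / pred$sd
  }
  data.frame(subject_id = subjectIds, age = ages, value = values, z = z,
             predicted_mean = pm, predicted_sd = ps, fold = fold,
             source = "crossval", stringsAsFactors = FALSE)
}

#' Deviation z-scores for a new cohort against a frozen model
#'
#' Applies a fitted normative model to new observations. The values must
#' already be corrected with the *reference* cohort's sex/hemisphere
#' betas (see [residualize()] / [correctCohort()]); uncorrected input is
#' refused.
#'
#' @param model a [NormativeModel-class].
#' @param ages new ages (years).
#' @param values corrected values carrying `attr(, "corrected") = TRUE`.
#' @return data.frame with `age`, `value`, `z`, `predicted_mean`,
#'   `predicted_sd`, `source = "applied"`.
#' @export
zscoreApply <- function(model, ages, values) {
  if (!isTRUE(attr(values, "corrected")))
    stop("values are not flagged as corrected; apply residualize()/",
         "correctCohort() with the reference cohort's betas first")
  pred <- predict(model, ages)
  data.frame(age = ages, value = as.numeric(values),
             z = (as.numeric(values) - pred$mean) / pred$sd,
             predicted_mean = pred$mean, predicted_sd = pred$sd,
             source = "applied", stringsAsFactors = FALSE)
}

#' Fit normative models for every (roi, metric, statistic) cell
#'
#' @param cohort corrected long-format cohort table (see
#'   [correctCohort()]).
#' @param seed,nRestarts passed to [fitGPR()].
#' @param glmTable optional [fitCohortGLM()] table whose sex/hemisphere
#'   betas are stored in each model.
#' @return named list of [NormativeModel-class] objects, keyed
#'   `"roi|metric|statistic"`.
#' @export
fitNormativeModels <- function(cohort, seed = 1, nRestarts = 5,
                               glmTable = NULL) {
  cells <- unique(cohort[c("roi", "metric", "statistic")])
  models <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- cohort$roi == cells$roi[i] & cohort$metric == cells$metric[i] &
      cohort$statistic == cells$statistic[i]
    sub <- cohort[sel, , drop = FALSE]
    betas <- c(sex_c = NA_real_, hemi_c = NA_real_)
    if (!is.null(glmTable)) {
      g <- glmTable[glmTable$roi == cells$roi[i] &
                    glmTable$metric == cells$metric[i] &
                    glmTable$statistic == cells$statistic[i], ]
      betas <- c(sex_c = g$beta[g$regressor == "sex_c"],
                 hemi_c = g$beta[g$regressor == "hemi_c"])
    }
    key <- paste(cells$roi[i], cells$metric[i], cells$statistic[i],
                 sep = "|")
    models[[key]] <- fitGPR(sub$age, sub$value, seed = seed,
                            nRestarts = nRestarts, roi = cells$roi[i],
                            metric = cells$metric[i],
                            statistic = cells$statistic[i],
                            correctionBetas = betas)
  }
  models
}

#' Apply a set of frozen normative models to a corrected cohort table
#'
#' @param models list from [fitNormativeModels()].
#' @param cohort corrected cohort table (must carry `corrected == TRUE`).
#' @return long data.frame of deviation scores with the cohort's
#'   identifying columns plus `z`, `predicted_mean`, `predicted_sd`.
#' @export
zscoreApplyCohort <- function(models, cohort) {
  if (!isTRUE(all(cohort$corrected)))
    stop("cohort is not flagged as corrected; run correctCohort() with ",
         "the reference cohort's GLM betas first")
  out <- list()
  for (key in names(models)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    sel <- cohort$roi == parts[1] & cohort$metric == parts[2] &
      cohort$statistic == parts[3]
    if (!any(sel)) next
    sub <- cohort[sel, , drop = FALSE]
    vals <- structure(sub$value, corrected = TRUE)
    zs <- zscoreApply(models[[key]], sub$age, vals)
    out[[key]] <- cbind(sub[c("subject_id", "group", "age", "sex",
                              "hemisphere", "roi", "metric", "statistic")],
                        zs[c("z", "predicted_mean", "predicted_sd")])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
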