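#' Build the covariate design matrix
#'
#' Columns `[intercept, age, age^2, sex_c, hemi_c]`, one row per
#' observation (subject x hemisphere). Age enters raw (uncentred) and
#' squared raw; sex and hemisphere use the centred +/- 1/2 coding (F/L =
#' -1/2, M/R = +1/2) so that removing their fitted effects moves every
#' observation to the cohort-average sex and hemisphere.
#'
#' @param rows data.frame with columns `age`, `sex`, `hemisphere`.
#' @return numeric matrix with named columns.
#' @export
buildDesign <- function(rows) {
  stopifnot(all(c("age", "sex", "hemisphere") %in% names(rows)))
  sexc <- .sexCode(rows$sex)
  hemic <- .hemiCode(rows$hemisphere)
  if (length(unique(sexc)) < 2)
    stop("rank-deficient design: column sex_c has a single level")
  if (length(unique(hemic)) < 2)
    stop("rank-deficient design: column hemi_c has a single level")
  cbind(intercept = 1, age = rows$age, age2 = rows$age^2,
        sex_c = sexc, hemi_c = hemic)
}

#' Fit the covariate GLM by ordinary least squares
#'
#' OLS estimates with classical standard errors, `t = beta / se`,
#' residual dof `n - p`, and sign-preserving z-equivalents of the
#' t-statistics. Rows with non-finite response are dropped (count kept in
#' the fit).
#'
#' @param y response vector (one ROI/metric/statistic).
#' @param design matrix from [buildDesign()].
#' @return a [GLMFit-class].
#' @export
fitGLM <- function(y, design) {
  ok <- is.finite(y)
  nDropped <- sum(!ok)
  if (!any(ok)) stop("all response values are non-finite")
  y <- y[ok]
  X <- design[ok, , drop = FALSE]
  p <- ncol(X)
  if (nrow(X) <= p) stop("need more observations than regressors")
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  fit <- lm.fit(X, y)
  dof <- nrow(X) - p
  sigma2 <- sum(fit$residuals^2) / dof
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXinv) * sigma2)
  beta <- fit$coefficients
  t <- beta / se
  new("GLMFit", beta = setNames(as.numeric(beta), colnames(X)),
      se = setNames(as.numeric(se), colnames(X)),
      t = setNames(as.numeric(t), colnames(X)),
      z = setNames(tToZ(as.numeric(t), dof), colnames(X)),
      dof = dof, sigma2 = sigma2, nDropped = nDropped)
}

#' Convert t-statistics to z-statistics
#'
#' The sign-preserving two-sided quantile map
#' `z = qnorm(pt(t, dof))`, evaluated through log-scale tail
#' probabilities so large |t| give finite, strictly monotone z rather
#' than overflowing to infinity.
#'
#' @param t t-statistics (vectorised).
#' @param dof residual degrees of freedom (>= 1, recycled).
#' @return z-statistics of the same sign as `t`.
#' @examples
#' tToZ(2, 10)
#' @export
tToZ <- function(t, dof) {
  stopifnot(all(dof >= 1))
  logTail <- pt(-abs(t), df = dof, log.p = TRUE)  # upper-tail log prob
  z <- -qnorm(logTail, log.p = TRUE)
  out <- sign(t) * z
  out[t == 0] <- 0
  out
}

#' Remove fitted sex and hemisphere effects
#'
#' `y - betaSex * sex_c - betaHemi * hemi_c`; the age terms are left
#' untouched so the corrected values retain the full age trajectory. For
#' an external cohort, pass the reference cohort's betas. The result
#' carries a `corrected` attribute consumed by [zscoreApply()].
#'
#' @param y values to correct.
#' @param sexC,hemiC centred +/- 1/2 covariates (use [buildDesign()] or
#'   the raw `sex`/`hemisphere` columns via `sex`/`hemisphere` args).
#' @param betas named vector containing `sex_c` and `hemi_c` (as from a
#'   [GLMFit-class] `coefficients()`).
#' @return corrected numeric vector with `attr(, "corrected") = TRUE`.
#' @export
residualize <- function(y, sexC, hemiC, betas) {
  if (!all(c("sex_c", "hemi_c") %in% names(betas)))
    stop("betas must contain named elements sex_c and hemi_c")
  if (length(sexC) != length(y) || length(hemiC) != length(y))
    stop("covariate length mismatch")
  out <- y - betas[["sex_c"]] * sexC - betas[["hemi_c"]] * hemiC
  attr(out, "corrected") <- TRUE
  out
}

#' Fit the covariate GLM for every (roi, metric, statistic) cell
#'
#' @param cohort long-format cohort data.frame (see [generateCohort()]).
#' @return a data.frame with one row per (roi, metric, statistic,
#'   regressor) carrying `beta`, `se`, `t`, `z`, `dof`.
#' @export
fitCohortGLM <- function(cohort) {
  cells <- unique(cohort[c("roi", "metric", "statistic")])
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- cohort$roi == cells$roi[i] & cohort$metric == cells$metric[i] &
      cohort$statistic == cells$statistic[i]
    sub <- cohort[sel, , drop = FALSE]
    fit <- fitGLM(sub$value, buildDesign(sub))
    data.frame(roi = cells$roi[i], metric = cells$metric[i],
               statistic = cells$statistic[i],
               regressor = names(fit@beta), beta = unname(fit@beta),
               se = unname(fit@se), t = unname(fit@t), z = unname(fit@z),
               dof = fit@dof, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Correct a cohort table for sex and hemisphere effects
#'
#' Applies [residualize()] per (roi, metric, statistic) cell, using either
#' the cohort's own GLM fits or a reference table of betas (e.g. when
#' scoring an external cohort against a reference cohort's models).
#'
#' @param cohort long-format cohort data.frame.
#' @param glmTable result of [fitCohortGLM()] (on this cohort or the
#'   reference cohort).
#' @return the cohort with `value` replaced by the corrected value and a
#'   logical column `corrected` set to `TRUE`.
#' @export
correctCohort <- function(cohort, glmTable) {
  out <- cohort
  out$corrected <- TRUE
  key <- paste(glmTable$roi, glmTable$metric, glmTable$statistic)
  for (k in unique(key)) {
    g <- glmTable[key == k, ]
    betas <- setNames(g$beta, g$regressor)
    sel <- paste(cohort$roi, cohort$metric, cohort$statistic) == k
    if (!any(sel)) next
    corr <- residualize(cohort$value[sel], .sexCode(cohort$sex[sel]),
                        .hemiCode(cohort$hemisphere[sel]), betas)
    out$value[sel] <- as.numeric(corr)
  }
  miss <- !(paste(cohort$roi, cohort$metric, cohort$statistic) %in% key)
  if (any(miss))
    stop("no GLM betas for: ",
         paste(unique(paste(cohort$roi[miss], cohort$metric[miss],
                            sep = "/")), collapse = ", "))
  out
}
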