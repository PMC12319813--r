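#' Cohort design for the synthetic generator
#'
#' @param nSubjects number of control subjects.
#' @param ageRange inclusive age range in years (ages drawn uniformly).
#' @param sexBalance fraction of female subjects (assigned exactly, then
#'   shuffled).
#' @param seed integer RNG seed; every draw of [generateCohort()] is
#'   determined by it.
#' @param nPatients number of additional patient-group subjects.
#' @param patientEffect additive shift applied to patient values: either a
#'   named numeric vector (ROI -> units, applied to every metric of that
#'   ROI) or a data.frame with columns `roi`, `metric`, `delta`.
#' @return a list of class `"CohortDesign"`.
#' @export
cohortDesign <- function(nSubjects = 260, ageRange = c(18, 79),
                         sexBalance = 0.5, seed = 1,
                         nPatients = 0, patientEffect = NULL) {
  stopifnot(nSubjects >= 2, length(ageRange) == 2, ageRange[1] < ageRange[2],
            sexBalance >= 0, sexBalance <= 1, nPatients >= 0)
  structure(list(nSubjects = nSubjects, ageRange = ageRange,
                 sexBalance = sexBalance, seed = as.integer(seed),
                 nPatients = nPatients, patientEffect = patientEffect),
            class = "CohortDesign")
}

#' Build a table of per-ROI trajectory specifications
#'
#' One row per (ROI, metric) pair, holding the generative counterparts of
#' the covariate-model coefficients: value at age 0 (`intercept`), linear
#' and quadratic age slopes, additive sex and hemisphere offsets (for the
#' centred +/- 1/2 coding), a heteroscedastic noise law
#' `sd(age) = noiseSd0 + noiseSdSlope * (age - 18)`, and a latent-network
#' membership (`networkId` in `"A"`, `"B"` or `"none"`) with loading in
#' native units.
#'
#' @param roi,metric character vectors (recycled to a common length).
#' @param intercept,betaAge,betaAge2,betaSex,betaHemi trajectory
#'   coefficients in native units (per year, per year^2 as appropriate).
#' @param noiseSd0 residual SD at age 18 (must be positive).
#' @param noiseSdSlope change of residual SD per year.
#' @param networkId,networkLoading latent cross-ROI covariance structure.
#' @return a data.frame of class `"TrajectorySpec"`.
#' @seealso [defaultTrajectorySpecs()] for the shipped parameter set.
#' @export
trajectorySpec <- function(roi, metric, intercept, betaAge = 0, betaAge2 = 0,
                           betaSex = 0, betaHemi = 0, noiseSd0 = 1,
                           noiseSdSlope = 0, networkId = "none",
                           networkLoading = 0) {
  df <- data.frame(roi = roi, metric = metric, intercept = intercept,
                   betaAge = betaAge, betaAge2 = betaAge2,
                   betaSex = betaSex, betaHemi = betaHemi,
                   noiseSd0 = noiseSd0, noiseSdSlope = noiseSdSlope,
                   networkId = networkId, networkLoading = networkLoading,
                   stringsAsFactors = FALSE)
  if (any(df$noiseSd0 < 0))
    stop("noiseSd0 must be non-negative")
  badHet <- df$noiseSd0 + df$noiseSdSlope * (80 - 18) < 0
  if (any(badHet))
    stop("noise SD must stay positive over ages 18-80 for: ",
         paste(df$roi[badHet], df$metric[badHet], sep = "/", collapse = ", "))
  if (anyDuplicated(df[c("roi", "metric")]))
    stop("duplicate (roi, metric) rows in trajectory specification")
  class(df) <- c("TrajectorySpec", "data.frame")
  df
}

#' Default trajectory parameter set
#'
#' Reads the parameter table shipped with the package: quadratic R1
#' trajectories peaking between 45 and 60 years, linear R2* and magnetic
#' susceptibility increases in iron-rich nuclei, mild heteroscedasticity,
#' small sex/hemisphere offsets, and two latent covariance networks
#' (caudate + putamen; pallidum/nigra/red-nucleus/subthalamic/ventral-
#' pallidum group). Values are illustrative of healthy-ageing basal-ganglia
#' qMRI, not fitted to any dataset.
#'
#' @return a `"TrajectorySpec"` data.frame.
#' @export
defaultTrajectorySpecs <- function() {
  path <- system.file("extdata", "default_trajectories.tsv",
                      package = "qmrinorm", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  do.call(trajectorySpec, setNames(as.list(df), c(
    "roi", "metric", "intercept", "betaAge", "betaAge2", "betaSex",
    "betaHemi", "noiseSd0", "noiseSdSlope", "networkId", "networkLoading")))
}

.sexCode <- function(sex) {
  s <- as.character(sex)
  map <- c("F" = -0.5, "M" = 0.5, "0" = -0.5, "1" = 0.5,
           "f" = -0.5, "m" = 0.5, "female" = -0.5, "male" = 0.5)
  out <- unname(map[s])
  if (any(is.na(out) & !is.na(s)))
    stop("unrecognised sex coding: ", paste(unique(s[is.na(out)]), collapse = ", "))
  out
}

.hemiCode <- function(h) {
  s <- as.character(h)
  map <- c("L" = -0.5, "R" = 0.5, "left" = -0.5, "right" = 0.5)
  out <- unname(map[s])
  if (any(is.na(out) & !is.na(s)))
    stop("unrecognised hemisphere coding: ",
         paste(unique(s[is.na(out)]), collapse = ", "))
  out
}

#' Generate a synthetic long-format cohort table
#'
#' Draws a seeded cohort with near-uniform ages, exact sex balance and two
#' hemisphere rows per subject x ROI x metric. Each value is
#' `intercept + betaAge * age + betaAge2 * age^2 + betaSex * sex_c +
#' betaHemi * hemi_c + loading * latent + eps`, where `sex_c`/`hemi_c` use
#' the centred +/- 1/2 coding, `latent` is a per-subject standard-normal
#' factor shared by every ROI in the same network, and
#' `eps ~ N(0, (noiseSd0 + noiseSdSlope * (age - 18))^2)`. Patient-group
#' subjects additionally receive the design's `patientEffect` shift.
#'
#' @param design a [cohortDesign()] object.
#' @param specs a [trajectorySpec()] table.
#' @param rois,metrics optional subsets to generate; every requested
#'   (roi, metric) pair must be covered by `specs`.
#' @return a long data.frame with columns `subject_id`, `group`, `age`,
#'   `sex`, `hemisphere`, `roi`, `metric`, `statistic` (always
#'   `"median"`), `value`.
#' @examples
#' specs <- trajectorySpec("Pu", "R2star", intercept = 25, betaAge = 0.2,
#'                         noiseSd0 = 2)
#' head(generateCohort(cohortDesign(nSubjects = 10, seed = 7), specs))
#' @export
generateCohort <- function(design, specs, rois = NULL, metrics = NULL) {
  stopifnot(inherits(design, "CohortDesign"), inherits(specs, "TrajectorySpec"))
  if (!is.null(rois) || !is.null(metrics)) {
    wantR <- if (is.null(rois)) unique(specs$roi) else rois
    wantM <- if (is.null(metrics)) unique(specs$metric) else metrics
    want <- expand.grid(roi = wantR, metric = wantM,
                        stringsAsFactors = FALSE)
    have <- paste(specs$roi, specs$metric)
    miss <- !(paste(want$roi, want$metric) %in% have)
    if (any(miss))
      stop("no trajectory specification for: ",
           paste(want$roi[miss], want$metric[miss], sep = "/", collapse = ", "))
    specs <- specs[specs$roi %in% wantR & specs$metric %in% wantM, ,
                   drop = FALSE]
  }

  nC <- design$nSubjects
  nP <- design$nPatients
  n <- nC + nP
  set.seed(design$seed)

  age <- runif(n, design$ageRange[1], design$ageRange[2])
  nF <- round(nC * design$sexBalance)
  sexC <- sample(c(rep("F", nF), rep("M", nC - nF)))
  sexP <- if (nP > 0) sample(c(rep("F", round(nP * design$sexBalance)),
                               rep("M", nP - round(nP * design$sexBalance))))
          else character(0)
  sex <- c(sexC, sexP)
  group <- c(rep("control", nC), rep("patient", nP))
  id <- sprintf("sub-%04d", seq_len(n))
  latent <- cbind(A = rnorm(n), B = rnorm(n), none = 0)

  nS <- nrow(specs)
  # row order: spec-major, then subject, then hemisphere L/R
  out <- data.frame(
    subject_id = rep(id, times = nS, each = 2),
    group = rep(group, times = nS, each = 2),
    age = rep(age, times = nS, each = 2),
    sex = rep(sex, times = nS, each = 2),
    hemisphere = rep(c("L", "R"), times = nS * n),
    roi = rep(specs$roi, each = 2 * n),
    metric = rep(specs$metric, each = 2 * n),
    statistic = "median",
    stringsAsFactors = FALSE)

  sexc <- .sexCode(out$sex)
  hemic <- .hemiCode(out$hemisphere)
  sp <- specs[rep(seq_len(nS), each = 2 * n), , drop = FALSE]
  lat <- latent[cbind(rep(rep(seq_len(n), each = 2), times = nS),
                      match(sp$networkId, colnames(latent)))]
  sdv <- sp$noiseSd0 + sp$noiseSdSlope * (out$age - 18)
  eps <- rnorm(nrow(out), 0, sdv)
  value <- sp$intercept + sp$betaAge * out$age + sp$betaAge2 * out$age^2 +
    sp$betaSex * sexc + sp$betaHemi * hemic +
    sp$networkLoading * lat + eps

  if (nP > 0 && !is.null(design$patientEffect)) {
    pe <- design$patientEffect
    if (is.data.frame(pe)) {
      key <- paste(out$roi, out$metric)
      delta <- pe$delta[match(key, paste(pe$roi, pe$metric))]
    } else {
      delta <- unname(pe[out$roi])
    }
    delta[is.na(delta)] <- 0
    value <- value + delta * (out$group == "patient")
  }
  out$value <- value
  rownames(out) <- NULL
  out
}
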