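#' Assemble and validate a pipeline configuration
#'
#' @param cohort reference cohort: TSV path or data.frame.
#' @param outDir output directory (created if absent).
#' @param appliedCohort optional second cohort (TSV path or data.frame)
#'   to score against the frozen reference models; its `group` column
#'   separates controls from patients.
#' @param seed master seed recorded in every output.
#' @param cvFolds cross-validation folds for reference z-scores.
#' @param gprRestarts optimiser restarts per normative fit.
#' @param fdrQ FDR level for the group comparison.
#' @param networkThresholds correlation thresholds for the deviation
#'   networks.
#' @param statistic which summary statistic to model.
#' @return validated config list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(cohort, outDir, appliedCohort = NULL, seed = 1,
                           cvFolds = 10, gprRestarts = 5, fdrQ = 0.05,
                           networkThresholds = c(0.4, 0.6),
                           statistic = "median") {
  if (is.character(cohort) && !file.exists(cohort))
    stop("cohort file does not exist: ", cohort)
  if (is.character(appliedCohort) && !is.null(appliedCohort) &&
      !file.exists(appliedCohort))
    stop("applied cohort file does not exist: ", appliedCohort)
  stopifnot(cvFolds >= 2, gprRestarts >= 1, fdrQ > 0, fdrQ < 1)
  structure(list(cohort = cohort, outDir = outDir,
                 appliedCohort = appliedCohort, seed = as.integer(seed),
                 cvFolds = cvFolds, gprRestarts = gprRestarts,
                 fdrQ = fdrQ, networkThresholds = networkThresholds,
                 statistic = statistic),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipelineConfig()]
#'   arguments.
#' @return a `"PipelineConfig"`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, y)
}

.loadCohortInput <- function(x) {
  if (is.character(x)) readCohort(x) else x
}

#' Run the normative-modelling pipeline end to end
#'
#' Executes the cohort-level stages in dependency order: covariate GLM,
#' sex/hemisphere correction, Gaussian-process normative fits,
#' cross-validated deviation z-scores, deviation-correlation matrices
#' and thresholded networks, and — when an applied cohort is supplied —
#' scoring of that cohort against the frozen models followed by a Welch
#' patient-versus-control comparison (on z-scores and on corrected
#' values) under BH-FDR control. All artefacts are TSV/JSON files in
#' `outDir`; a manifest records the seed, parameters and per-stage row
#' counts. Reruns with an identical config reproduce identical outputs.
#'
#' @param config a [pipelineConfig()] (or YAML path).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "qmrinorm",
                   version = as.character(utils::packageVersion("qmrinorm")),
                   seed = config$seed,
                   parameters = config[c("cvFolds", "gprRestarts", "fdrQ",
                                         "networkThresholds", "statistic")],
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohort <- stage("read_cohort", .loadCohortInput(config$cohort))
  cohort <- cohort[cohort$statistic == config$statistic, , drop = FALSE]
  manifest$stages$read_cohort <- list(rows = nrow(cohort))

  glmTable <- stage("glm", fitCohortGLM(cohort))
  writeCohortTSV <- function(df, name) {
    write.table(df, file.path(config$outDir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  writeCohortTSV(glmTable, "glm.tsv")
  manifest$stages$glm <- list(rows = nrow(glmTable))

  corrected <- stage("correct", correctCohort(cohort, glmTable))
  writeCohortTSV(corrected, "corrected.tsv")
  manifest$stages$correct <- list(rows = nrow(corrected))

  models <- stage("gpr", fitNormativeModels(
    corrected, seed = config$seed, nRestarts = config$gprRestarts,
    glmTable = glmTable))
  saveNormativeModels(models, file.path(config$outDir, "models.json"))
  manifest$stages$gpr <- list(models = length(models))

  zref <- stage("zscores_crossval", {
    cells <- unique(corrected[c("roi", "metric", "statistic")])
    zs <- lapply(seq_len(nrow(cells)), function(i) {
      sel <- corrected$roi == cells$roi[i] &
        corrected$metric == cells$metric[i] &
        corrected$statistic == cells$statistic[i]
      sub <- corrected[sel, , drop = FALSE]
      cv <- zscoreCrossval(sub$age, sub$value, sub$subject_id,
                           k = config$cvFolds, seed = config$seed,
                           nRestarts = config$gprRestarts)
      cbind(sub[c("subject_id", "group", "age", "sex", "hemisphere",
                  "roi", "metric", "statistic")],
            cv[c("z", "predicted_mean", "predicted_sd", "fold")])
    })
    out <- do.call(rbind, zs); rownames(out) <- NULL; out
  })
  writeCohortTSV(zref, "zscores.tsv")
  manifest$stages$zscores_crossval <- list(rows = nrow(zref))

  networks <- list()
  for (met in unique(zref$metric)) {
    dm <- deviationMatrix(zref, "across_rois_per_metric", metric = met,
                          statistic = config$statistic)
    if (ncol(dm) < 2) next
    cm <- corrMatrix(dm)
    writeCohortTSV(data.frame(roi = rownames(cm), cm,
                              check.names = FALSE),
                   paste0("corr_", met, ".tsv"))
    networks[[met]] <- lapply(config$networkThresholds, function(thr)
      list(threshold = thr,
           components = thresholdNetwork(cm, thr)$components))
  }
  jsonlite::write_json(networks, file.path(config$outDir, "networks.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$stages$networks <- list(metrics = length(networks))

  comparison <- NULL
  if (!is.null(config$appliedCohort)) {
    applied <- stage("read_applied", .loadCohortInput(config$appliedCohort))
    applied <- applied[applied$statistic == config$statistic, ,
                       drop = FALSE]
    appliedCorr <- stage("correct_applied",
                         correctCohort(applied, glmTable))
    zApplied <- stage("zscores_applied",
                      zscoreApplyCohort(models, appliedCorr))
    writeCohortTSV(zApplied, "zscores_applied.tsv")
    manifest$stages$zscores_applied <- list(rows = nrow(zApplied))

    ctrl <- zApplied[zApplied$group == "control", , drop = FALSE]
    pat <- zApplied[zApplied$group == "patient", , drop = FALSE]
    if (nrow(ctrl) && nrow(pat)) {
      comparison <- stage("compare", {
        onZ <- compareGroups(ctrl, pat, "z", q = config$fdrQ)
        ctrlV <- appliedCorr[appliedCorr$group == "control", ]
        patV <- appliedCorr[appliedCorr$group == "patient", ]
        onV <- compareGroups(ctrlV, patV, "value", q = config$fdrQ)
        list(z = onZ, value = onV)
      })
      writeCohortTSV(comparison$z, "comparison_z.tsv")
      writeCohortTSV(comparison$value, "comparison_value.tsv")
      manifest$stages$compare <- list(cells = nrow(comparison$z))
    }
  }

  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(glm = glmTable, corrected = corrected, models = models,
                 zscores = zref, networks = networks,
                 comparison = comparison, manifest = manifest))
}

#' Extract per-subject ROI metrics from maps into a cohort table
#'
#' Convenience wrapper over [roiStatistics()] for a set of subjects whose
#' quantitative maps share one parcellation: builds the long cohort rows
#' consumed by the statistical stages.
#'
#' @param maps named list `subject_id -> 3D array` (one metric).
#' @param labels integer label array common to all subjects.
#' @param rois named vector `roi_name -> label value`.
#' @param covariates data.frame with `subject_id`, `age`, `sex`; one row
#'   per subject.
#' @param metric metric name recorded in the table.
#' @param hemisphereLabels optional named list
#'   `roi_name -> c(L = label, R = label)` when hemispheres carry
#'   distinct labels; otherwise rows are marked `pooled`.
#' @return long cohort data.frame (statistics `median`, `iqr`,
#'   `skewness`).
#' @export
extractCohortMetrics <- function(maps, labels, rois, covariates,
                                 metric, hemisphereLabels = NULL) {
  rows <- list()
  for (sid in names(maps)) {
    cov <- covariates[covariates$subject_id == sid, , drop = FALSE]
    if (nrow(cov) != 1) stop("covariates missing for subject ", sid)
    for (rn in names(rois)) {
      hl <- if (is.null(hemisphereLabels) || is.null(hemisphereLabels[[rn]]))
        c(pooled = rois[[rn]]) else hemisphereLabels[[rn]]
      for (h in names(hl)) {
        st <- roiStatistics(maps[[sid]], labels, hl[[h]])
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = sid, group = "control", age = cov$age,
          sex = cov$sex, hemisphere = h, roi = rn, metric = metric,
          statistic = c("median", "iqr", "skewness"),
          value = unname(st), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
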