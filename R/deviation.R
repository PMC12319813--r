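#' Reshape a long deviation-score table into a wide matrix
#'
#' Rows are observations (subject x hemisphere), columns are either the
#' metrics of one ROI (`axis = "across_metrics_per_roi"`) or the ROIs of
#' one metric (`axis = "across_rois_per_metric"`).
#'
#' @param zscores long table with `subject_id`, `hemisphere`, `roi`,
#'   `metric`, `statistic`, `z` (as from [zscoreCrossval()] /
#'   [zscoreApplyCohort()]).
#' @param axis which correlation structure is being studied.
#' @param roi,metric the fixed ROI (for the metric axis) or fixed metric
#'   (for the ROI axis).
#' @param statistic which summary statistic's z-scores to use.
#' @return numeric matrix with observation rownames and ROI/metric
#'   colnames; missing cells are `NA`.
#' @export
deviationMatrix <- function(zscores,
                            axis = c("across_rois_per_metric",
                                     "across_metrics_per_roi"),
                            roi = NULL, metric = NULL,
                            statistic = "median") {
  axis <- match.arg(axis)
  sub <- zscores[zscores$statistic == statistic, , drop = FALSE]
  if (axis == "across_rois_per_metric") {
    if (is.null(metric)) stop("metric must be given for the ROI axis")
    sub <- sub[sub$metric == metric, , drop = FALSE]
    colKey <- sub$roi
  } else {
    if (is.null(roi)) stop("roi must be given for the metric axis")
    sub <- sub[sub$roi == roi, , drop = FALSE]
    colKey <- sub$metric
  }
  rowKey <- paste(sub$subject_id, sub$hemisphere, sep = "|")
  rows <- unique(rowKey); cols <- unique(colKey)
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  m[cbind(match(rowKey, rows), match(colKey, cols))] <- sub$z
  m
}

#' Pearson correlation matrix of deviation scores
#'
#' Pairwise-complete Pearson correlations with a symmetric result, unit
#' diagonal, and `NA` (with a warning) for cells backed by fewer than 3
#' complete pairs or by a zero-variance column.
#'
#' @param m numeric matrix (observations x variables).
#' @return correlation matrix.
#' @export
corrMatrix <- function(m) {
  p <- ncol(m)
  zeroVar <- apply(m, 2, function(col) {
    v <- col[is.finite(col)]
    length(v) > 0 && sd(v) == 0
  })
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  nPair <- crossprod(!is.na(m))
  bad <- nPair < 3 | outer(zeroVar, zeroVar, `|`)
  diag(bad) <- FALSE
  if (any(bad)) {
    warning(sum(bad) / 2, " correlation cell(s) undefined ",
            "(fewer than 3 complete pairs or zero variance)")
    r[bad] <- NA_real_
  }
  diag(r) <- 1
  (r + t(r)) / 2
}

#' Threshold a correlation matrix into a deviation network
#'
#' Keeps undirected edges with `r >= threshold` (positive correlations
#' only) and returns them together with the connected components, sorted
#' by decreasing size — the "networks of variation" of jointly
#' fluctuating nuclei.
#'
#' @param corr symmetric correlation matrix with dimnames.
#' @param threshold edge threshold (e.g. 0.4 or 0.6).
#' @return list with `edges` (data.frame `from`, `to`, `r`) and
#'   `components` (list of character vectors of node names).
#' @export
thresholdNetwork <- function(corr, threshold) {
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-8,
                        check.attributes = FALSE)))
    stop("correlation matrix must be symmetric")
  nodes <- colnames(corr)
  if (is.null(nodes)) nodes <- as.character(seq_len(ncol(corr)))
  adj <- !is.na(corr) & corr >= threshold
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                      r = corr[idx], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  comp <- igraph::components(g)
  comps <- split(nodes, comp$membership)
  comps <- comps[order(-vapply(comps, length, integer(1)))]
  names(comps) <- NULL
  list(edges = edges, components = comps)
}

#' Welch two-sample t-test
#'
#' Welch statistic with Satterthwaite degrees of freedom and a two-sided
#' p-value; groups with zero variance and equal means return `t = 0,
#' p = 1` by convention.
#'
#' @param groupA,groupB numeric vectors (each n >= 2).
#' @return named numeric `c(t, dof, p, mean_a, mean_b, n_a, n_b)`.
#' @export
welchTTest <- function(groupA, groupB) {
  groupA <- groupA[is.finite(groupA)]
  groupB <- groupB[is.finite(groupB)]
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs at least 2 finite observations")
  va <- var(groupA); vb <- var(groupB)
  if (va == 0 && vb == 0) {
    if (mean(groupA) == mean(groupB))
      return(c(t = 0, dof = length(groupA) + length(groupB) - 2, p = 1,
               mean_a = mean(groupA), mean_b = mean(groupB),
               n_a = length(groupA), n_b = length(groupB)))
    stop("zero variance in both groups with unequal means")
  }
  ht <- t.test(groupA, groupB, var.equal = FALSE)
  c(t = unname(ht$statistic), dof = unname(ht$parameter),
    p = ht$p.value, mean_a = mean(groupA), mean_b = mean(groupB),
    n_a = length(groupA), n_b = length(groupB))
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Adjusted p-values via the step-up rule (`stats::p.adjust`,
#' method `"BH"`) and rejection flags at level `q`.
#'
#' @param p raw p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `adjusted` (same order as input) and `reject`
#'   (logical).
#' @export
bhFDR <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  list(adjusted = adj, reject = adj <= q)
}

#' Patient-versus-control comparison with FDR control
#'
#' Welch t-tests per (roi, metric, statistic) cell comparing a value
#' column (z-scores or corrected medians) between two groups, with
#' Benjamini-Hochberg adjustment within each (metric, statistic) family
#' of ROIs. By default the two hemisphere rows of a subject are pooled
#' (averaged) before testing, so each subject contributes one
#' observation; hemisphere rows are correlated within subject and
#' treating them as independent would overstate the evidence.
#'
#' @param controls,patients long tables carrying `roi`, `metric`,
#'   `statistic` and the column named by `valueCol`.
#' @param valueCol column to compare (`"z"` or `"value"`).
#' @param q FDR level.
#' @param poolSubjects average within subject before testing (requires a
#'   `subject_id` column; silently disabled when absent).
#' @return data.frame with one row per cell: Welch `t`, `dof`, `p_raw`,
#'   `p_adjusted`, `significant`, group means and sizes.
#' @export
compareGroups <- function(controls, patients, valueCol = "z", q = 0.05,
                          poolSubjects = TRUE) {
  poolTab <- function(df) {
    if (!poolSubjects || !"subject_id" %in% names(df)) return(df)
    agg <- stats::aggregate(
      df[[valueCol]],
      by = df[c("subject_id", "roi", "metric", "statistic")], FUN = mean)
    names(agg)[ncol(agg)] <- valueCol
    agg
  }
  controls <- poolTab(controls)
  patients <- poolTab(patients)
  cells <- unique(rbind(controls[c("roi", "metric", "statistic")],
                        patients[c("roi", "metric", "statistic")]))
  res <- lapply(seq_len(nrow(cells)), function(i) {
    selC <- controls$roi == cells$roi[i] &
      controls$metric == cells$metric[i] &
      controls$statistic == cells$statistic[i]
    selP <- patients$roi == cells$roi[i] &
      patients$metric == cells$metric[i] &
      patients$statistic == cells$statistic[i]
    w <- welchTTest(controls[[valueCol]][selC], patients[[valueCol]][selP])
    data.frame(roi = cells$roi[i], metric = cells$metric[i],
               statistic = cells$statistic[i],
               t = w[["t"]], dof = w[["dof"]], p_raw = w[["p"]],
               mean_controls = w[["mean_a"]], mean_patients = w[["mean_b"]],
               n_controls = w[["n_a"]], n_patients = w[["n_b"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- NA_real_
  out$significant <- NA
  fam <- paste(out$metric, out$statistic)
  for (f in unique(fam)) {
    sel <- fam == f
    adj <- bhFDR(out$p_raw[sel], q)
    out$p_adjusted[sel] <- adj$adjusted
    out$significant[sel] <- adj$reject
  }
  rownames(out) <- NULL
  out
}
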