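#' Read a 3D quantitative or label map from NIfTI-1
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @return an `RNifti` `niftiImage` (array with affine metadata; use
#'   [mapAffine()] for the voxel-to-mm matrix).
#' @export
readMap <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4 && d[4] == 1) img <- img[, , , 1]
  else if (length(d) != 3)
    stop("expected a 3D map; got dimensions [",
         paste(d, collapse = " x "), "] - select a volume first")
  img
}

#' Write a 3D map to NIfTI-1
#'
#' @param data numeric or integer 3D array (or `niftiImage`). Integer
#'   storage is preserved as an integer datatype on disk.
#' @param path output file (`.nii.gz`).
#' @param affine optional 4 x 4 voxel-to-mm matrix applied as the
#'   sform/qform (RAS).
#' @return the path, invisibly.
#' @export
writeMap <- function(data, path, affine = NULL) {
  img <- RNifti::asNifti(data)
  if (!is.null(affine)) {
    # pixdim carries the voxel scale; the qform rotation must be
    # unit-normalised or the scale would be applied twice on write
    scales <- sqrt(colSums(affine[1:3, 1:3]^2))
    RNifti::pixdim(img) <- scales
    affn <- affine
    affn[1:3, 1:3] <- sweep(affine[1:3, 1:3], 2, scales, "/")
    RNifti::qform(img) <- structure(affn, code = 2L)
    RNifti::sform(img) <- structure(affine, code = 2L)
  }
  dtype <- if (is.integer(data)) "int32" else "double"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Voxel-to-mm affine of a map
#'
#' @param img a `niftiImage` from [readMap()].
#' @return 4 x 4 matrix mapping 0-based voxel indices to mm (RAS).
#' @export
mapAffine <- function(img) {
  m <- RNifti::xform(img)
  attributes(m) <- list(dim = dim(m))
  m
}

#' Check that a subject's maps share one grid
#'
#' @param ... arrays/`niftiImage`s to compare.
#' @return `TRUE` invisibly; otherwise an error listing the shapes.
#' @export
checkSameGrid <- function(...) {
  dims <- lapply(list(...), dim)
  if (length(unique(lapply(dims, paste, collapse = "x"))) > 1)
    stop("maps are on different grids: ",
         paste(vapply(dims, paste, "", collapse = "x"), collapse = " vs "))
  invisible(TRUE)
}

.cohortColumns <- c("subject_id", "age", "sex", "hemisphere", "roi",
                    "metric", "statistic", "value")

#' Read a long-format cohort table from TSV
#'
#' Validates the schema, types the columns, normalises sex coding
#' (`M`/`F` or `0`/`1`, logged via a message) and rejects duplicate
#' (subject, roi, hemisphere, metric, statistic) records. Unknown columns
#' are preserved; a missing `group` column defaults to `"control"`.
#'
#' @param path TSV file.
#' @return data.frame in the cohort schema.
#' @export
readCohort <- function(path) {
  if (file.size(path) == 0) stop("cohort file is empty: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("cohort file has no rows: ", path)
  miss <- setdiff(.cohortColumns, names(df))
  if (length(miss))
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "))
  if (!"group" %in% names(df)) df$group <- "control"
  raw <- unique(as.character(df$sex))
  sexc <- .sexCode(df$sex)          # validates the dialect
  df$sex <- ifelse(sexc < 0, "F", "M")
  if (!all(raw %in% c("F", "M")))
    message("sex coding normalised: ",
            paste(raw, ifelse(.sexCode(raw) < 0, "F", "M"),
                  sep = "->", collapse = ", "))
  df$age <- as.numeric(df$age)
  df$value <- as.numeric(df$value)
  key <- paste(df$subject_id, df$roi, df$hemisphere, df$metric,
               df$statistic)
  if (anyDuplicated(key))
    stop("duplicate (subject, roi, hemisphere, metric, statistic) rows, ",
         "e.g.: ", key[duplicated(key)][1])
  df
}

#' Write a cohort table to TSV
#'
#' @param cohort data.frame in the cohort schema.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialise a signal dictionary to a JSON sidecar
#'
#' Records the protocol and the R1/B1 grid definitions; the simulated
#' entries are regenerated exactly on load, so the sidecar stays small
#' and text-only.
#'
#' @param dict a [SignalDictionary-class].
#' @param path output `.json` file.
#' @return the path, invisibly.
#' @export
saveDictionary <- function(dict, path) {
  p <- dict@protocol
  jsonlite::write_json(list(
    protocol = list(TI1 = p@TI1, TI2 = p@TI2, TR = p@TR,
                    alpha1 = p@alpha1, alpha2 = p@alpha2,
                    readoutTR = p@readoutTR, nReadout = p@nReadout,
                    inversionEfficiency = p@inversionEfficiency),
    r1Range = range(dict@r1Grid),
    r1Step = if (length(dict@r1Grid) > 1) diff(dict@r1Grid[1:2]) else 1,
    b1Range = range(dict@b1Grid),
    b1Step = if (length(dict@b1Grid) > 1) diff(dict@b1Grid[1:2]) else 0.005),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a dictionary saved with [saveDictionary()]
#'
#' @param path `.json` sidecar.
#' @return a [SignalDictionary-class] with regenerated entries.
#' @export
loadDictionary <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  protocol <- do.call(mp2rageProtocol, as.list(s$protocol))
  buildDictionary(protocol, r1Range = s$r1Range, r1Step = s$r1Step,
                  b1Range = s$b1Range, b1Step = s$b1Step)
}

#' Serialise normative models to JSON
#'
#' Stores, per model, the kernel hyperparameters, standardisation
#' constants, training arrays and correction betas — everything needed
#' to reconstruct predictions exactly.
#'
#' @param models list from [fitNormativeModels()].
#' @param path output `.json` file.
#' @return the path, invisibly.
#' @export
saveNormativeModels <- function(models, path) {
  ser <- lapply(models, function(m) list(
    roi = m@roi, metric = m@metric, statistic = m@statistic,
    hyper = as.list(m@hyper),
    xMean = m@xMean, xSd = m@xSd, yMean = m@yMean, ySd = m@ySd,
    ages = m@xTrain * m@xSd + m@xMean,
    values = m@yTrain * m@ySd + m@yMean,
    logML = m@logML,
    correctionBetas = as.list(m@correctionBetas)))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Load normative models saved with [saveNormativeModels()]
#'
#' @param path `.json` file.
#' @return named list of [NormativeModel-class] objects.
#' @export
loadNormativeModels <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(ser, function(s) {
    hyper <- unlist(s$hyper)
    x <- (s$ages - s$xMean) / s$xSd
    y <- (s$values - s$yMean) / s$ySd
    K <- .gpKernel(x, x, hyper, noise = TRUE) + 1e-10 * diag(length(x))
    L <- t(chol(K))
    alpha <- solve(t(L), solve(L, y))
    new("NormativeModel", roi = s$roi, metric = s$metric,
        statistic = s$statistic, hyper = hyper, xTrain = x, yTrain = y,
        xMean = s$xMean, xSd = s$xSd, yMean = s$yMean, ySd = s$ySd,
        alpha = as.numeric(alpha), L = L, logML = s$logML,
        correctionBetas = {
          cb <- c(sex_c = NA_real_, hemi_c = NA_real_)
          for (nm in intersect(names(s$correctionBetas), names(cb))) {
            v <- suppressWarnings(as.numeric(s$correctionBetas[[nm]]))
            if (length(v) == 1 && is.finite(v)) cb[[nm]] <- v
          }
          cb
        },
        cvFolds = NA_real_, cvSeed = NA_real_)
  })
  names(out) <- names(ser)
  out
}
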