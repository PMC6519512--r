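## Plain-text readers and writers: TSV ROI series and confounds, CSV edge
## tables with a JSON edge-map sidecar.

#' Write / read ROI time series as TSV
#'
#' Time-by-ROI table, tab separated, header = ROI names.
#'
#' @param ts an [ROITimeSeries-class].
#' @param path output file.
#' @return `writeROISeries`: invisibly, the path. `readROISeries`: an
#'   [ROITimeSeries-class].
#' @export
writeROISeries <- function(ts, path) {
  stopifnot(is(ts, "ROITimeSeries"))
  utils::write.table(ts@values, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeROISeries
#' @param tr repetition time of the stored series, seconds.
#' @export
readROISeries <- function(path, tr) {
  x <- as.matrix(utils::read.delim(path, check.names = FALSE))
  ROITimeSeries(x, tr = tr)
}

#' Write / read confounds as TSV
#'
#' Headers carry the role as `role.index` (e.g. `motion.1`, `spike.3`) so
#' the role tags round-trip.
#'
#' @param confounds a [ConfoundSet-class].
#' @param path output file.
#' @return `writeConfounds`: invisibly, the path. `readConfounds`: a
#'   [ConfoundSet-class].
#' @export
writeConfounds <- function(confounds, path) {
  stopifnot(is(confounds, "ConfoundSet"))
  v <- confounds@values
  colnames(v) <- sprintf("%s.%d", confounds@roles,
                         seq_along(confounds@roles))
  utils::write.table(v, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeConfounds
#' @export
readConfounds <- function(path) {
  x <- as.matrix(utils::read.delim(path, check.names = FALSE))
  roles <- sub("\\.[0-9]+$", "", colnames(x))
  ConfoundSet(x, roles)
}

#' Write / read a subject-by-edge table as CSV (+ JSON sidecar)
#'
#' The CSV has columns `subject_id`, `label`, `edge_0001`, ...; the optional
#' JSON sidecar records the edge map (ROI pairs and names), the ROI labels
#' and any ground-truth signal edges, so a table round-trips losslessly.
#'
#' @param table an [EdgeTable-class].
#' @param csvPath output CSV path.
#' @param jsonPath optional sidecar path (default: `csvPath` with a
#'   `.json` extension).
#' @return `writeEdgeTable`: invisibly, `csvPath`. `readEdgeTable`: an
#'   [EdgeTable-class].
#' @export
writeEdgeTable <- function(table, csvPath, jsonPath = NULL) {
  stopifnot(is(table, "EdgeTable"))
  if (is.null(jsonPath)) jsonPath <- paste0(csvPath, ".json")
  x <- edgeMatrix(table)
  colnames(x) <- rownames(table)
  df <- data.frame(subject_id = subjectIds(table),
                   label = groupLabels(table), x, check.names = FALSE)
  utils::write.csv(df, csvPath, row.names = FALSE)
  em <- edgeMap(table)
  jsonlite::write_json(
    list(roiNames = roiNames(table),
         signalEdges = signalEdges(table),
         edgeMap = em[, c("edge", "roi_i", "roi_j", "roi_name_i",
                          "roi_name_j")]),
    jsonPath, auto_unbox = FALSE, digits = NA)
  invisible(csvPath)
}

#' @rdname writeEdgeTable
#' @export
readEdgeTable <- function(csvPath, jsonPath = NULL) {
  if (is.null(jsonPath)) {
    cand <- paste0(csvPath, ".json")
    jsonPath <- if (file.exists(cand)) cand else NULL
  }
  df <- utils::read.csv(csvPath, check.names = FALSE)
  x <- as.matrix(df[, -(1:2), drop = FALSE])
  rois <- NULL; sig <- NULL
  if (!is.null(jsonPath)) {
    side <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
    rois <- side$roiNames
    sig <- side$signalEdges
    if (!length(sig)) sig <- NULL
  }
  EdgeTable(x, labels = df$label, roiNames = rois,
            subjectIds = df$subject_id, signalEdges = sig)
}

#' Read pipeline configuration from YAML
#'
#' The file may hold any [PipelineParams()] fields under `params:` and
#' grid-search grids under `grids:` (`p0`, `n`, `c`); missing entries fall
#' back to the package defaults.
#'
#' @param path YAML file.
#' @return List with `params` (a [PipelineParams-class]) and `grids`.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines(c("params:", "  p0: 0.01", "  repeats: 5",
#'              "grids:", "  c: [0.5, 1.0]"), f)
#' readPipelineConfig(f)$params
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  p <- cfg$params
  if (is.null(p)) p <- list()
  params <- do.call(PipelineParams, p)
  grids <- defaultGrids()
  for (g in intersect(names(cfg$grids), names(grids)))
    grids[[g]] <- cfg$grids[[g]]
  list(params = params, grids = grids)
}

#' Write a per-fold JSON log of a repeated-CV run
#'
#' One record per fold: repeat and fold ids, held-out subjects, screened
#' and selected edge indices, test metrics (or the failure message), and
#' decision scores -- an audit trail of what each training fold selected.
#'
#' @param results a [CVResults-class].
#' @param path output JSON file.
#' @return Invisibly, the path.
#' @export
writeFoldLog <- function(results, path) {
  stopifnot(is(results, "CVResults"))
  recs <- lapply(results@folds, function(f) {
    r <- list(repeat_id = f$repeat_id, fold_id = f$fold_id,
              test_subjects = f$testIdx, n_screened = length(f$screened),
              selected_edges = f$selected)
    if (is.null(f$failure)) {
      r$metrics <- f$metrics[c("accuracy", "sensitivity", "specificity",
                               "recall", "precision")]
      r$scores <- unname(f$scores)
    } else r$failure <- f$failure
    r
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a linear SVM model as JSON
#'
#' Serializes feature indices, standardized-scale weights, bias, cost and
#' the training standardization parameters, so a model can be re-applied to
#' new data without refitting.
#'
#' @param model an [SVMModel-class].
#' @param path JSON file.
#' @return `writeSVMModel`: invisibly, the path. `readSVMModel`: an
#'   [SVMModel-class].
#' @export
writeSVMModel <- function(model, path) {
  stopifnot(is(model, "SVMModel"))
  jsonlite::write_json(
    list(featureIndices = model@featureIndices, weights = model@weights,
         bias = model@bias, cost = model@cost,
         center = model@center, scale = model@scale),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeSVMModel
#' @export
readSVMModel <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SVMModel", featureIndices = as.integer(m$featureIndices),
      weights = as.numeric(m$weights), bias = as.numeric(m$bias),
      cost = as.numeric(m$cost), center = as.numeric(m$center),
      scale = as.numeric(m$scale))
}

#' Write ROC curve points to CSV
#'
#' @param roc the list returned by [rocAUC()] (or a curve data.frame).
#' @param path CSV file.
#' @return Invisibly, the path.
#' @export
writeROC <- function(roc, path) {
  curve <- if (is.data.frame(roc)) roc else roc$curve
  utils::write.csv(curve, path, row.names = FALSE)
  invisible(path)
}
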