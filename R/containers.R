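#' Construct an ROI time-series object
#'
#' @param values numeric matrix, timepoints x ROIs.
#' @param tr repetition time in seconds.
#' @param roiNames optional ROI labels; defaults to existing column names or
#'   `ROI_001`-style labels.
#' @return A [ROITimeSeries-class] object.
#' @examples
#' ts <- ROITimeSeries(matrix(rnorm(40), 10, 4), tr = 2)
#' repetitionTime(ts)
#' @export
ROITimeSeries <- function(values, tr, roiNames = NULL) {
  values <- as.matrix(values)
  if (is.null(roiNames)) roiNames <- colnames(values)
  if (is.null(roiNames))
    roiNames <- sprintf("ROI_%03d", seq_len(ncol(values)))
  colnames(values) <- roiNames
  new("ROITimeSeries", values = values, tr = as.numeric(tr))
}

#' Construct a confound set
#'
#' @param values numeric matrix, timepoints x regressors.
#' @param roles character role per column: `"motion"`, `"motion_derivative"`,
#'   `"csf"`, `"wm"` or `"spike"`.
#' @return A [ConfoundSet-class] object.
#' @export
ConfoundSet <- function(values, roles) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("%s_%d", roles, seq_along(roles))
  new("ConfoundSet", values = values, roles = as.character(roles))
}

#' Canonical edge order for n ROIs
#'
#' Edges are the strict upper triangle of the ROI-by-ROI matrix flattened
#' row-major: edge k runs over i = 1..n-1, j = i+1..n, so that edge 1 is the
#' pair (1, 2) and edge n(n-1)/2 the pair (n-1, n). All edge indices in the
#' package are 1-based and follow this order.
#'
#' @param n number of ROIs (n >= 2).
#' @return Integer matrix with n(n-1)/2 rows and columns `i`, `j`.
#' @examples
#' edgePairs(4)     # 6 edges; last row is (3, 4)
#' @export
edgePairs <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 2L)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i = i, j = j)
}

#' Map an edge index to its ROI pair
#'
#' Inverse of the canonical flattening of [edgePairs()]; round-trips with
#' [vectorizeEdges()].
#'
#' @param k edge index (1-based), may be a vector.
#' @param n number of ROIs.
#' @return Integer matrix with columns `i`, `j`, one row per element of `k`.
#' @examples
#' edgeIndexToPair(1, 90)      # (1, 2)
#' edgeIndexToPair(4005, 90)   # (89, 90)
#' @export
edgeIndexToPair <- function(k, n) {
  n <- as.integer(n)
  nE <- n * (n - 1L) / 2L
  k <- as.integer(k)
  if (any(k < 1L) || any(k > nE))
    stop("edge index out of range 1..", nE, " for n = ", n)
  # row i holds (n - i) edges; solve for i from the cumulative count
  kk <- k - 1L
  i <- floor((2 * n - 1 - sqrt((2 * n - 1)^2 - 8 * kk)) / 2) + 1
  i <- as.integer(i)
  start <- (i - 1L) * n - (i * (i - 1L)) %/% 2L  # edges before row i (0-based)
  j <- as.integer(kk - start + i + 1L)
  cbind(i = i, j = j)
}

#' Number of ROIs implied by an edge count
#' @param nEdges number of edges, must equal n(n-1)/2 for integer n.
#' @return n, the ROI count.
#' @keywords internal
roiCountFromEdges <- function(nEdges) {
  n <- (1 + sqrt(1 + 8 * nEdges)) / 2
  if (abs(n - round(n)) > 1e-8)
    stop(nEdges, " is not a triangular number: no ROI count gives this many edges")
  as.integer(round(n))
}

#' Construct a subject-by-edge feature table
#'
#' @param values numeric matrix, subjects x edges (edge count must be
#'   n(n-1)/2 for some ROI count n, in the canonical order of [edgePairs()]).
#' @param labels per-subject group label, 0 = control, 1 = patient.
#' @param roiNames optional ROI labels (length n).
#' @param subjectIds optional subject identifiers.
#' @param signalEdges optional integer vector of ground-truth discriminative
#'   edge indices (stored in `metadata`).
#' @return An [EdgeTable-class] object.
#' @examples
#' x <- EdgeTable(matrix(rnorm(8 * 6), 8, 6), labels = rep(0:1, each = 4))
#' edgeMap(x)[1:3, ]
#' @export
EdgeTable <- function(values, labels, roiNames = NULL, subjectIds = NULL,
                      signalEdges = NULL) {
  values <- as.matrix(values)
  nS <- nrow(values); nE <- ncol(values)
  n <- roiCountFromEdges(nE)
  labels <- as.integer(labels)
  if (length(labels) != nS)
    stop("need one label per subject")
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0 (control) or 1 (patient)")
  if (length(unique(labels)) < 2L)
    stop("labels must contain both classes")
  if (is.null(roiNames)) roiNames <- sprintf("ROI_%03d", seq_len(n))
  if (length(roiNames) != n)
    stop("need ", n, " ROI names for ", nE, " edges")
  if (is.null(subjectIds)) subjectIds <- sprintf("sub_%03d", seq_len(nS))
  pairs <- edgePairs(n)
  wid <- max(4L, nchar(nE))
  edgeIds <- sprintf("edge_%0*d", wid, seq_len(nE))
  rd <- S4Vectors::DataFrame(edge = seq_len(nE),
                             roi_i = pairs[, 1L], roi_j = pairs[, 2L],
                             roi_name_i = roiNames[pairs[, 1L]],
                             roi_name_j = roiNames[pairs[, 2L]],
                             row.names = edgeIds)
  cd <- S4Vectors::DataFrame(subject_id = subjectIds, label = labels,
                             row.names = subjectIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fc = t(values)), rowData = rd, colData = cd,
    metadata = list(roiNames = roiNames,
                    signalEdges = as.integer(signalEdges)))
  new("EdgeTable", se)
}

#' Pipeline parameter constructor
#'
#' @param p0 t-test screening threshold (default 0.05).
#' @param nOccurrence inner occurrence threshold N (default 5).
#' @param svmCost linear-SVM cost c (default 1).
#' @param kOuter,kInner outer / inner folds (default 10 / 10).
#' @param repeats outer repetitions (default 100).
#' @param nPermutations default permutation count (default 1000).
#' @param lambdaFolds nested lambda-selection CV folds (default 5).
#' @param nLambda,lambdaMinRatio lambda path controls (default 100, 1e-3).
#' @param stratified stratify outer folds by group (default TRUE).
#' @param seed master RNG seed (default 1).
#' @return A [PipelineParams-class] object.
#' @export
PipelineParams <- function(p0 = 0.05, nOccurrence = 5L, svmCost = 1,
                           kOuter = 10L, kInner = 10L, repeats = 100L,
                           nPermutations = 1000L, lambdaFolds = 5L,
                           nLambda = 100L, lambdaMinRatio = 1e-3,
                           stratified = TRUE, seed = 1L) {
  new("PipelineParams", p0 = p0, nOccurrence = as.integer(nOccurrence),
      svmCost = svmCost, kOuter = as.integer(kOuter),
      kInner = as.integer(kInner), repeats = as.integer(repeats),
      nPermutations = as.integer(nPermutations),
      lambdaFolds = as.integer(lambdaFolds), nLambda = as.integer(nLambda),
      lambdaMinRatio = lambdaMinRatio, stratified = stratified,
      seed = as.integer(seed))
}

## ---- accessors -----------------------------------------------------------

#' @rdname FCSelect-generics
#' @export
setMethod("repetitionTime", "ROITimeSeries", function(x) x@tr)

#' @rdname FCSelect-generics
#' @export
setMethod("roiNames", "ROITimeSeries", function(x) colnames(x@values))

#' @rdname FCSelect-generics
#' @export
setMethod("roiNames", "ConnectivityMatrix", function(x) rownames(x@values))

#' @rdname FCSelect-generics
#' @export
setMethod("roiNames", "EdgeTable",
          function(x) S4Vectors::metadata(x)$roiNames)

#' @rdname FCSelect-generics
#' @export
setMethod("seriesValues", "ROITimeSeries", function(x) x@values)

#' @rdname FCSelect-generics
#' @export
setMethod("seriesValues", "ConfoundSet", function(x) x@values)

#' @rdname FCSelect-generics
#' @export
setMethod("seriesValues", "ConnectivityMatrix", function(x) x@values)

#' @rdname FCSelect-generics
#' @export
setMethod("confoundRoles", "ConfoundSet", function(x) x@roles)

#' @rdname FCSelect-generics
#' @export
setMethod("edgeMatrix", "EdgeTable",
          function(x) t(SummarizedExperiment::assay(x, "fc")))

#' @rdname FCSelect-generics
#' @export
setMethod("edgeMap", "EdgeTable", function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))
})

#' @rdname FCSelect-generics
#' @export
setMethod("groupLabels", "EdgeTable",
          function(x) SummarizedExperiment::colData(x)$label)

#' @rdname FCSelect-generics
#' @export
setMethod("subjectIds", "EdgeTable",
          function(x) SummarizedExperiment::colData(x)$subject_id)

#' @rdname FCSelect-generics
#' @export
setMethod("signalEdges", "EdgeTable",
          function(x) S4Vectors::metadata(x)$signalEdges)

#' @rdname FCSelect-generics
#' @export
setMethod("signalEdges", "SyntheticSpec", function(x) x@signalEdges)

#' @rdname FCSelect-generics
#' @export
setMethod("foldResults", "CVResults", function(x) x@folds)

#' @rdname FCSelect-generics
#' @export
setMethod("pipelineParams", "CVResults", function(x) x@params)

#' @rdname FCSelect-generics
#' @export
setMethod("stableEdges", "StabilityReport", function(x) x@table$edge)

## ---- show methods --------------------------------------------------------

setMethod("show", "ROITimeSeries", function(object) {
  cat(sprintf("ROITimeSeries: %d timepoints x %d ROIs, TR = %g s (%.1f s scan)\n",
              nrow(object@values), ncol(object@values), object@tr,
              nrow(object@values) * object@tr))
})

setMethod("show", "ConfoundSet", function(object) {
  tab <- table(factor(object@roles,
                      c("motion", "motion_derivative", "csf", "wm", "spike")))
  cat(sprintf("ConfoundSet: %d timepoints x %d regressors (%s)\n",
              nrow(object@values), ncol(object@values),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  v <- object@values[upper.tri(object@values)]
  cat(sprintf("ConnectivityMatrix: %d ROIs, %d edges, r in [%.3f, %.3f]\n",
              nrow(object@values), length(v), min(v), max(v)))
})

setMethod("show", "EdgeTable", function(object) {
  y <- groupLabels(object)
  cat(sprintf("EdgeTable: %d subjects (%d controls, %d patients) x %d edges (%d ROIs)\n",
              ncol(object), sum(y == 0L), sum(y == 1L), nrow(object),
              length(roiNames(object))))
  gt <- signalEdges(object)
  if (length(gt))
    cat("  ground-truth signal edges:", paste(gt, collapse = ", "), "\n")
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(paste0("SyntheticSpec: %d vs %d subjects, %d ROIs (%d edges), ",
                     "%d timepoints @ TR %g s\n"),
              object@nGroup0, object@nGroup1, object@nRoi,
              object@nRoi * (object@nRoi - 1L) / 2L,
              object@nTimepoints, object@tr))
  cat(sprintf("  %d signal edges, delta = %g (r scale), d = %g (edge scale), seed %d\n",
              nrow(object@signalEdges), object@delta, object@effectSizeD,
              object@seed))
})

setMethod("show", "PipelineParams", function(object) {
  cat(sprintf("PipelineParams: p0 = %g, N = %d, c = %g\n",
              object@p0, object@nOccurrence, object@svmCost))
  cat(sprintf("  CV: %d x %d-fold outer (stratified: %s), %d-fold inner, %d-fold lambda CV\n",
              object@repeats, object@kOuter, object@stratified,
              object@kInner, object@lambdaFolds))
  cat(sprintf("  lambda path: %d values to %g * lambda_max; permutations: %d; seed %d\n",
              object@nLambda, object@lambdaMinRatio, object@nPermutations,
              object@seed))
})

setMethod("show", "CVResults", function(object) {
  ok <- vapply(object@folds, function(f) is.null(f$failure), logical(1))
  cat(sprintf("CVResults: %d fold evaluations (%d failed), %d subjects x %d edges\n",
              length(object@folds), sum(!ok), object@nSubjects, object@nEdges))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult: B = %d\n", object@B))
  cat(sprintf("  accuracy %.4f vs null mean %.4f -> p = %.4g\n",
              object@observedAccuracy, mean(object@nullAccuracy),
              object@pAccuracy))
  cat(sprintf("  AUC      %.4f vs null mean %.4f -> p = %.4g\n",
              object@observedAUC, mean(object@nullAUC), object@pAUC))
})

setMethod("show", "StabilityReport", function(object) {
  cat(sprintf("StabilityReport: %d stable edges (occurrence > %g of %d folds)\n",
              nrow(object@table), object@threshold, object@nFolds))
  cat(sprintf("  mean LASSO features per training fold: %.3f; FWE: %s at alpha = %g\n",
              object@meanSelectedCount, object@fweMethod, object@alpha))
  if (nrow(object@table)) {
    df <- object@table
    cat(sprintf("  %-30s occ %5d  w %.4f  p_fwe %.4g %s (%s)\n",
                paste(df$roi_name_i, "-", df$roi_name_j),
                df$occurrence, df$weight, df$p_fwe,
                ifelse(df$significant, "*", " "), df$direction))
  }
  cat("  note: group-difference tests are post hoc on the full sample after\n",
      " selection on the same data (circular); interpret p-values accordingly.\n")
})
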