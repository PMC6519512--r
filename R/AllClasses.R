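#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats cor lm.fit pt rnorm runif sd setNames var predict coef
#' @importFrom utils head write.csv read.csv
NULL

#' ROI time-series container
#'
#' Holds one subject's region-of-interest (ROI) time series: a numeric
#' time-by-ROI matrix together with the repetition time (TR, seconds).
#' Column names are the ROI labels in atlas order.
#'
#' @slot values numeric matrix, timepoints x ROIs; column names are ROI labels.
#' @slot tr repetition time in seconds.
#'
#' @seealso [ROITimeSeries()], [cleanTimeseries()], [correlationMatrix()]
#' @exportClass ROITimeSeries
setClass("ROITimeSeries",
  representation(values = "matrix", tr = "numeric"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v)) return("'values' must be a numeric matrix")
    if (anyNA(v) || any(!is.finite(v))) return("'values' contains missing or non-finite entries")
    if (nrow(v) < 2) return("at least 2 timepoints are required")
    if (is.null(colnames(v))) return("'values' must carry ROI names as column names")
    if (anyDuplicated(colnames(v))) return("ROI names must be unique")
    if (length(object@tr) != 1 || !is.finite(object@tr) || object@tr <= 0)
      return("'tr' must be a single positive number (seconds)")
    TRUE
  })

#' Confound regressor container
#'
#' Time-by-regressor nuisance matrix with a role tag per column. Roles follow
#' the usual resting-state cleaning recipe: head-motion parameters and their
#' first-order derivatives, mean CSF and white-matter signals, and 0/1 spike
#' (scrubbing) indicators marking motion-corrupted volumes.
#'
#' @slot values numeric matrix, timepoints x regressors.
#' @slot roles character vector, one of `"motion"`, `"motion_derivative"`,
#'   `"csf"`, `"wm"`, `"spike"` per column.
#'
#' @seealso [simulateConfounds()], [cleanTimeseries()]
#' @exportClass ConfoundSet
setClass("ConfoundSet",
  representation(values = "matrix", roles = "character"),
  validity = function(object) {
    ok <- c("motion", "motion_derivative", "csf", "wm", "spike")
    if (ncol(object@values) != length(object@roles))
      return("one role per confound column is required")
    if (length(object@roles) && !all(object@roles %in% ok))
      return(paste0("roles must be in {", paste(ok, collapse = ", "), "}"))
    sp <- which(object@roles == "spike")
    for (j in sp) {
      if (!all(object@values[, j] %in% c(0, 1)))
        return("spike columns must be 0/1 indicators")
    }
    TRUE
  })

#' ROI-by-ROI connectivity matrix
#'
#' Symmetric Pearson-correlation matrix over ROIs with unit diagonal.
#'
#' @slot values numeric n_roi x n_roi matrix with ROI names as dimnames.
#'
#' @seealso [correlationMatrix()], [vectorizeEdges()]
#' @exportClass ConnectivityMatrix
setClass("ConnectivityMatrix",
  representation(values = "matrix"),
  validity = function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) return("connectivity matrix must be square")
    if (is.null(rownames(v))) return("ROI names required as dimnames")
    if (max(abs(v - t(v))) > 1e-8) return("connectivity matrix must be symmetric")
    if (max(abs(diag(v) - 1)) > 1e-8) return("diagonal must be 1")
    if (max(abs(v)) > 1 + 1e-8) return("entries must lie in [-1, 1]")
    TRUE
  })

#' Subject-by-edge feature table
#'
#' The pipeline's feature container: one functional-connectivity value per
#' subject and edge, stored as a [SummarizedExperiment::SummarizedExperiment]
#' with edges as rows and subjects as columns. `rowData` carries the canonical
#' edge map (edge index k, ROI indices i < j, ROI names); `colData` carries
#' the subject identifiers and the binary group label (0 = control,
#' 1 = patient). Ground-truth signal edges of synthetic cohorts, if any, are
#' recorded in `metadata(x)$signalEdges`.
#'
#' Use [EdgeTable()] to construct one from a subjects-by-edges matrix, and
#' [edgeMatrix()], [groupLabels()], [edgeMap()] to access the modelling view.
#'
#' @seealso [EdgeTable()], [simulateEdgeTable()], [connectivityPipeline()]
#' @exportClass EdgeTable
setClass("EdgeTable", contains = "SummarizedExperiment",
  validity = function(object) {
    cd <- SummarizedExperiment::colData(object)
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("subject_id", "label") %in% colnames(cd)))
      return("colData must contain 'subject_id' and 'label'")
    if (!all(cd$label %in% c(0L, 1L)))
      return("labels must be 0 (control) or 1 (patient)")
    if (!all(c("edge", "roi_i", "roi_j") %in% colnames(rd)))
      return("rowData must contain 'edge', 'roi_i', 'roi_j'")
    n <- max(rd$roi_j)
    if (nrow(object) != n * (n - 1) / 2)
      return("row count must equal n_roi*(n_roi-1)/2 for the implied ROI count")
    if (any(rd$roi_i >= rd$roi_j)) return("edge map must satisfy roi_i < roi_j")
    if (anyDuplicated(rd$roi_i * (n + 1) + rd$roi_j)) return("edge map must be a bijection")
    TRUE
  })

#' Synthetic two-group cohort specification
#'
#' Describes a synthetic resting-state cohort: group sizes, ROI count, scan
#' length and TR, which edges carry a group difference, and how large that
#' difference is on the two simulation routes (correlation-scale `delta` for
#' the time-series route, standardized mean difference `effectSizeD` for the
#' direct edge-table route).
#'
#' Defaults mirror the cohort every downstream default assumes: 30 controls
#' vs 39 patients, 90 ROIs (4005 edges), 205 timepoints at TR = 2 s, and five
#' signal edges.
#'
#' @slot nRoi number of ROIs.
#' @slot nGroup0,nGroup1 subjects in group 0 (controls) / group 1 (patients).
#' @slot nTimepoints scan length in volumes.
#' @slot tr repetition time, seconds.
#' @slot signalEdges integer matrix with columns `i`, `j` (i < j): ROI pairs
#'   carrying the planted group difference.
#' @slot delta correlation difference (group1 - group0) per signal edge.
#' @slot effectSizeD standardized mean difference for the direct edge route.
#' @slot edgeSd standard deviation of edge values on the direct route
#'   (Fisher-z scale).
#' @slot baseRank rank of the background covariance factor model.
#' @slot seed integer RNG seed.
#'
#' @seealso [SyntheticSpec()], [simulateEdgeTable()], [makeGroupCovariances()]
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(nRoi = "integer", nGroup0 = "integer", nGroup1 = "integer",
                 nTimepoints = "integer", tr = "numeric",
                 signalEdges = "matrix", delta = "numeric",
                 effectSizeD = "numeric", edgeSd = "numeric",
                 baseRank = "integer", seed = "integer"),
  validity = function(object) {
    cnt <- c(object@nRoi, object@nGroup0, object@nGroup1, object@nTimepoints,
             object@baseRank)
    if (any(cnt <= 0L)) return("all counts must be positive")
    if (object@tr <= 0) return("'tr' must be positive seconds")
    if (object@edgeSd <= 0) return("'edgeSd' must be positive")
    se <- object@signalEdges
    if (nrow(se)) {
      if (ncol(se) != 2) return("'signalEdges' needs columns i, j")
      if (any(se[, 1] >= se[, 2])) return("signal edges must satisfy i < j")
      if (any(se < 1) || any(se > object@nRoi)) return("signal edge ROI out of range")
      if (anyDuplicated(se[, 1] * (object@nRoi + 1L) + se[, 2]))
        return("signal edges must be distinct")
    }
    TRUE
  })

#' Pipeline tuning parameters
#'
#' The tunables the pipeline grid-searches plus the cross-validation layout:
#' `p0` is the two-sample t-test screening threshold, `nOccurrence` the
#' number of inner CV-LASSO repetitions (out of `kInner`) an edge must be
#' selected in, and `svmCost` the linear-SVM cost. `repeats` outer
#' repetitions of `kOuter`-fold CV give `repeats * kOuter` test-fold
#' evaluations. `lambdaFolds` controls the nested CV used to pick the LASSO
#' penalty by the one-standard-error rule.
#'
#' @slot p0 screening p-value threshold, 0 < p0 <= 1.
#' @slot nOccurrence inner occurrence threshold N, 1..kInner.
#' @slot svmCost SVM cost c > 0.
#' @slot kOuter,kInner outer / inner fold counts (default 10 each).
#' @slot repeats outer CV repetitions (default 100).
#' @slot nPermutations default permutation count (default 1000).
#' @slot lambdaFolds folds of the nested lambda-selection CV (default 5).
#' @slot nLambda,lambdaMinRatio lambda path: `nLambda` log-spaced values from
#'   lambda_max down to `lambdaMinRatio * lambda_max`.
#' @slot stratified logical; stratify outer folds by group (default TRUE).
#' @slot seed master RNG seed.
#'
#' @seealso [PipelineParams()], [runRepeatedCV()], [gridSearch()]
#' @exportClass PipelineParams
setClass("PipelineParams",
  representation(p0 = "numeric", nOccurrence = "integer", svmCost = "numeric",
                 kOuter = "integer", kInner = "integer", repeats = "integer",
                 nPermutations = "integer", lambdaFolds = "integer",
                 nLambda = "integer", lambdaMinRatio = "numeric",
                 stratified = "logical", seed = "integer"),
  validity = function(object) {
    if (object@p0 <= 0 || object@p0 > 1) return("'p0' must satisfy 0 < p0 <= 1")
    if (object@nOccurrence < 1L || object@nOccurrence > object@kInner)
      return("'nOccurrence' must lie in 1..kInner")
    if (object@svmCost <= 0) return("'svmCost' must be positive")
    if (object@kOuter < 2L || object@kInner < 2L || object@lambdaFolds < 2L)
      return("fold counts must be >= 2")
    if (object@repeats < 1L) return("'repeats' must be >= 1")
    if (object@lambdaMinRatio <= 0 || object@lambdaMinRatio >= 1)
      return("'lambdaMinRatio' must lie in (0, 1)")
    TRUE
  })

#' Trained linear SVM model
#'
#' Linear soft-margin SVM decision function f(x) = w . x_std + b on features
#' standardized with the training mean/sd stored in the model. The positive
#' class (score > 0) is always the patient group (label 1).
#'
#' @slot featureIndices edge indices (columns of the edge table) used.
#' @slot weights numeric weight per feature (standardized scale).
#' @slot bias intercept b.
#' @slot cost SVM cost c.
#' @slot center,scale per-feature training mean and sd used to standardize.
#'
#' @seealso [trainLSVM()], [decisionScores()]
#' @exportClass SVMModel
setClass("SVMModel",
  representation(featureIndices = "integer", weights = "numeric",
                 bias = "numeric", cost = "numeric",
                 center = "numeric", scale = "numeric"),
  validity = function(object) {
    p <- length(object@featureIndices)
    if (length(object@weights) != p || length(object@center) != p ||
        length(object@scale) != p)
      return("weights/center/scale must have one entry per feature")
    if (object@cost <= 0) return("'cost' must be positive")
    TRUE
  })

#' Repeated cross-validation results
#'
#' All per-fold results of [runRepeatedCV()]: for every (repeat, fold) pair
#' the screened and selected edges, the trained SVM (or a failure record),
#' test-fold metrics and decision scores. Aggregate with
#' [aggregateMetrics()], [countOuterOccurrence()], [stabilityReport()].
#'
#' @slot folds list of per-fold records (see [evaluateFold()]).
#' @slot params the [PipelineParams-class] used.
#' @slot nEdges number of edges in the feature table.
#' @slot nSubjects number of subjects.
#'
#' @exportClass CVResults
setClass("CVResults",
  representation(folds = "list", params = "PipelineParams",
                 nEdges = "integer", nSubjects = "integer"))

#' Permutation-test result
#'
#' Null distributions of mean accuracy and pooled AUC under group-label
#' permutation, with add-one p-values
#' p = (1 + #\{null >= observed\}) / (B + 1).
#'
#' @slot B permutation count.
#' @slot nullAccuracy,nullAUC length-B null distributions.
#' @slot observedAccuracy,observedAUC observed statistics.
#' @slot pAccuracy,pAUC permutation p-values.
#'
#' @seealso [permutationTest()]
#' @exportClass PermutationResult
setClass("PermutationResult",
  representation(B = "integer", nullAccuracy = "numeric", nullAUC = "numeric",
                 observedAccuracy = "numeric", observedAUC = "numeric",
                 pAccuracy = "numeric", pAUC = "numeric"),
  validity = function(object) {
    if (length(object@nullAccuracy) != object@B ||
        length(object@nullAUC) != object@B)
      return("null distributions must have length B")
    if (object@pAccuracy <= 0 || object@pAccuracy > 1 ||
        object@pAUC <= 0 || object@pAUC > 1)
      return("p-values must lie in (0, 1]")
    TRUE
  })

#' Cross-fold stability report
#'
#' Per-edge outer occurrence counts over all training folds, the stable edges
#' (occurrence strictly above the threshold) with ROI-pair names, a
#' model-derived weight per stable edge, FWE-corrected group-difference
#' t-tests, and the average LASSO-feature count per training fold.
#'
#' The group-difference tests are run post hoc on the full sample, after the
#' same data drove feature selection; the printed report carries this
#' circularity caveat.
#'
#' @slot table data.frame: edge, roi_i, roi_j, pair name, occurrence, weight,
#'   t, p, p_fwe, significant, direction -- one row per stable edge, sorted by
#'   occurrence descending.
#' @slot occurrence integer vector, outer occurrence per edge (all edges).
#' @slot threshold occurrence threshold used (strictly-greater rule).
#' @slot nFolds number of successful training folds counted.
#' @slot meanSelectedCount average LASSO-feature count per training fold.
#' @slot fweMethod multiplicity correction used ("bonferroni" or "holm").
#' @slot alpha significance level of the corrected tests.
#'
#' @seealso [stabilityReport()]
#' @exportClass StabilityReport
setClass("StabilityReport",
  representation(table = "data.frame", occurrence = "integer",
                 threshold = "numeric", nFolds = "integer",
                 meanSelectedCount = "numeric", fweMethod = "character",
                 alpha = "numeric"))
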