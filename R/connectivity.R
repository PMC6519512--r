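#' Temporal cleaning of ROI time series
#'
#' Applies the standard resting-state cleaning recipe, in fixed order:
#' (1) linear detrending of each ROI column; (2) least-squares residualization
#' against all confound columns plus an intercept; (3) zero-phase band-pass
#' filtering (second-order Butterworth run forward and backward, so the
#' effective magnitude response is the squared Butterworth response and the
#' phase is zero).
#'
#' A rank-deficient confound matrix is handled by dropping collinear columns
#' (with a warning); a band edge at or beyond the Nyquist frequency
#' 1/(2 TR) is an error.
#'
#' @param ts an [ROITimeSeries-class].
#' @param confounds an optional [ConfoundSet-class] with the same number of
#'   timepoints; `NULL` skips confound regression.
#' @param band numeric length-2 band in Hz, default `c(0.01, 0.1)`; `NULL`
#'   skips filtering.
#' @return A cleaned [ROITimeSeries-class].
#' @examples
#' ts <- simulateROITimeSeries(diag(4), 120, tr = 2, seed = 1)
#' cleanTimeseries(ts, band = c(0.01, 0.1))
#' @export
cleanTimeseries <- function(ts, confounds = NULL, band = c(0.01, 0.1)) {
  stopifnot(is(ts, "ROITimeSeries"))
  x <- ts@values
  nT <- nrow(x)
  # (1) linear detrend
  tt <- seq_len(nT)
  x <- stats::lm.fit(cbind(1, tt), x)$residuals
  # (2) confound regression with intercept; drop collinear columns
  if (!is.null(confounds)) {
    stopifnot(is(confounds, "ConfoundSet"))
    cf <- confounds@values
    if (nrow(cf) != nT)
      stop("confounds have ", nrow(cf), " rows but the series has ", nT)
    # keep the linear-trend term in the design so confounds are effectively
    # detrended too (regressing a detrended series on raw confounds would
    # leave trend-shaped residuals)
    design <- cbind(`(Intercept)` = 1, trend = tt, cf)
    qrD <- qr(design)
    if (qrD$rank < ncol(design)) {
      keep <- qrD$pivot[seq_len(qrD$rank)]
      dropped <- colnames(design)[setdiff(seq_len(ncol(design)), keep)]
      warning("dropping collinear confound column(s): ",
              paste(dropped, collapse = ", "))
      design <- design[, sort(keep), drop = FALSE]
    }
    x <- stats::lm.fit(design, x)$residuals
  }
  # (3) zero-phase Butterworth band-pass
  if (!is.null(band)) {
    fs <- 1 / ts@tr
    nyq <- fs / 2
    if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
        band[2] >= nyq)
      stop("band must satisfy 0 < low < high < Nyquist = ", signif(nyq, 4),
           " Hz at TR = ", ts@tr, " s")
    bf <- signal::butter(2, band / nyq, type = "pass")
    x <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  }
  colnames(x) <- roiNames(ts)
  ROITimeSeries(x, tr = ts@tr)
}

#' Average unit (voxel) series into ROI series
#'
#' @param unitSeries numeric matrix, timepoints x units (e.g. voxels).
#' @param unitToRoi ROI label per unit column.
#' @param roiOrder optional atlas order for the output ROIs; defaults to the
#'   order of first appearance in `unitToRoi`.
#' @param tr repetition time, seconds.
#' @return An [ROITimeSeries-class]: column r is the unweighted mean of all
#'   units labelled r.
#' @export
extractROISeries <- function(unitSeries, unitToRoi, roiOrder = NULL, tr = 2) {
  unitSeries <- as.matrix(unitSeries)
  if (ncol(unitSeries) != length(unitToRoi))
    stop("need one ROI label per unit column")
  if (is.null(roiOrder)) roiOrder <- unique(unitToRoi)
  bad <- setdiff(unitToRoi, roiOrder)
  if (length(bad))
    stop("unit label(s) not in the atlas: ", paste(bad, collapse = ", "))
  out <- sapply(roiOrder, function(r) {
    cols <- which(unitToRoi == r)
    if (!length(cols)) stop("ROI '", r, "' has no units")
    rowMeans(unitSeries[, cols, drop = FALSE])
  })
  ROITimeSeries(out, tr = tr, roiNames = roiOrder)
}

#' Pearson connectivity matrix of an ROI time series
#'
#' @param ts an [ROITimeSeries-class]; every column must have nonzero
#'   variance.
#' @return A [ConnectivityMatrix-class] (symmetric, unit diagonal).
#' @export
correlationMatrix <- function(ts) {
  stopifnot(is(ts, "ROITimeSeries"))
  v <- apply(ts@values, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance ROI(s): ",
         paste(roiNames(ts)[v == 0], collapse = ", "))
  m <- stats::cor(ts@values)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  new("ConnectivityMatrix", values = m)
}

#' Flatten a connectivity matrix into the canonical edge vector
#'
#' The strict upper triangle in row-major order (see [edgePairs()]): for 90
#' ROIs this yields the 4005-edge feature vector.
#'
#' @param m a [ConnectivityMatrix-class] or a symmetric numeric matrix
#'   (asymmetry beyond 1e-8 is an error).
#' @return Named numeric vector of length n(n-1)/2 with an `edgeMap`
#'   attribute (the [edgePairs()] matrix).
#' @examples
#' ts <- simulateROITimeSeries(diag(4), 50, seed = 1)
#' length(vectorizeEdges(correlationMatrix(ts)))   # 6
#' @export
vectorizeEdges <- function(m) {
  v <- if (is(m, "ConnectivityMatrix")) m@values else as.matrix(m)
  if (nrow(v) != ncol(v) || max(abs(v - t(v))) > 1e-8)
    stop("input must be a symmetric square matrix (tolerance 1e-8)")
  n <- nrow(v)
  out <- t(v)[lower.tri(v)]   # row-major strict upper triangle
  pairs <- edgePairs(n)
  names(out) <- sprintf("edge_%0*d", max(4L, nchar(length(out))),
                        seq_along(out))
  attr(out, "edgeMap") <- pairs
  out
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorizeEdges()] with unit diagonal.
#'
#' @param edges numeric vector of length n(n-1)/2.
#' @param roiNames optional ROI labels.
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
unvectorizeEdges <- function(edges, roiNames = NULL) {
  n <- roiCountFromEdges(length(edges))
  m <- diag(n)
  pairs <- edgePairs(n)
  m[pairs] <- edges
  m[pairs[, c(2L, 1L), drop = FALSE]] <- edges
  if (!is.null(roiNames)) dimnames(m) <- list(roiNames, roiNames)
  m
}

#' Full connectivity pipeline over a list of subjects
#'
#' Cleans each subject's ROI series, computes the Pearson connectivity
#' matrix, and stacks the canonical edge vectors into an [EdgeTable-class].
#'
#' @param seriesList list of [ROITimeSeries-class], one per subject (all with
#'   the same ROIs).
#' @param labels per-subject group label (0 control / 1 patient).
#' @param confoundsList optional list of [ConfoundSet-class] matching
#'   `seriesList`.
#' @param band band-pass edges in Hz (`NULL` to skip), default
#'   `c(0.01, 0.1)`.
#' @param fisherZ apply the Fisher z-transform atanh(r) to the edge values
#'   (default `FALSE`: raw Pearson r is the feature).
#' @param subjectIds optional subject identifiers.
#' @return An [EdgeTable-class].
#' @export
connectivityPipeline <- function(seriesList, labels, confoundsList = NULL,
                                 band = c(0.01, 0.1), fisherZ = FALSE,
                                 subjectIds = NULL) {
  stopifnot(length(seriesList) >= 2,
            length(labels) == length(seriesList),
            is.null(confoundsList) ||
              length(confoundsList) == length(seriesList))
  rois <- roiNames(seriesList[[1]])
  rows <- lapply(seq_along(seriesList), function(s) {
    ts <- seriesList[[s]]
    if (!identical(roiNames(ts), rois))
      stop("subject ", s, " has different ROI names")
    cf <- if (is.null(confoundsList)) NULL else confoundsList[[s]]
    cleaned <- cleanTimeseries(ts, confounds = cf, band = band)
    vectorizeEdges(correlationMatrix(cleaned))
  })
  x <- do.call(rbind, rows)
  if (fisherZ) x <- atanh(pmin(pmax(x, -1 + 1e-12), 1 - 1e-12))
  EdgeTable(x, labels = labels, roiNames = rois, subjectIds = subjectIds)
}
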