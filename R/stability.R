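## Cross-fold occurrence accounting, stable edges, post-hoc group tests.

#' Outer occurrence count per edge
#'
#' How many successful training folds selected each edge as a LASSO feature
#' (over all repeats x folds of a [runRepeatedCV()] run).
#'
#' @param results a [CVResults-class].
#' @return Integer vector, one count per edge.
#' @export
countOuterOccurrence <- function(results) {
  stopifnot(is(results, "CVResults"))
  occ <- integer(results@nEdges)
  for (f in results@folds) {
    if (is.null(f$failure))
      occ[f$selected] <- occ[f$selected] + 1L
  }
  occ
}

#' Stable edges above an occurrence threshold
#'
#' Edges selected in strictly more than `threshold` training folds (the
#' strictly-greater rule: with 1000 folds and threshold 500, an edge must
#' occur at least 501 times), named via the table's edge map.
#'
#' @param occurrence integer vector from [countOuterOccurrence()].
#' @param threshold occurrence cut-off (strictly greater).
#' @param table the [EdgeTable-class] the results were computed on (for
#'   ROI-pair names); optional.
#' @return data.frame with `edge`, `occurrence` and, when `table` is given,
#'   `roi_i`, `roi_j`, `roi_name_i`, `roi_name_j`; sorted by occurrence
#'   descending.
#' @export
stableFeatures <- function(occurrence, threshold, table = NULL) {
  stopifnot(threshold >= 0)
  idx <- which(occurrence > threshold)
  out <- data.frame(edge = idx, occurrence = occurrence[idx])
  if (!is.null(table)) {
    em <- edgeMap(table)
    out <- cbind(out, em[idx, c("roi_i", "roi_j", "roi_name_i",
                                "roi_name_j")])
  }
  out <- out[order(-out$occurrence, out$edge), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group-difference tests on selected edges
#'
#' Pooled-variance two-sided t-test per edge on the full sample with
#' family-wise-error correction across the tested edges (Bonferroni by
#' default, Holm by flag). Direction is `"HC>PE"` when the control mean
#' exceeds the patient mean. These tests are post hoc: when run on edges
#' that the same sample selected, the p-values are optimistically biased.
#'
#' @param table an [EdgeTable-class].
#' @param edges edge indices to test (non-empty).
#' @param alpha significance level for the corrected tests (default 0.05).
#' @param method `"bonferroni"` (default) or `"holm"`.
#' @return data.frame with `edge`, `t`, `p`, `p_fwe`, `significant`,
#'   `direction`.
#' @export
groupDifferenceTests <- function(table, edges, alpha = 0.05,
                                 method = c("bonferroni", "holm")) {
  method <- match.arg(method)
  stopifnot(is(table, "EdgeTable"), length(edges) >= 1)
  x <- edgeMatrix(table)[, edges, drop = FALSE]
  y <- groupLabels(table)
  tt <- ttestScreen(x, y, p0 = 1)
  pf <- stats::p.adjust(tt$p, method = method)
  data.frame(edge = edges, t = tt$tstat, p = tt$p, p_fwe = pf,
             significant = pf < alpha,
             direction = ifelse(tt$tstat > 0, "HC>PE", "HC<PE"))
}

#' Model-derived weight summary per edge
#'
#' For each requested edge, the mean absolute standardized SVM weight over
#' the successful folds whose model contained it; `NA` when the edge never
#' entered any model.
#'
#' @param results a [CVResults-class].
#' @param edges edge indices.
#' @return Numeric vector, one weight (or `NA`) per requested edge.
#' @export
featureWeightSummary <- function(results, edges) {
  stopifnot(is(results, "CVResults"))
  sums <- numeric(results@nEdges)
  cnts <- integer(results@nEdges)
  for (f in results@folds) {
    if (is.null(f$failure)) {
      idx <- f$model@featureIndices
      sums[idx] <- sums[idx] + abs(f$model@weights)
      cnts[idx] <- cnts[idx] + 1L
    }
  }
  out <- ifelse(cnts[edges] > 0L, sums[edges] / cnts[edges], NA_real_)
  as.numeric(out)
}

#' Average LASSO-feature count per training fold
#'
#' Arithmetic mean of the selected-feature-set size over all successful
#' folds (failed folds excluded).
#'
#' @param results a [CVResults-class].
#' @return A single number.
#' @export
meanSelectedCount <- function(results) {
  stopifnot(is(results, "CVResults"))
  ok <- Filter(function(f) is.null(f$failure), results@folds)
  if (!length(ok)) stop("zero successful folds")
  mean(vapply(ok, function(f) length(f$selected), numeric(1)))
}

#' Build the cross-fold stability report
#'
#' Combines [countOuterOccurrence()], [stableFeatures()],
#' [featureWeightSummary()], [groupDifferenceTests()] and
#' [meanSelectedCount()] into one report: the stable edges (occurrence
#' strictly above `threshold`) with ROI-pair names, weights, and
#' FWE-corrected group-difference statistics.
#'
#' @param results a [CVResults-class].
#' @param table the [EdgeTable-class] the results were computed on.
#' @param threshold occurrence cut-off; default half of the fold count
#'   (e.g. 500 of 1000).
#' @param alpha significance level (default 0.05).
#' @param method FWE correction, `"bonferroni"` (default) or `"holm"`.
#' @return A [StabilityReport-class].
#' @export
stabilityReport <- function(results, table, threshold = NULL, alpha = 0.05,
                            method = c("bonferroni", "holm")) {
  method <- match.arg(method)
  stopifnot(is(results, "CVResults"), is(table, "EdgeTable"))
  nFolds <- length(results@folds)
  if (is.null(threshold)) threshold <- nFolds / 2
  occ <- countOuterOccurrence(results)
  stab <- stableFeatures(occ, threshold, table)
  if (nrow(stab)) {
    stab$weight <- featureWeightSummary(results, stab$edge)
    gd <- groupDifferenceTests(table, stab$edge, alpha = alpha,
                               method = method)
    stab <- cbind(stab, gd[, c("t", "p", "p_fwe", "significant",
                               "direction")])
  } else {
    stab$weight <- numeric(0); stab$t <- numeric(0); stab$p <- numeric(0)
    stab$p_fwe <- numeric(0); stab$significant <- logical(0)
    stab$direction <- character(0)
  }
  new("StabilityReport", table = stab, occurrence = occ,
      threshold = as.numeric(threshold), nFolds = as.integer(nFolds),
      meanSelectedCount = meanSelectedCount(results),
      fweMethod = method, alpha = alpha)
}

#' Write a stability report to CSV and Markdown
#'
#' @param report a [StabilityReport-class].
#' @param csvPath,mdPath output paths (`NULL` skips either).
#' @return Invisibly, the report table.
#' @export
writeStabilityReport <- function(report, csvPath = NULL, mdPath = NULL) {
  stopifnot(is(report, "StabilityReport"))
  df <- report@table
  if (!is.null(csvPath)) utils::write.csv(df, csvPath, row.names = FALSE)
  if (!is.null(mdPath)) {
    lines <- c("# Stable discriminative edges",
               "",
               sprintf("Occurrence > %g of %d training folds; FWE: %s at alpha = %g.",
                       report@threshold, report@nFolds, report@fweMethod,
                       report@alpha),
               sprintf("Mean LASSO features per training fold: %.3f.",
                       report@meanSelectedCount),
               "",
               "| Edge | Occurrence | Weight | t | p (FWE) | Direction |",
               "| --- | --- | --- | --- | --- | --- |")
    if (nrow(df)) {
      nm <- if ("roi_name_i" %in% names(df))
        paste(df$roi_name_i, "-", df$roi_name_j) else as.character(df$edge)
      lines <- c(lines, sprintf("| %s | %d | %.4f | %.3f | %.4g%s | %s |",
                                nm, df$occurrence, df$weight, df$t,
                                df$p_fwe,
                                ifelse(df$significant, " *", ""),
                                df$direction))
    }
    lines <- c(lines, "",
               paste("Note: group-difference tests are post hoc on the full",
                     "sample after selection on the same data (circular);",
                     "interpret p-values accordingly."))
    writeLines(lines, mdPath)
  }
  invisible(df)
}
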