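#' Create a synthetic cohort specification
#'
#' Defaults emulate a two-group resting-state cohort of 30 controls and 39
#' patients with 90 ROIs (4005 edges), 205 retained volumes at TR = 2 s, and
#' five discriminative edges. The planted difference is `delta` on the
#' correlation scale for the time-series route and `effectSizeD` standard
#' deviations (of `edgeSd`) on the direct edge-table route; the defaults
#' (delta = 0.3, d = 1.5, sd = 0.2) describe the same effect on both routes.
#'
#' @param nRoi,nGroup0,nGroup1,nTimepoints,tr cohort dimensions; see
#'   [SyntheticSpec-class].
#' @param signalEdges two-column integer matrix of ROI pairs (i < j) carrying
#'   the group difference; default: five fixed pairs spread over the atlas.
#' @param delta correlation difference (group1 - group0) at each signal edge.
#' @param effectSizeD standardized mean difference on the direct edge route.
#' @param edgeSd edge-value standard deviation on the direct route.
#' @param baseRank factor count of the background covariance model.
#' @param seed integer RNG seed.
#' @return A [SyntheticSpec-class] object.
#' @examples
#' spec <- SyntheticSpec(nRoi = 10, signalEdges = cbind(2, 7), delta = 0.4)
#' spec
#' @export
SyntheticSpec <- function(nRoi = 90L, nGroup0 = 30L, nGroup1 = 39L,
                          nTimepoints = 205L, tr = 2,
                          signalEdges = NULL, delta = 0.3,
                          effectSizeD = 1.5, edgeSd = 0.2,
                          baseRank = 5L, seed = 1L) {
  if (is.null(signalEdges)) {
    if (nRoi >= 90) {
      signalEdges <- rbind(c(5L, 6L), c(12L, 58L), c(29L, 76L),
                           c(42L, 63L), c(85L, 88L))
    } else {
      signalEdges <- cbind(1L, 2L)
    }
  }
  signalEdges <- matrix(as.integer(signalEdges), ncol = 2,
                        dimnames = list(NULL, c("i", "j")))
  new("SyntheticSpec", nRoi = as.integer(nRoi),
      nGroup0 = as.integer(nGroup0), nGroup1 = as.integer(nGroup1),
      nTimepoints = as.integer(nTimepoints), tr = as.numeric(tr),
      signalEdges = signalEdges, delta = delta,
      effectSizeD = effectSizeD, edgeSd = edgeSd,
      baseRank = as.integer(baseRank), seed = as.integer(seed))
}

#' Build the two group correlation matrices of a synthetic cohort
#'
#' A background correlation structure is drawn from a low-rank factor model
#' (rank `baseRank`) plus a diagonal, shared by both groups. The planted
#' `delta` is then added to group 1 at every signal edge, and each matrix is
#' repaired to a valid correlation matrix by clipping eigenvalues at 1e-6 and
#' re-normalizing to unit diagonal. The repair moves entries by at most a
#' small amount; construction fails if it distorts a planted difference by
#' more than 0.02, or if any target correlation would leave (-1, 1).
#'
#' @param spec a [SyntheticSpec-class].
#' @return List with correlation matrices `group0` and `group1`
#'   (unit diagonal, symmetric positive definite).
#' @examples
#' cv <- makeGroupCovariances(SyntheticSpec(nRoi = 10, seed = 3,
#'                                          signalEdges = cbind(2, 7)))
#' cv$group1[2, 7] - cv$group0[2, 7]   # close to delta
#' @export
makeGroupCovariances <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  n <- spec@nRoi
  set.seed(spec@seed)
  f <- matrix(rnorm(n * spec@baseRank, sd = 0.4), n, spec@baseRank)
  s <- tcrossprod(f) + diag(n)
  base <- stats::cov2cor(s)

  se <- spec@signalEdges
  if (nrow(se)) {
    r0 <- base[se]
    if (any(abs(r0 + spec@delta) >= 1))
      stop("infeasible construction: |r + delta| >= 1 at a signal edge ",
           "(base r = ", paste(round(r0, 3), collapse = ", "),
           ", delta = ", spec@delta, ")")
  }
  g1 <- base
  for (e in seq_len(nrow(se))) {
    i <- se[e, 1L]; j <- se[e, 2L]
    g1[i, j] <- g1[j, i] <- base[i, j] + spec@delta
  }
  g0 <- .repairCorrelation(base)
  g1 <- .repairCorrelation(g1)
  if (nrow(se)) {
    achieved <- g1[se] - g0[se]
    if (any(abs(achieved - spec@delta) > 0.02))
      stop("positive-definite repair distorted a planted delta by more than ",
           "0.02 (achieved: ", paste(round(achieved, 3), collapse = ", "), ")")
  }
  dimnames(g0) <- dimnames(g1) <-
    list(sprintf("ROI_%03d", 1:n), sprintf("ROI_%03d", 1:n))
  list(group0 = g0, group1 = g1)
}

# Eigenvalue clipping at 1e-6 followed by re-normalization to unit diagonal.
.repairCorrelation <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= 1e-6 && max(abs(diag(m) - 1)) < 1e-12) return(m)
  v <- pmax(e$values, 1e-6)
  m2 <- e$vectors %*% (v * t(e$vectors))
  stats::cov2cor((m2 + t(m2)) / 2)
}

#' Simulate ROI time series with a target correlation structure
#'
#' Draws zero-mean Gaussian series whose population correlation is `cov`
#' (by multiplying i.i.d. normal deviates with its Cholesky factor), so the
#' sample correlation converges to `cov` as the series lengthens.
#'
#' @param cov symmetric positive-definite correlation (or covariance) matrix.
#' @param nTimepoints number of volumes to simulate.
#' @param tr repetition time, seconds.
#' @param seed integer RNG seed; same seed, same output.
#' @return An [ROITimeSeries-class].
#' @export
simulateROITimeSeries <- function(cov, nTimepoints, tr = 2, seed = 1L) {
  cov <- as.matrix(cov)
  if (max(abs(cov - t(cov))) > 1e-8) stop("'cov' must be symmetric")
  ch <- tryCatch(chol(cov),
                 error = function(e) stop("'cov' must be positive definite"))
  set.seed(as.integer(seed))
  z <- matrix(rnorm(nTimepoints * ncol(cov)), nTimepoints, ncol(cov))
  x <- z %*% ch
  colnames(x) <- if (!is.null(colnames(cov))) colnames(cov) else
    sprintf("ROI_%03d", seq_len(ncol(cov)))
  ROITimeSeries(x, tr = tr)
}

#' Simulate a subject-by-edge feature table directly
#'
#' The fast route for statistical validation: edge values are drawn as
#' independent Gaussians on the Fisher-z scale (sd `edgeSd`) around a zero
#' baseline, and the signal edges of group 1 (patients) are shifted by
#' `effectSizeD * edgeSd` so that the planted standardized mean difference is
#' exactly `effectSizeD`. Ground-truth signal edge indices are recorded in
#' the table's metadata.
#'
#' @param spec a [SyntheticSpec-class].
#' @return An [EdgeTable-class] with `nGroup0 + nGroup1` subjects and
#'   `nRoi (nRoi - 1) / 2` edges; controls first, then patients.
#' @examples
#' tab <- simulateEdgeTable(SyntheticSpec(nRoi = 10, nGroup0 = 6, nGroup1 = 8,
#'                                        signalEdges = cbind(2, 7)))
#' tab
#' @export
simulateEdgeTable <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  n <- spec@nRoi
  nE <- n * (n - 1L) / 2L
  nS <- spec@nGroup0 + spec@nGroup1
  set.seed(spec@seed)
  x <- matrix(rnorm(nS * nE, sd = spec@edgeSd), nS, nE)
  labels <- rep(c(0L, 1L), c(spec@nGroup0, spec@nGroup1))
  sig <- pairToEdgeIndex(spec@signalEdges[, 1L], spec@signalEdges[, 2L], n)
  if (length(sig))
    x[labels == 1L, sig] <- x[labels == 1L, sig] +
      spec@effectSizeD * spec@edgeSd
  EdgeTable(x, labels = labels, signalEdges = sig)
}

#' Map an ROI pair to its canonical edge index
#'
#' @param i,j ROI indices with i < j (vectors allowed).
#' @param n number of ROIs.
#' @return Integer edge index/indices; inverse of [edgeIndexToPair()].
#' @export
pairToEdgeIndex <- function(i, j, n) {
  i <- as.integer(i); j <- as.integer(j); n <- as.integer(n)
  if (any(i >= j) || any(i < 1L) || any(j > n))
    stop("ROI pairs must satisfy 1 <= i < j <= n")
  as.integer((i - 1L) * n - (i * (i - 1L)) %/% 2L + (j - i))
}

#' Simulate confound regressors
#'
#' Motion parameters are random walks (plus their first-order differences with a
#' leading zero), CSF and white-matter averages are smooth noise, and spikes
#' are one 0/1 indicator column per flagged volume, each summing to 1.
#'
#' @param nTimepoints number of volumes.
#' @param nMotion number of motion parameters (default 6; derivatives added).
#' @param spikeRate probability that a volume is flagged (default 0).
#' @param seed integer RNG seed.
#' @return A [ConfoundSet-class].
#' @export
simulateConfounds <- function(nTimepoints, nMotion = 6L, spikeRate = 0,
                              seed = 1L) {
  stopifnot(nMotion >= 0, spikeRate >= 0, spikeRate < 1)
  set.seed(as.integer(seed))
  cols <- list(); roles <- character(0)
  if (nMotion > 0) {
    motion <- sapply(seq_len(nMotion),
                     function(i) cumsum(rnorm(nTimepoints, sd = 0.02)))
    deriv <- rbind(0, diff(motion))
    cols <- c(cols, list(motion, deriv))
    roles <- c(roles, rep("motion", nMotion),
               rep("motion_derivative", nMotion))
  }
  smooth <- function() as.numeric(stats::filter(rnorm(nTimepoints), 0.8,
                                                method = "recursive"))
  cols <- c(cols, list(cbind(smooth()), cbind(smooth())))
  roles <- c(roles, "csf", "wm")
  flagged <- which(runif(nTimepoints) < spikeRate)
  if (length(flagged)) {
    spikes <- matrix(0, nTimepoints, length(flagged))
    spikes[cbind(flagged, seq_along(flagged))] <- 1
    cols <- c(cols, list(spikes))
    roles <- c(roles, rep("spike", length(flagged)))
  }
  ConfoundSet(do.call(cbind, cols), roles)
}
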