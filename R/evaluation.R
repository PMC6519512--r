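## Outer repeated k-fold CV, grid search over (p0, N, c), permutation test.

# Deterministic child-seed derivation: the master seed spawns per-repeat,
# per-fold and per-permutation streams without overlap; results stay below
# 2^31 so they are valid set.seed() inputs.
childSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 1117) %%
               2147483563) + 1L
}

# Fold assignment: stratified deals each class round-robin after shuffling,
# so every fold contains both classes whenever feasible.
assignFolds <- function(y, k, seed, stratified = TRUE) {
  set.seed(as.integer(seed))
  k <- as.integer(k)
  n <- length(y)
  if (!stratified) return(sample(rep_len(seq_len(k), n)))
  grp <- integer(n)
  offset <- 0L
  for (cls in sort(unique(y))) {
    idx <- sample(which(y == cls))
    grp[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  grp
}

#' Evaluate one outer cross-validation fold
#'
#' Runs the full per-fold pipeline strictly inside the training subjects:
#' t-test screen at `p0`, inner CV-LASSO stability selection, occurrence
#' thresholding at N, then a linear SVM; metrics and decision scores are
#' computed on the held-out subjects. A fold whose selected feature set is
#' empty is returned as a failure record instead of a model.
#'
#' @param x subjects x edges matrix (all subjects).
#' @param y labels 0/1 (all subjects).
#' @param testIdx indices of the held-out subjects.
#' @param params a [PipelineParams-class].
#' @param seed RNG seed for the inner split and nested lambda CV.
#' @return List with `testIdx`, `screened`, `innerOccurrence` (aligned with
#'   `screened`), `selected`, `model` ([SVMModel-class]), `metrics`,
#'   `scores`, `yTest`, and `failure` (`NULL`, or a message when the fold
#'   could not be trained).
#' @export
evaluateFold <- function(x, y, testIdx, params, seed = 1L) {
  train <- setdiff(seq_len(nrow(x)), testIdx)
  xtr <- x[train, , drop = FALSE]; ytr <- y[train]
  base <- list(testIdx = testIdx, screened = integer(0),
               innerOccurrence = integer(0), selected = integer(0),
               model = NULL, metrics = NULL, scores = NULL,
               yTest = y[testIdx])
  scr <- ttestScreen(xtr, ytr, params@p0)
  if (!length(scr$screened)) {
    base$failure <- "no edges passed the t-test screen"
    return(base)
  }
  base$screened <- scr$screened
  sel <- cvLassoSelect(xtr[, scr$screened, drop = FALSE], ytr,
                       kInner = params@kInner, seed = childSeed(seed, 1L),
                       lambdaFolds = params@lambdaFolds,
                       nLambda = params@nLambda,
                       lambdaMinRatio = params@lambdaMinRatio)
  base$innerOccurrence <- sel$innerOccurrence
  keep <- selectByOccurrence(sel$innerOccurrence, params@nOccurrence)
  base$selected <- scr$screened[keep]
  if (!length(base$selected)) {
    base$failure <- "empty selected feature set"
    return(base)
  }
  model <- trainLSVM(xtr[, base$selected, drop = FALSE], ytr,
                     cost = params@svmCost,
                     featureIndices = base$selected)
  scores <- decisionScores(model, x[testIdx, base$selected, drop = FALSE])
  base$model <- model
  base$scores <- scores
  base$metrics <- confusionMetrics(y[testIdx], as.integer(scores > 0))
  base$failure <- NULL
  base
}

# Shared engine for runRepeatedCV and the permutation nulls.
runCVMatrix <- function(x, y, params, seed) {
  folds <- vector("list", params@repeats * params@kOuter)
  pos <- 0L
  for (r in seq_len(params@repeats)) {
    rSeed <- childSeed(seed, r)
    fid <- assignFolds(y, params@kOuter, rSeed, params@stratified)
    for (f in seq_len(params@kOuter)) {
      pos <- pos + 1L
      res <- evaluateFold(x, y, which(fid == f), params,
                          seed = childSeed(rSeed, f))
      res$repeat_id <- r
      res$fold_id <- f
      folds[[pos]] <- res
    }
  }
  new("CVResults", folds = folds, params = params,
      nEdges = ncol(x), nSubjects = nrow(x))
}

#' Repeated stratified k-fold cross-validation of the full pipeline
#'
#' For each of `repeats` repetitions a fresh `kOuter`-fold split is drawn and
#' every fold is evaluated with [evaluateFold()] -- all feature selection and
#' model fitting strictly inside the training subjects. With the defaults
#' (100 x 10) this yields 1000 test-fold evaluations.
#'
#' @param table an [EdgeTable-class].
#' @param params a [PipelineParams-class].
#' @return A [CVResults-class].
#' @seealso [aggregateMetrics()], [stabilityReport()], [permutationTest()]
#' @export
runRepeatedCV <- function(table, params = PipelineParams()) {
  stopifnot(is(table, "EdgeTable"), is(params, "PipelineParams"))
  validObject(params)
  runCVMatrix(edgeMatrix(table), groupLabels(table), params, params@seed)
}

#' Aggregate repeated-CV results
#'
#' Mean and standard deviation (denominator n-1) of every metric across the
#' successful test folds, plus the ROC/AUC pooled over all test-fold decision
#' scores. Metrics that are undefined in a fold (e.g. sensitivity in a fold
#' without patients) are dropped from that metric's aggregate.
#'
#' @param results a [CVResults-class].
#' @return List with `metrics` (data.frame metric/mean/sd/n), `pooledAUC`,
#'   `pooledROC`, `nFolds`, `nFailed`.
#' @export
aggregateMetrics <- function(results) {
  stopifnot(is(results, "CVResults"))
  ok <- Filter(function(f) is.null(f$failure), results@folds)
  if (!length(ok)) stop("zero successful folds: nothing to aggregate")
  nms <- c("accuracy", "sensitivity", "specificity", "recall", "precision")
  metr <- lapply(nms, function(m)
    vapply(ok, function(f) f$metrics[[m]], numeric(1)))
  tab <- data.frame(
    metric = nms,
    mean = vapply(metr, function(v) mean(v, na.rm = TRUE), numeric(1)),
    sd = vapply(metr, function(v) stats::sd(v, na.rm = TRUE), numeric(1)),
    n = vapply(metr, function(v) sum(is.finite(v)), integer(1)))
  scores <- unlist(lapply(ok, `[[`, "scores"))
  yAll <- unlist(lapply(ok, `[[`, "yTest"))
  roc <- rocAUC(scores, yAll)
  list(metrics = tab, pooledAUC = roc$auc, pooledROC = roc$curve,
       nFolds = length(results@folds),
       nFailed = length(results@folds) - length(ok))
}

#' Default grid-search grids
#'
#' The screening threshold p0 runs over 0.001, 0.005, 0.01 and 0.025..0.2 in
#' steps of 0.025 (11 values); the occurrence threshold N over 1..10; the
#' SVM cost c over 0.1..2 in steps of 0.1 (20 values) -- 2200 triples.
#'
#' @return List with components `p0`, `n`, `c`.
#' @export
defaultGrids <- function() {
  list(p0 = c(0.001, 0.005, 0.01, seq(0.025, 0.2, by = 0.025)),
       n = 1:10,
       c = seq(0.1, 2, by = 0.1))
}

#' Grid search over (p0, N, c)
#'
#' Evaluates one `kOuter`-fold CV per parameter triple, with the fold split
#' shared across all triples, and returns the triple maximizing mean
#' test-fold accuracy. This follows the protocol of selecting parameters on
#' test-fold accuracy directly; for an unbiased performance estimate wrap
#' the search in an outer CV of its own (see the vignette). Ties are broken
#' deterministically: larger N (sparser models), then smaller c, then
#' smaller p0. Duplicated grid values are deduplicated before evaluation.
#'
#' @param table an [EdgeTable-class].
#' @param p0Grid,nGrid,cGrid parameter grids (defaults: [defaultGrids()]).
#' @param params a [PipelineParams-class] supplying the CV layout (fold
#'   counts, lambda path, stratification, seed).
#' @return List with `best` (a [PipelineParams-class] carrying the winning
#'   triple), `table` (data.frame p0/n/c/accuracy/nFailed over all triples),
#'   and `foldAssignment`.
#' @export
gridSearch <- function(table, p0Grid = defaultGrids()$p0,
                       nGrid = defaultGrids()$n, cGrid = defaultGrids()$c,
                       params = PipelineParams()) {
  stopifnot(is(table, "EdgeTable"), length(p0Grid) > 0, length(nGrid) > 0,
            length(cGrid) > 0)
  x <- edgeMatrix(table); y <- groupLabels(table)
  p0Grid <- sort(unique(p0Grid))
  nGrid <- sort(unique(as.integer(nGrid)))
  cGrid <- sort(unique(cGrid))
  stopifnot(max(nGrid) <= params@kInner)
  k <- params@kOuter
  fid <- assignFolds(y, k, childSeed(params@seed, 0L), params@stratified)

  dims <- c(length(p0Grid), length(nGrid), length(cGrid), k)
  acc <- array(NA_real_, dims)
  for (f in seq_len(k)) {
    testIdx <- which(fid == f)
    train <- setdiff(seq_len(nrow(x)), testIdx)
    xtr <- x[train, , drop = FALSE]; ytr <- y[train]
    pvals <- ttestScreen(xtr, ytr, p0 = 1)$p
    fSeed <- childSeed(params@seed, f)
    for (a in seq_along(p0Grid)) {
      screened <- which(pvals < p0Grid[a])
      if (!length(screened)) next
      sel <- cvLassoSelect(xtr[, screened, drop = FALSE], ytr,
                           kInner = params@kInner,
                           seed = childSeed(fSeed, a),
                           lambdaFolds = params@lambdaFolds,
                           nLambda = params@nLambda,
                           lambdaMinRatio = params@lambdaMinRatio)
      sets <- lapply(nGrid, function(N)
        screened[selectByOccurrence(sel$innerOccurrence, N)])
      sig <- vapply(sets, paste, character(1), collapse = ",")
      for (u in unique(sig)) {
        bIdx <- which(sig == u)[1L]
        selected <- sets[[bIdx]]
        if (!length(selected)) next
        for (cc in seq_along(cGrid)) {
          model <- trainLSVM(xtr[, selected, drop = FALSE], ytr,
                             cost = cGrid[cc], featureIndices = selected)
          sc <- decisionScores(model, x[testIdx, selected, drop = FALSE])
          a1 <- confusionMetrics(y[testIdx], as.integer(sc > 0))$accuracy
          acc[a, which(sig == u), cc, f] <- a1
        }
      }
    }
  }
  grid <- expand.grid(p0 = p0Grid, n = nGrid, c = cGrid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$accuracy <- NA_real_
  grid$nFailed <- NA_integer_
  for (r in seq_len(nrow(grid))) {
    a <- match(grid$p0[r], p0Grid); b <- match(grid$n[r], nGrid)
    cc <- match(grid$c[r], cGrid)
    v <- acc[a, b, cc, ]
    grid$nFailed[r] <- sum(is.na(v))
    grid$accuracy[r] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  ord <- order(-grid$accuracy, -grid$n, grid$c, grid$p0, na.last = TRUE)
  bestRow <- grid[ord[1L], ]
  if (is.na(bestRow$accuracy))
    stop("every parameter triple failed on every fold")
  best <- params
  best@p0 <- bestRow$p0
  best@nOccurrence <- as.integer(bestRow$n)
  best@svmCost <- bestRow$c
  list(best = best, table = grid, foldAssignment = fid)
}

#' Permutation test of classifier accuracy and AUC
#'
#' Re-runs the repeated-CV pipeline `B` times with the group labels
#' permuted (parameters fixed at the supplied triple) and compares the
#' observed mean accuracy and pooled AUC with the null distributions using
#' the add-one estimator p = (1 + #\{null >= observed\}) / (B + 1).
#'
#' @param table an [EdgeTable-class].
#' @param params a [PipelineParams-class]; its `seed` drives the label
#'   permutations and all CV splits.
#' @param B permutation count (default `params@nPermutations`).
#' @param repeats outer repetitions used for the observed run and each
#'   permutation (default `params@repeats`; reduce for large B).
#' @return A [PermutationResult-class].
#' @export
permutationTest <- function(table, params = PipelineParams(),
                            B = params@nPermutations,
                            repeats = params@repeats) {
  stopifnot(is(table, "EdgeTable"), B >= 1)
  x <- edgeMatrix(table); y <- groupLabels(table)
  p2 <- params
  p2@repeats <- as.integer(repeats)
  # the test statistic is (mean accuracy, pooled AUC) with a deterministic
  # fallback when every fold fails (no features survive selection); using
  # the same rule for the observed and permuted runs keeps them exchangeable
  runStat <- function(yy, sd) {
    agg <- tryCatch(aggregateMetrics(runCVMatrix(x, yy, p2, sd)),
                    error = function(e) NULL)
    if (is.null(agg))
      return(c(acc = max(mean(yy), 1 - mean(yy)), auc = 0.5))
    c(acc = agg$metrics$mean[agg$metrics$metric == "accuracy"],
      auc = agg$pooledAUC)
  }
  obs <- runStat(y, p2@seed)
  obsAcc <- obs[["acc"]]
  obsAUC <- obs[["auc"]]
  nullAcc <- nullAUC <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    bSeed <- childSeed(params@seed, 100000L + b)
    set.seed(bSeed)
    yPerm <- sample(y)
    st <- runStat(yPerm, childSeed(bSeed, 1L))
    nullAcc[b] <- st[["acc"]]
    nullAUC[b] <- st[["auc"]]
  }
  new("PermutationResult", B = as.integer(B),
      nullAccuracy = nullAcc, nullAUC = nullAUC,
      observedAccuracy = obsAcc, observedAUC = obsAUC,
      pAccuracy = (1 + sum(nullAcc >= obsAcc)) / (B + 1),
      pAUC = (1 + sum(nullAUC >= obsAUC)) / (B + 1))
}
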