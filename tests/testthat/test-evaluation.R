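# Minimal hand-built CVResults for aggregation arithmetic.
fakeResults <- function(accs, scores, yTest, selected = list(1L, 1:2)) {
  mk <- function(i) {
    cm <- list(accuracy = accs[i], sensitivity = accs[i],
               specificity = accs[i], recall = accs[i], precision = accs[i])
    list(repeat_id = 1L, fold_id = i, testIdx = i, screened = 1:3,
         innerOccurrence = integer(3),
         selected = selected[[(i - 1) %% length(selected) + 1]],
         model = NULL, metrics = cm, scores = scores[[i]],
         yTest = yTest[[i]], failure = NULL)
  }
  new("CVResults", folds = lapply(seq_along(accs), mk),
      params = PipelineParams(), nEdges = 3L,
      nSubjects = length(unlist(yTest)))
}

test_that("child seeds are valid 32-bit seeds and deterministic", {
  s <- vapply(1:500, function(i) FCSelect:::childSeed(17L, i), integer(1))
  expect_true(all(s > 0 & s < 2^31))
  expect_identical(FCSelect:::childSeed(17L, 3L), FCSelect:::childSeed(17L, 3L))
  expect_false(FCSelect:::childSeed(17L, 3L) == FCSelect:::childSeed(17L, 4L))
})

test_that("stratified fold assignment partitions subjects with both classes", {
  y <- rep(c(0L, 1L), c(12, 18))
  fid <- FCSelect:::assignFolds(y, 5, seed = 3, stratified = TRUE)
  expect_identical(sort(unique(fid)), 1:5)
  for (f in 1:5) {
    expect_true(all(table(y[fid == f]) >= 1))
  }
  expect_identical(length(fid), 30L)
})

test_that("repeated CV produces repeats x k folds that partition subjects", {
  tab <- makeSignalTable(nRoi = 8, n0 = 12, n1 = 14, d = 2, seed = 5,
                         signalEdges = rbind(c(1, 2), c(3, 7)))
  params <- PipelineParams(repeats = 3, kOuter = 5, kInner = 5,
                           nOccurrence = 3L, seed = 9)
  res <- runRepeatedCV(tab, params)
  expect_identical(length(foldResults(res)), 15L)
  for (r in 1:3) {
    idx <- unlist(lapply(Filter(function(f) f$repeat_id == r,
                                foldResults(res)), `[[`, "testIdx"))
    expect_setequal(idx, 1:26)   # each repeat partitions all subjects once
  }
  # fixed master seed: bit-identical end to end
  res2 <- runRepeatedCV(tab, params)
  expect_identical(lapply(foldResults(res), `[[`, "selected"),
                   lapply(foldResults(res2), `[[`, "selected"))
  expect_identical(aggregateMetrics(res)$metrics,
                   aggregateMetrics(res2)$metrics)
})

test_that("per-fold selection never uses held-out subjects", {
  tab <- makeSignalTable(nRoi = 8, n0 = 10, n1 = 12, d = 2, seed = 6,
                         signalEdges = rbind(c(1, 2), c(3, 7)))
  x <- edgeMatrix(tab); y <- groupLabels(tab)
  params <- PipelineParams(kInner = 5, nOccurrence = 3L)
  testIdx <- c(1, 2, 11, 12)
  f1 <- evaluateFold(x, y, testIdx, params, seed = 4)
  xNoise <- x
  set.seed(99)
  xNoise[testIdx, ] <- rnorm(length(testIdx) * ncol(x))
  f2 <- evaluateFold(xNoise, y, testIdx, params, seed = 4)
  expect_identical(f1$screened, f2$screened)
  expect_identical(f1$selected, f2$selected)
  expect_equal(f1$model@weights, f2$model@weights)
})

test_that("folds that cannot select features are recorded as failures", {
  set.seed(21)
  x <- matrix(rnorm(24 * 10), 24, 10)
  y <- rep(0:1, 12)
  params <- PipelineParams(p0 = 1e-9, kInner = 5)
  f <- evaluateFold(x, y, 1:4, params, seed = 2)
  expect_match(f$failure, "screen")
  expect_null(f$model)
})

test_that("aggregation computes fold mean, SD and pooled AUC", {
  scores <- list(c(1, -1), c(2, -2))
  yTest <- list(c(1L, 0L), c(1L, 0L))
  res <- fakeResults(c(0.8, 1.0), scores, yTest)
  agg <- aggregateMetrics(res)
  acc <- agg$metrics[agg$metrics$metric == "accuracy", ]
  expect_equal(acc$mean, 0.9)
  expect_equal(acc$sd, 0.1414214, tolerance = 1e-6)
  # pooled AUC is the Mann-Whitney statistic on the concatenated scores
  expect_equal(agg$pooledAUC,
               rocAUC(unlist(scores), unlist(yTest))$auc)
  # SD is zero when every fold agrees
  same <- aggregateMetrics(fakeResults(c(0.75, 0.75), scores, yTest))
  expect_equal(same$metrics$sd[1], 0)
})

test_that("grid search honours grids, deduplication and tie-breaking", {
  tab <- makeSignalTable(nRoi = 8, n0 = 12, n1 = 12, d = 3, seed = 7,
                         signalEdges = rbind(c(1, 2), c(3, 7)))
  params <- PipelineParams(kOuter = 4, kInner = 4, nOccurrence = 2L,
                           seed = 2)

  # single-point grids return that triple
  gs1 <- gridSearch(tab, p0Grid = 0.05, nGrid = 2, cGrid = 0.7,
                    params = params)
  expect_equal(gs1$best@p0, 0.05)
  expect_identical(gs1$best@nOccurrence, 2L)
  expect_equal(gs1$best@svmCost, 0.7)
  expect_identical(nrow(gs1$table), 1L)

  # duplicated grid values are collapsed before evaluation
  gs2 <- gridSearch(tab, p0Grid = c(0.05, 0.05), nGrid = c(2, 2, 3),
                    cGrid = c(0.7, 0.7), params = params)
  expect_identical(nrow(gs2$table), 2L)

  # deterministic tie-breaking: with a dominant signal many triples reach
  # the maximum; the winner must be the largest N, then smallest c / p0
  gs3 <- gridSearch(tab, p0Grid = c(0.01, 0.05), nGrid = c(2, 4),
                    cGrid = c(0.5, 1), params = params)
  top <- gs3$table[which(gs3$table$accuracy ==
                           max(gs3$table$accuracy, na.rm = TRUE)), ]
  expect_identical(gs3$best@nOccurrence, as.integer(max(top$n)))
  sub <- top[top$n == max(top$n), ]
  expect_equal(gs3$best@svmCost, min(sub$c))
})

test_that("permutation p-values follow the add-one formula", {
  tab <- makeSignalTable(nRoi = 8, n0 = 10, n1 = 10, d = 3, seed = 8,
                         signalEdges = rbind(c(1, 2), c(3, 7)))
  params <- PipelineParams(repeats = 1, kOuter = 4, kInner = 4,
                           nOccurrence = 2L, seed = 5)
  pr <- permutationTest(tab, params, B = 9, repeats = 1)
  expect_identical(pr@B, 9L)
  expect_length(pr@nullAccuracy, 9)
  expect_equal(pr@pAccuracy,
               (1 + sum(pr@nullAccuracy >= pr@observedAccuracy)) / 10)
  expect_equal(pr@pAUC, (1 + sum(pr@nullAUC >= pr@observedAUC)) / 10)
  expect_gt(pr@pAccuracy, 0)
  expect_lte(pr@pAccuracy, 1)
  # strong planted signal should beat most label permutations
  expect_lt(pr@pAUC, 0.5)
})
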