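test_that("outer occurrence counting satisfies the double-counting identity", {
  tab <- makeSignalTable(nRoi = 8, n0 = 12, n1 = 12, d = 2.5, seed = 4,
                         signalEdges = rbind(c(1, 2), c(3, 7)))
  res <- runRepeatedCV(tab, PipelineParams(repeats = 2, kOuter = 4,
                                           kInner = 4, nOccurrence = 2L,
                                           seed = 6))
  occ <- countOuterOccurrence(res)
  ok <- Filter(function(f) is.null(f$failure), foldResults(res))
  expect_identical(sum(occ),
                   sum(vapply(ok, function(f) length(f$selected), integer(1))))
  expect_true(all(occ <= length(foldResults(res))))
  # an edge selected in every successful fold, and one never selected
  sizes <- table(unlist(lapply(ok, `[[`, "selected")))
  expect_identical(max(occ), as.integer(max(sizes)))
  expect_identical(occ[which.max(-occ)], min(occ))
})

test_that("stable-feature extraction uses the strictly-greater rule", {
  occ <- c(800L, 400L, 501L, 0L)
  occ <- c(occ, integer(6))    # 10 edges = 5 ROIs
  s <- stableFeatures(occ, 500)
  expect_identical(s$edge, c(1L, 3L))
  expect_identical(s$occurrence, c(800L, 501L))
  # threshold at the fold count keeps only ever-present edges
  expect_identical(stableFeatures(occ, 799)$edge, 1L)
  # threshold 0 keeps every edge ever selected
  expect_identical(stableFeatures(occ, 0)$edge, c(1L, 3L, 2L))
  # monotone: higher threshold never grows the set
  for (thr in c(0, 100, 500, 799))
    expect_true(all(stableFeatures(occ, thr + 100)$edge %in%
                      stableFeatures(occ, thr)$edge))
})

test_that("stable edges resolve to valid ROI pairs through the edge map", {
  tab <- makeSignalTable(nRoi = 8, n0 = 12, n1 = 12, d = 3, seed = 9,
                         signalEdges = rbind(c(1, 2), c(3, 7)))
  res <- runRepeatedCV(tab, PipelineParams(repeats = 2, kOuter = 4,
                                           kInner = 4, nOccurrence = 2L,
                                           seed = 2))
  rep <- stabilityReport(res, tab)
  df <- rep@table
  expect_true(nrow(df) >= 1)
  for (r in seq_len(nrow(df))) {
    pair <- edgeIndexToPair(df$edge[r], 8)
    expect_identical(unname(pair[1, ]), c(df$roi_i[r], df$roi_j[r]))
    expect_identical(df$edge[r],
                     pairToEdgeIndex(df$roi_i[r], df$roi_j[r], 8))
  }
  # sorted by occurrence descending; corrected p never below raw p
  expect_true(all(diff(df$occurrence) <= 0))
  expect_true(all(df$p_fwe >= df$p - 1e-15))
})

test_that("group-difference tests apply FWE correction and directions", {
  tab <- makeSignalTable(nRoi = 8, n0 = 15, n1 = 15, d = 2, seed = 3,
                         signalEdges = rbind(c(1, 2), c(3, 7)))
  gd <- groupDifferenceTests(tab, edges = c(1L, 5L, 9L, 13L, 20L))
  expect_equal(gd$p_fwe, pmin(1, gd$p * 5))
  expect_true(all(gd$significant == (gd$p_fwe < 0.05)))
  # Bonferroni significance implies raw significance at the same alpha
  expect_true(all(!gd$significant | gd$p < 0.05))
  # single tested edge: corrected equals raw
  g1 <- groupDifferenceTests(tab, edges = 1L)
  expect_equal(g1$p_fwe, g1$p)
  # direction matches the sign of the group mean difference
  x <- edgeMatrix(tab); y <- groupLabels(tab)
  for (r in seq_len(nrow(gd))) {
    diffMeans <- mean(x[y == 0, gd$edge[r]]) - mean(x[y == 1, gd$edge[r]])
    expect_identical(gd$direction[r], if (diffMeans > 0) "HC>PE" else "HC<PE")
  }
  # Holm is never less powerful than Bonferroni
  gh <- groupDifferenceTests(tab, edges = c(1L, 5L, 9L), method = "holm")
  gb <- groupDifferenceTests(tab, edges = c(1L, 5L, 9L))
  expect_true(all(gh$p_fwe <= gb$p_fwe + 1e-15))
})

test_that("weight summaries average |w| over the folds containing the edge", {
  mkModel <- function(idx, w) new("SVMModel", featureIndices = idx,
                                  weights = w, bias = 0, cost = 1,
                                  center = numeric(length(idx)),
                                  scale = rep(1, length(idx)))
  mkFold <- function(model, selected, id) {
    list(repeat_id = 1L, fold_id = id, testIdx = id, screened = selected,
         innerOccurrence = integer(0), selected = selected, model = model,
         metrics = list(accuracy = 1, sensitivity = 1, specificity = 1,
                        recall = 1, precision = 1),
         scores = 1, yTest = 1L, failure = NULL)
  }
  folds <- list(mkFold(mkModel(c(1L, 2L), c(0.5, -0.2)), c(1L, 2L), 1L),
                mkFold(mkModel(1L, -0.7), 1L, 2L))
  res <- new("CVResults", folds = folds, params = PipelineParams(),
             nEdges = 3L, nSubjects = 4L)
  w <- featureWeightSummary(res, c(1L, 2L, 3L))
  expect_equal(w[1], 0.6)          # mean(|0.5|, |-0.7|)
  expect_equal(w[2], 0.2)
  expect_true(is.na(w[3]))         # never entered a model: absent, not zero
  # invariant to fold order
  res2 <- new("CVResults", folds = rev(folds), params = PipelineParams(),
              nEdges = 3L, nSubjects = 4L)
  expect_equal(featureWeightSummary(res2, c(1L, 2L, 3L)), w)
})

test_that("mean selected count averages over successful folds only", {
  mkFold <- function(selected, failure = NULL) {
    list(repeat_id = 1L, fold_id = 1L, testIdx = 1, screened = integer(0),
         innerOccurrence = integer(0), selected = selected, model = NULL,
         metrics = NULL, scores = NULL, yTest = integer(0),
         failure = failure)
  }
  res <- new("CVResults",
             folds = list(mkFold(1:8), mkFold(1:10),
                          mkFold(integer(0), failure = "empty set")),
             params = PipelineParams(), nEdges = 20L, nSubjects = 5L)
  expect_equal(meanSelectedCount(res), 9)
})

test_that("stability report round-trips through its writers", {
  tab <- makeSignalTable(nRoi = 8, n0 = 12, n1 = 12, d = 3, seed = 10,
                         signalEdges = rbind(c(1, 2), c(3, 7)))
  res <- runRepeatedCV(tab, PipelineParams(repeats = 1, kOuter = 4,
                                           kInner = 4, nOccurrence = 2L,
                                           seed = 3))
  rep <- stabilityReport(res, tab)
  csv <- tempfile(fileext = ".csv"); md <- tempfile(fileext = ".md")
  writeStabilityReport(rep, csvPath = csv, mdPath = md)
  back <- read.csv(csv)
  expect_identical(back$edge, rep@table$edge)
  expect_identical(back$occurrence, rep@table$occurrence)
  lines <- readLines(md)
  expect_true(any(grepl("circular", lines)))
  expect_true(any(grepl("\\| Edge \\|", lines)))
})
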