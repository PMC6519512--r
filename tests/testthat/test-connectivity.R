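test_that("cleaning detrends, removes confounds, and is idempotent up to the filter", {
  set.seed(1)
  nT <- 200
  sig <- matrix(rnorm(nT * 3), nT, 3)
  sig[, 1] <- sig[, 1] + 0.05 * seq_len(nT)        # linear trend
  ts <- ROITimeSeries(sig, tr = 2)

  # a confound identical to an ROI column drives that ROI's residual to zero
  cf <- ConfoundSet(cbind(sig[, 2]), roles = "csf")
  out <- cleanTimeseries(ts, cf, band = NULL)
  expect_lt(max(abs(seriesValues(out)[, 2])), 1e-8)

  # detrend + confound regression (no filter) is exactly idempotent
  once <- cleanTimeseries(ts, cf, band = NULL)
  twice <- cleanTimeseries(once, cf, band = NULL)
  expect_lt(max(abs(seriesValues(twice) - seriesValues(once))), 1e-6)

  # collinear confounds are dropped with a warning, fit unchanged
  cf2 <- ConfoundSet(cbind(sig[, 2], sig[, 2] * 2), roles = c("csf", "wm"))
  expect_warning(out2 <- cleanTimeseries(ts, cf2, band = NULL), "collinear")
  expect_equal(seriesValues(out2), seriesValues(out), tolerance = 1e-10)
})

test_that("band-pass keeps in-band and removes out-of-band oscillations", {
  tt <- seq(0, by = 2, length.out = 600)   # TR = 2 s
  inband <- sin(2 * pi * 0.05 * tt)
  outband <- sin(2 * pi * 0.2 * tt)
  ts <- ROITimeSeries(cbind(a = inband, b = outband), tr = 2)
  out <- seriesValues(cleanTimeseries(ts, band = c(0.01, 0.1)))
  core <- 150:450                          # away from filter edge effects
  expect_gt(max(abs(out[core, 1])), 0.9)   # 0.05 Hz retained within 10%
  expect_lt(max(abs(out[core, 2])), 0.1)   # 0.2 Hz attenuated > 90%

  # band must sit inside (0, Nyquist)
  expect_error(cleanTimeseries(ts, band = c(0.01, 0.3)), "Nyquist")
  expect_error(cleanTimeseries(ts, band = c(0, 0.1)), "Nyquist")
})

test_that("ROI extraction averages unit series", {
  m <- cbind(c(1, 1, 1), c(2, 2, 2), c(3, 4, 5), c(3, 4, 5))
  # one unit per ROI: identity
  out <- extractROISeries(m[, 1:2], c("A", "B"), tr = 2)
  expect_equal(unname(seriesValues(out)), unname(m[, 1:2]))
  # duplicated units average to either one
  out2 <- extractROISeries(m[, 3:4], c("C", "C"), tr = 2)
  expect_equal(unname(seriesValues(out2)[, 1]), c(3, 4, 5))
  # plain arithmetic mean
  out3 <- extractROISeries(cbind(c(1, 1), c(3, 3)), c("D", "D"), tr = 2)
  expect_equal(unname(seriesValues(out3)[, 1]), c(2, 2))
  # empty ROI is an error naming the ROI
  expect_error(extractROISeries(m[, 1:2], c("A", "B"), roiOrder = c("A", "B", "Z")),
               "Z")
})

test_that("Pearson connectivity matches the closed form", {
  ts <- ROITimeSeries(cbind(a = c(1, 2, 3), b = c(1, 2, 3) * 2 + 1,
                            c = c(3, 2, 1), d = c(1, 3, 2)), tr = 2)
  m <- seriesValues(correlationMatrix(ts))
  expect_equal(m["a", "b"], 1)
  expect_equal(m["a", "c"], -1)
  expect_equal(m["a", "d"], 0.5)
  expect_equal(diag(m), setNames(rep(1, 4), colnames(m)))

  # invariant to positive affine rescaling of a column
  ts2 <- ROITimeSeries(seriesValues(ts) %*% diag(c(3, 1, 1, 1)) + 5, tr = 2,
                       roiNames = roiNames(ts))
  expect_equal(seriesValues(correlationMatrix(ts2)), m)

  expect_error(correlationMatrix(ROITimeSeries(cbind(a = c(1, 1, 1),
                                                     b = c(1, 2, 3)), 2)),
               "zero-variance.*a")
})

test_that("edge vectorization follows the canonical row-major order", {
  # 90 ROIs give the full 4005-edge vector
  expect_identical(nrow(edgePairs(90)), 4005L)

  m <- matrix(0.5, 2, 2); diag(m) <- 1
  dimnames(m) <- list(c("r1", "r2"), c("r1", "r2"))
  expect_equal(as.numeric(vectorizeEdges(m)), 0.5)

  # canonical order for n = 4: pair (1,2) first, (3,4) last
  m4 <- outer(1:4, 1:4, function(i, j) i * 10 + j)
  m4 <- (m4 + t(m4)) / 2; diag(m4) <- 1
  dimnames(m4) <- list(letters[1:4], letters[1:4])
  v <- vectorizeEdges(m4)
  expect_equal(as.numeric(v[1]), m4[1, 2])
  expect_equal(as.numeric(v[6]), m4[3, 4])
  expect_equal(as.numeric(v), unname(m4[edgePairs(4)]))

  expect_error(vectorizeEdges(matrix(c(1, 0.2, 0.3, 1), 2)), "symmetric")
})

test_that("vectorize/unvectorize round-trip exactly for n up to 20", {
  set.seed(8)
  for (n in c(2, 3, 6, 11, 20)) {
    a <- matrix(rnorm(n * n), n)
    m <- (a + t(a)) / 2; diag(m) <- 1
    dimnames(m) <- list(paste0("R", 1:n), paste0("R", 1:n))
    v <- vectorizeEdges(m)
    expect_equal(unvectorizeEdges(as.numeric(v), rownames(m)), m)
  }
})

test_that("edge index <-> ROI pair mapping matches brute-force enumeration", {
  expect_identical(unname(edgeIndexToPair(1, 90)[1, ]), c(1L, 2L))
  expect_identical(unname(edgeIndexToPair(4005, 90)[1, ]), c(89L, 90L))
  expect_error(edgeIndexToPair(4006, 90), "out of range")
  expect_error(edgeIndexToPair(0, 90), "out of range")

  for (n in c(6, 13)) {
    brute <- NULL
    for (i in 1:(n - 1)) for (j in (i + 1):n) brute <- rbind(brute, c(i, j))
    k <- seq_len(n * (n - 1) / 2)
    ij <- edgeIndexToPair(k, n)
    expect_true(all(ij == brute))
    expect_identical(pairToEdgeIndex(ij[, 1], ij[, 2], n), k)
  }
})

test_that("the connectivity pipeline assembles a valid edge table", {
  set.seed(3)
  series <- lapply(1:6, function(s)
    simulateROITimeSeries(diag(5), 120, tr = 2, seed = s))
  tab <- connectivityPipeline(series, labels = rep(0:1, each = 3),
                              band = c(0.01, 0.1))
  expect_s4_class(tab, "EdgeTable")
  expect_identical(dim(edgeMatrix(tab)), c(6L, 10L))
  expect_true(all(abs(edgeMatrix(tab)) <= 1))
  # Fisher-z option transforms the same values through atanh
  tabz <- connectivityPipeline(series, labels = rep(0:1, each = 3),
                               band = c(0.01, 0.1), fisherZ = TRUE)
  expect_equal(edgeMatrix(tabz), atanh(edgeMatrix(tab)), tolerance = 1e-10)
})
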