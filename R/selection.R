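## Feature selection: univariate t-test screen, then inner CV-LASSO with the
## one-standard-error rule combined across folds by an occurrence threshold.

#' Two-sample t-test screen over edges
#'
#' Pooled-variance (Student) two-sided t-test per edge, controls vs patients;
#' edges with p < `p0` pass the screen. The t statistic is signed as
#' control minus patient, so positive t means HC > patient at that edge.
#' An edge with zero pooled variance gets p = 1 (with a warning) and never
#' passes.
#'
#' @param x an [EdgeTable-class], or a subjects-by-edges numeric matrix.
#' @param y group labels (0 control / 1 patient); ignored when `x` is an
#'   [EdgeTable-class].
#' @param p0 screening threshold, 0 < p0 <= 1.
#' @return List with `tstat`, `p` (per edge) and `screened` (indices with
#'   p < p0, canonical order).
#' @examples
#' ttestScreen(rbind(c(1, 0), c(2, 0), c(3, 0), c(4, 1), c(5, 1), c(6, 0)),
#'             y = c(0, 0, 0, 1, 1, 1), p0 = 0.05)$tstat
#' @export
ttestScreen <- function(x, y = NULL, p0 = 0.05) {
  if (is(x, "EdgeTable")) { y <- groupLabels(x); x <- edgeMatrix(x) }
  x <- as.matrix(x); y <- as.integer(y)
  stopifnot(length(y) == nrow(x), p0 > 0, p0 <= 1)
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  if (n0 < 2L || n1 < 2L)
    stop("need at least 2 subjects per class for the t-test screen")
  x0 <- x[y == 0L, , drop = FALSE]; x1 <- x[y == 1L, , drop = FALSE]
  m0 <- colMeans(x0); m1 <- colMeans(x1)
  ss0 <- colSums(x0^2) - n0 * m0^2
  ss1 <- colSums(x1^2) - n1 * m1^2
  df <- n0 + n1 - 2L
  sp2 <- (ss0 + ss1) / df
  se <- sqrt(sp2 * (1 / n0 + 1 / n1))
  tstat <- (m0 - m1) / se
  degenerate <- !is.finite(tstat)
  if (any(degenerate)) {
    warning(sum(degenerate), " edge(s) with zero pooled variance; p set to 1")
    tstat[degenerate] <- 0
  }
  p <- 2 * stats::pt(-abs(tstat), df = df)
  p[degenerate] <- 1
  list(tstat = tstat, p = p, screened = which(p < p0))
}

# Per-column standardization with population (1/n) variance; constant
# columns keep scale 1 so they map to all-zeros rather than NaN.
standardizeFit <- function(x) {
  center <- colMeans(x)
  scale <- sqrt(colMeans(x^2) - center^2)
  scale[scale < .Machine$double.eps] <- 1
  list(center = center, scale = scale)
}

standardizeApply <- function(x, std) {
  sweep(sweep(x, 2L, std$center, "-"), 2L, std$scale, "/")
}

# Log-spaced lambda path from lambda_max = max |(1/n) X'(y - ybar)| down to
# minRatio * lambda_max.
lambdaGrid <- function(x, y, nLambda = 100L, minRatio = 1e-3) {
  yc <- y - mean(y)
  lmax <- max(abs(colMeans(x * yc)))
  if (lmax <= 0) lmax <- .Machine$double.eps
  exp(seq(log(lmax), log(lmax * minRatio), length.out = nLambda))
}

#' LASSO fit at a single penalty
#'
#' Minimizes (1/2n) sum (y - b0 - X b)^2 + lambda * sum |b| with an
#' unpenalized intercept. Features are expected on a common scale (the
#' pipeline standardizes them before every fit). Single-feature problems are
#' solved in closed form (soft thresholding); larger ones via coordinate
#' descent (glmnet) at high precision.
#'
#' @param x numeric matrix, subjects x features.
#' @param y numeric response (the pipeline uses labels 0/1: a
#'   linear-probability fit under squared error).
#' @param lambda penalty, lambda >= 0.
#' @return List with `intercept` and `beta` (length ncol(x)).
#' @export
fitLasso <- function(x, y, lambda) {
  x <- as.matrix(x); y <- as.numeric(y)
  if (!all(is.finite(x)) || !all(is.finite(y)) || !is.finite(lambda))
    stop("non-finite inputs to the LASSO fit")
  stopifnot(lambda >= 0, nrow(x) == length(y))
  p <- ncol(x)
  if (p == 1L) {
    xc <- x[, 1L] - mean(x); yc <- y - mean(y)
    v <- mean(xc^2)
    if (v <= 0) return(list(intercept = mean(y), beta = 0))
    cc <- mean(xc * yc)
    beta <- sign(cc) * max(abs(cc) - lambda, 0) / v
    return(list(intercept = mean(y) - beta * mean(x),
                beta = beta))
  }
  if (lambda == 0) {
    fit <- stats::lm.fit(cbind(1, x), y)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    return(list(intercept = unname(cf[1L]), beta = unname(cf[-1L])))
  }
  g <- glmnet::glmnet(x, y, family = "gaussian", standardize = FALSE,
                      intercept = TRUE, thresh = 1e-12)
  cf <- as.numeric(stats::coef(g, s = lambda, exact = TRUE, x = x, y = y))
  list(intercept = cf[1L], beta = cf[-1L])
}

#' One-standard-error choice of the LASSO penalty
#'
#' Given a descending penalty grid and its cross-validated MSE curve, returns
#' the largest lambda whose CV MSE is within one standard error of the
#' minimum: lambda_1se = max\{lambda : cvm(lambda) <= min(cvm) + se(argmin)\}.
#'
#' @param lambda descending penalty grid.
#' @param cvm cross-validated mean squared error per lambda.
#' @param cvse standard error of `cvm` per lambda.
#' @return The selected lambda.
#' @examples
#' oneSeLambda(c(1, 0.5, 0.1), c(0.30, 0.20, 0.25), c(0.05, 0.06, 0.05)) # 0.5
#' @export
oneSeLambda <- function(lambda, cvm, cvse) {
  if (!length(lambda)) stop("empty lambda grid")
  stopifnot(length(cvm) == length(lambda), length(cvse) == length(lambda),
            all(cvse >= 0))
  if (is.unsorted(rev(lambda))) stop("lambda grid must be descending")
  imin <- which.min(cvm)
  lambda[min(which(cvm <= cvm[imin] + cvse[imin]))]
}

# Cross-validated lambda path on one fitting set: standardize, build the
# path, CV it with `nfolds` random folds, pick lambda by the 1SE rule, and
# return the active set of the full-data fit at that lambda.
cvLassoPath <- function(x, y, nfolds = 5L, seed = 1L,
                        nLambda = 100L, minRatio = 1e-3) {
  n <- nrow(x); p <- ncol(x)
  set.seed(as.integer(seed))
  fid <- sample(rep_len(seq_len(nfolds), n))
  if (p >= 2L) {
    # glmnet standardizes on the fitting subjects of each internal fit,
    # which is exactly the per-fit standardization this pipeline wants
    cvfit <- glmnet::cv.glmnet(x, y, family = "gaussian",
                               nlambda = nLambda,
                               lambda.min.ratio = minRatio,
                               foldid = fid, standardize = TRUE,
                               intercept = TRUE,
                               grouped = min(table(fid)) >= 3)
    l1se <- oneSeLambda(cvfit$lambda, cvfit$cvm, cvfit$cvsd)
    beta <- as.numeric(stats::coef(cvfit$glmnet.fit,
                                   s = l1se))[-1L]
    return(list(lambda = cvfit$lambda, cvm = cvfit$cvm, cvse = cvfit$cvsd,
                lambda1se = l1se, beta = beta,
                active = which(abs(beta) > 0)))
  }
  # single screened feature: closed-form fits along the grid
  std <- standardizeFit(x)
  xs <- standardizeApply(x, std)
  grid <- lambdaGrid(xs, y, nLambda, minRatio)
  mse <- matrix(NA_real_, nfolds, length(grid))
  for (f in seq_len(nfolds)) {
    tr <- fid != f
    fit <- lapply(grid, function(l) fitLasso(xs[tr, , drop = FALSE],
                                             y[tr], l))
    pred <- vapply(fit, function(fl)
      mean((y[!tr] - fl$intercept - xs[!tr, 1L] * fl$beta)^2), numeric(1))
    mse[f, ] <- pred
  }
  cvm <- colMeans(mse)
  cvse <- apply(mse, 2, stats::sd) / sqrt(nfolds)
  l1se <- oneSeLambda(grid, cvm, cvse)
  beta <- fitLasso(xs, y, l1se)$beta
  list(lambda = grid, cvm = cvm, cvse = cvse, lambda1se = l1se,
       beta = beta, active = which(abs(beta) > 0))
}

#' Inner CV-LASSO stability selection
#'
#' Splits the training subjects into `kInner` groups; for each group in turn,
#' a LASSO is fit on the remaining subjects with the penalty chosen by an
#' internal `lambdaFolds`-fold CV curve and the one-standard-error rule
#' ([oneSeLambda()]). The nonzero-coefficient set of each of the `kInner`
#' fits is one candidate feature set; `innerOccurrence` counts, per edge, in
#' how many of the `kInner` sets it appears.
#'
#' If excluding some group would leave only one class in the fitting set, the
#' split is redone stratified by group (with a warning).
#'
#' @param x subjects-by-features numeric matrix (typically the screened
#'   columns of the training fold).
#' @param y labels 0/1.
#' @param kInner number of inner groups (default 10).
#' @param seed RNG seed for the split and the nested lambda CV.
#' @param lambdaFolds folds of the nested lambda-selection CV (default 5).
#' @param nLambda,lambdaMinRatio lambda path controls.
#' @return List with `innerSets` (length `kInner`, column indices of `x`) and
#'   `innerOccurrence` (integer per column of `x`, range 0..kInner).
#' @export
cvLassoSelect <- function(x, y, kInner = 10L, seed = 1L, lambdaFolds = 5L,
                          nLambda = 100L, lambdaMinRatio = 1e-3) {
  x <- as.matrix(x); y <- as.numeric(y)
  kInner <- as.integer(kInner)
  stopifnot(nrow(x) >= kInner, length(unique(y)) == 2L)
  set.seed(as.integer(seed))
  grp <- sample(rep_len(seq_len(kInner), nrow(x)))
  oneClass <- vapply(seq_len(kInner),
                     function(g) length(unique(y[grp != g])) < 2L, logical(1))
  if (any(oneClass)) {
    warning("random inner split left a one-class fitting set; ",
            "falling back to a stratified split")
    grp <- integer(nrow(x))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      grp[idx] <- rep_len(seq_len(kInner), length(idx))
    }
  }
  innerSets <- vector("list", kInner)
  occ <- integer(ncol(x))
  for (g in seq_len(kInner)) {
    keep <- grp != g
    cv <- cvLassoPath(x[keep, , drop = FALSE], y[keep],
                      nfolds = lambdaFolds, seed = childSeed(seed, g),
                      nLambda = nLambda, minRatio = lambdaMinRatio)
    innerSets[[g]] <- cv$active
    occ[cv$active] <- occ[cv$active] + 1L
  }
  list(innerSets = innerSets, innerOccurrence = occ)
}

#' Occurrence-threshold feature selection
#'
#' @param innerOccurrence integer vector from [cvLassoSelect()].
#' @param n occurrence threshold N: an edge is kept if it appeared in at
#'   least N of the inner feature sets.
#' @return Integer indices of the kept features, in canonical order.
#' @examples
#' selectByOccurrence(c(10L, 3L, 7L), 5)   # features 1 and 3
#' @export
selectByOccurrence <- function(innerOccurrence, n) {
  stopifnot(n >= 1)
  which(innerOccurrence >= n)
}
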