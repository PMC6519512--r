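## Linear soft-margin SVM (libsvm via e1071) and the test-fold metrics.

#' Train a linear soft-margin SVM
#'
#' C-classification linear SVM minimizing (1/2)||w||^2 + c * sum hinge
#' losses, fit with libsvm. Features are standardized with the training
#' mean/sd (stored in the model and re-applied at prediction time). The sign
#' convention is normalized so that patients (label 1) score positive.
#'
#' @param x training subjects x selected features matrix (>= 1 feature).
#' @param y labels 0 (control) / 1 (patient); both classes required.
#' @param cost SVM cost c > 0.
#' @param featureIndices optional original edge indices of the columns of
#'   `x` (defaults to 1..ncol(x)); stored for bookkeeping.
#' @param tolerance libsvm termination tolerance (default 1e-8, tight enough
#'   that the solution is at the optimum of the hinge objective for the
#'   problem sizes this pipeline meets).
#' @return An [SVMModel-class].
#' @examples
#' m <- trainLSVM(cbind(c(-2, -1, 1, 2)), c(0, 0, 1, 1), cost = 10)
#' decisionScores(m, cbind(c(-1.5, 1.5)))
#' @export
trainLSVM <- function(x, y, cost = 1, featureIndices = NULL,
                      tolerance = 1e-8) {
  x <- as.matrix(x); y <- as.integer(y)
  if (ncol(x) < 1L) stop("no features selected upstream; refusing to train")
  if (length(unique(y)) < 2L) stop("both classes required to train the SVM")
  stopifnot(cost > 0, nrow(x) == length(y))
  if (is.null(featureIndices)) featureIndices <- seq_len(ncol(x))
  std <- standardizeFit(x)
  xs <- standardizeApply(x, std)
  fit <- e1071::svm(xs, factor(y, levels = c(0L, 1L)),
                    type = "C-classification", kernel = "linear",
                    cost = cost, scale = FALSE, tolerance = tolerance)
  w <- as.numeric(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm signs the decision function so its first training label is
  # positive; enforce patient-positive deterministically
  if (fit$labels[1L] == which(fit$levels == "0")) { w <- -w; b <- -b }
  # With no free support vectors (all alphas at the box bound) the dual does
  # not pin the bias and libsvm's midpoint pick need not minimize the primal
  # objective; recompute b as the exact 1-D hinge minimizer given w.
  if (all(abs(fit$coefs) >= cost * (1 - 1e-9))) {
    ypm <- ifelse(y == 1L, 1, -1)
    s <- drop(xs %*% w)
    bp <- sort(unique(ypm - s))           # hinge breakpoints in b
    g <- vapply(bp, function(bb) sum(pmax(0, 1 - ypm * (s + bb))), numeric(1))
    opt <- bp[abs(g - min(g)) < 1e-12]
    b <- (min(opt) + max(opt)) / 2
  }
  new("SVMModel", featureIndices = as.integer(featureIndices),
      weights = w, bias = b, cost = cost,
      center = unname(std$center), scale = unname(std$scale))
}

#' Decision scores of a linear SVM
#'
#' Signed score f(x) = w . x_std + b; predicted class is patient (1) iff the
#' score is positive.
#'
#' @param model an [SVMModel-class].
#' @param x subjects x features matrix with the same columns the model was
#'   trained on.
#' @return Numeric score per subject.
#' @export
decisionScores <- function(model, x) {
  stopifnot(is(model, "SVMModel"))
  x <- as.matrix(x)
  if (ncol(x) != length(model@weights))
    stop("feature count mismatch: model has ", length(model@weights),
         ", data has ", ncol(x))
  xs <- standardizeApply(x, list(center = model@center, scale = model@scale))
  drop(xs %*% model@weights) + model@bias
}

#' Classification metrics from a confusion table
#'
#' Patient (label 1) is the positive class. Sensitivity and recall are both
#' TP/(TP+FN); precision TP/(TP+FP) is emitted alongside. Ratios with a zero
#' denominator are returned as `NaN`.
#'
#' @param yTrue,yPred true and predicted labels (0/1), equal length.
#' @return List with `accuracy`, `sensitivity`, `specificity`, `recall`,
#'   `precision` and the counts `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusionMetrics(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusionMetrics <- function(yTrue, yPred) {
  yTrue <- as.integer(yTrue); yPred <- as.integer(yPred)
  if (!length(yTrue)) stop("empty input")
  stopifnot(length(yTrue) == length(yPred))
  tp <- sum(yTrue == 1L & yPred == 1L)
  fp <- sum(yTrue == 0L & yPred == 1L)
  tn <- sum(yTrue == 0L & yPred == 0L)
  fn <- sum(yTrue == 1L & yPred == 0L)
  sens <- tp / (tp + fn)
  list(accuracy = (tp + tn) / length(yTrue),
       sensitivity = sens,
       specificity = tn / (tn + fp),
       recall = sens,
       precision = tp / (tp + fp),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' ROC curve and AUC
#'
#' AUC is computed as the Mann-Whitney probability that a random patient
#' scores above a random control, with ties counted 1/2; the curve is
#' emitted at every distinct threshold (one (FPR, TPR) point per distinct
#' score, plus the end points), so trapezoidal integration of the curve
#' reproduces the same AUC.
#'
#' @param scores decision scores (higher = more patient-like).
#' @param yTrue labels 0/1; both classes required.
#' @return List with `auc` and `curve` (data.frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
rocAUC <- function(scores, yTrue) {
  yTrue <- as.integer(yTrue)
  stopifnot(length(scores) == length(yTrue))
  nPos <- sum(yTrue == 1L); nNeg <- sum(yTrue == 0L)
  if (nPos == 0L || nNeg == 0L) stop("both classes required for the ROC")
  r <- rank(scores)
  auc <- (sum(r[yTrue == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & yTrue == 1L) / nPos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & yTrue == 0L) / nNeg,
                numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  list(auc = auc, curve = curve)
}
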