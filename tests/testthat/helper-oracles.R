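## Independent oracles used by the test suite. These deliberately avoid the
## code paths they check: the LASSO oracle enumerates KKT sign patterns, the
## SVM oracle solves the dual QP with a generic interior-point solver.

# Exact LASSO minimizer of (1/2n)||y - b0 - X b||^2 + lambda ||b||_1 for
# small p, by enumerating all 3^p sign patterns and checking the KKT
# conditions of each candidate.
lassoKKTOracle <- function(x, y, lambda, tol = 1e-8) {
  x <- as.matrix(x); n <- nrow(x); p <- ncol(x)
  stopifnot(p <= 4)
  xc <- sweep(x, 2, colMeans(x))
  yc <- y - mean(y)
  G <- crossprod(xc) / n
  cvec <- as.numeric(crossprod(xc, yc)) / n
  signs <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), p)))
  for (r in seq_len(nrow(signs))) {
    s <- signs[r, ]
    A <- which(s != 0)
    beta <- numeric(p)
    if (length(A)) {
      sol <- tryCatch(solve(G[A, A, drop = FALSE],
                            cvec[A] - lambda * s[A]),
                      error = function(e) NULL)
      if (is.null(sol)) next
      if (any(sign(sol) != s[A])) next
      beta[A] <- sol
    }
    grad0 <- cvec - as.numeric(G %*% beta)   # at inactive coordinates
    if (length(A) < p && any(abs(grad0[setdiff(seq_len(p), A)]) > lambda + tol))
      next
    return(list(intercept = mean(y) - sum(colMeans(x) * beta), beta = beta))
  }
  stop("no KKT-consistent sign pattern found")
}

lassoObjective <- function(x, y, intercept, beta, lambda) {
  r <- y - intercept - as.numeric(as.matrix(x) %*% beta)
  sum(r^2) / (2 * length(y)) + lambda * sum(abs(beta))
}

# Primal soft-margin objective (1/2)||w||^2 + C sum hinge, labels in {-1,+1}.
hingeObjective <- function(w, b, x, ypm, C) {
  f <- as.numeric(as.matrix(x) %*% w) + b
  0.5 * sum(w^2) + C * sum(pmax(0, 1 - ypm * f))
}

# Linear-SVM oracle: exact minimizer of the soft-margin objective for tiny
# problems, by enumerating the dual KKT active sets. Each alpha_i is either
# 0, at the box bound C, or free (on the margin); for every assignment the
# stationarity conditions give a small linear system in (alpha_free, b),
# and consistent candidates are ranked by their exact primal objective.
svmDualOracle <- function(x, ypm, C, tol = 1e-7) {
  x <- as.matrix(x); n <- nrow(x)
  stopifnot(n <= 9)
  K <- tcrossprod(x)
  states <- as.matrix(expand.grid(rep(list(0:2), n)))  # 0: zero, 1: box, 2: free
  best <- NULL; bestObj <- Inf
  for (r in seq_len(nrow(states))) {
    st <- states[r, ]
    Fset <- which(st == 2L); Cset <- which(st == 1L)
    alpha <- numeric(n); alpha[Cset] <- C
    if (length(Fset)) {
      # y_i f(x_i) = 1 for i in Fset, plus sum alpha_i y_i = 0
      M <- rbind(cbind(K[Fset, Fset, drop = FALSE] *
                         (ypm[Fset] %o% ypm[Fset]), ypm[Fset]),
                 c(ypm[Fset], 0))
      rhs <- c(1 - ypm[Fset] *
                 as.numeric(K[Fset, Cset, drop = FALSE] %*%
                              (C * ypm[Cset])),
               -C * sum(ypm[Cset]))
      sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      aF <- sol[seq_along(Fset)]; b <- sol[length(sol)]
      if (any(aF < -tol) || any(aF > C + tol)) next
      alpha[Fset] <- pmin(pmax(aF, 0), C)
      w <- as.numeric(crossprod(alpha * ypm, x))
    } else {
      if (abs(C * sum(ypm[Cset])) > tol) next
      w <- as.numeric(crossprod(alpha * ypm, x))
      f1 <- function(b) sum(pmax(0, 1 - ypm * (as.numeric(x %*% w) + b)))
      b <- stats::optimize(f1, c(-1e3, 1e3), tol = 1e-12)$minimum
    }
    marg <- ypm * (as.numeric(x %*% w) + b)
    if (any(marg[st == 0L] < 1 - tol)) next
    if (any(marg[Cset] > 1 + tol)) next
    obj <- hingeObjective(w, b, x, ypm, C)
    if (obj < bestObj) { bestObj <- obj; best <- list(w = w, b = b) }
  }
  if (is.null(best)) stop("no KKT-consistent active set found")
  best
}

# Small standardized two-class fixture on the scale the SVM/LASSO fits see.
makeTwoClassMatrix <- function(n0, n1, p, d = 1, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm((n0 + n1) * p), n0 + n1, p)
  y <- rep(c(0L, 1L), c(n0, n1))
  x[y == 1L, 1L] <- x[y == 1L, 1L] + d
  list(x = x, y = y)
}

# Quick synthetic edge table for pipeline-level tests.
makeSignalTable <- function(nRoi = 12, n0 = 15, n1 = 15, d = 2, seed = 1,
                            signalEdges = rbind(c(1, 2), c(3, 8))) {
  simulateEdgeTable(SyntheticSpec(nRoi = nRoi, nGroup0 = n0, nGroup1 = n1,
                                  signalEdges = signalEdges,
                                  effectSizeD = d, seed = seed))
}
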