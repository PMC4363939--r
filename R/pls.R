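# Partial least squares regression by NIPALS.
#
# NIPALS is used rather than a kernel/SVD algorithm because the union week
# protocol produces design matrices with structurally missing cells: the
# iterative weight/score regressions extend naturally to available-data
# projections (each inner product is taken over the observed entries and
# normalized by the observed weight mass). With complete data the algorithm
# coincides with standard PLS2.

.asMatrix <- function(x, prefix) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0(prefix, seq_len(ncol(x)))
  x
}

.scaleParams <- function(M, scale) {
  ctr <- colMeans(M, na.rm = TRUE)
  scl <- if (scale) apply(M, 2, sd, na.rm = TRUE) else rep(1, ncol(M))
  list(center = ctr, scale = scl)
}

#' Fit a PLS regression model
#'
#' Mean-centers and unit-variance scales X and Y, then extracts `ncomp`
#' latent components by NIPALS. Missing X entries are tolerated: weights,
#' scores and loadings are computed from the observed entries only, and
#' deflation touches only observed cells.
#'
#' @param X n x p predictor matrix (NA allowed; no all-NA row or column).
#' @param Y n x r response matrix or vector (complete).
#' @param ncomp number of latent components; at most min(n-1, p).
#' @param scale unit-variance scale the columns (default TRUE).
#' @param tol,maxIter NIPALS convergence control.
#' @return a \linkS4class{PLSModel}.
#' @export
fitPLS <- function(X, Y, ncomp, scale = TRUE, tol = 1e-12, maxIter = 500L) {
  X <- .asMatrix(X, "V")
  Y <- .asMatrix(Y, "Y")
  n <- nrow(X); p <- ncol(X); r <- ncol(Y)
  if (n < 2) stop("need at least two observations")
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (anyNA(Y)) stop("training responses must be complete")
  if (any(rowSums(!is.na(X)) == 0)) stop("X contains an all-missing row")
  if (any(colSums(!is.na(X)) == 0)) stop("X contains an all-missing column")

  xs <- .scaleParams(X, scale)
  zero <- !is.finite(xs$scale) | xs$scale == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero-variance column(s): ",
            paste(head(colnames(X)[zero], 5), collapse = ", "))
    X <- X[, !zero, drop = FALSE]
    p <- ncol(X)
    if (p == 0) stop("no non-constant predictor columns remain")
    xs <- .scaleParams(X, scale)
  }
  ncomp <- as.integer(ncomp)
  if (ncomp < 1 || ncomp > min(n - 1, p))
    stop("'ncomp' must lie in [1, min(n-1, p)] = [1, ", min(n - 1, p), "]")

  ys <- .scaleParams(Y, scale)
  yzero <- !is.finite(ys$scale) | ys$scale == 0
  ys$scale[yzero] <- 1   # constant responses stay centered only

  Xs <- sweep(sweep(X, 2, xs$center), 2, xs$scale, "/")
  Ys <- sweep(sweep(Y, 2, ys$center), 2, ys$scale, "/")
  M <- !is.na(Xs)
  X0 <- ifelse(M, Xs, 0)
  ssxTot <- sum(X0^2)
  ssyTot <- sum(Ys^2)

  W <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  P <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  Q <- matrix(0, r, ncomp, dimnames = list(colnames(Y), NULL))
  Tm <- matrix(0, n, ncomp)
  ssY <- numeric(ncomp)
  r2x <- numeric(ncomp)
  r2y <- numeric(ncomp)

  actual <- 0L
  for (a in seq_len(ncomp)) {
    if (sum(X0^2) < 1e-10 * max(ssxTot, 1)) break   # X exhausted: rank reached
    u <- Ys[, which.max(apply(Ys, 2, var)), drop = TRUE]
    if (all(u == 0)) break                          # Y fully explained
    tOld <- rep(Inf, n)
    for (it in seq_len(maxIter)) {
      wDen <- as.vector(crossprod(M, u^2))
      w <- as.vector(crossprod(X0, u))
      w <- ifelse(wDen > 0, w / wDen, 0)
      nw <- sqrt(sum(w^2))
      if (nw == 0) stop("NIPALS collapsed: zero weight vector at component ", a)
      w <- w / nw
      tDen <- as.vector(M %*% w^2)
      tv <- as.vector(X0 %*% w)
      tv <- ifelse(tDen > 0, tv / tDen, 0)
      q <- as.vector(crossprod(Ys, tv)) / sum(tv^2)
      u <- as.vector(Ys %*% q) / sum(q^2)
      if (sqrt(sum((tv - tOld)^2)) < tol * max(1, sqrt(sum(tv^2)))) break
      tOld <- tv
    }
    if (sum(tv^2) < 1e-12 * n) break                # degenerate score
    pDen <- as.vector(crossprod(M, tv^2))
    pl <- as.vector(crossprod(X0, tv))
    pl <- ifelse(pDen > 0, pl / pDen, 0)

    defl <- (tv %*% t(pl)) * M
    X0 <- X0 - defl
    Ys <- Ys - tv %*% t(q)
    W[, a] <- w; P[, a] <- pl; Q[, a] <- q; Tm[, a] <- tv
    ssY[a] <- sum(tv^2) * sum(q^2)
    r2x[a] <- if (ssxTot > 0) 1 - sum(X0^2) / ssxTot else 0
    r2y[a] <- if (ssyTot > 0) 1 - sum(Ys^2) / ssyTot else 0
    actual <- a
  }
  if (actual == 0L) stop("no usable latent component could be extracted")
  if (actual < ncomp) {
    ncomp <- actual
    W <- W[, seq_len(actual), drop = FALSE]
    P <- P[, seq_len(actual), drop = FALSE]
    Q <- Q[, seq_len(actual), drop = FALSE]
    Tm <- Tm[, seq_len(actual), drop = FALSE]
    ssY <- ssY[seq_len(actual)]
    r2x <- r2x[seq_len(actual)]
    r2y <- r2y[seq_len(actual)]
  }

  PW <- crossprod(P, W)
  if (rcond(PW) < 1e-12) {
    # rank-deficient tail (possible under heavy missingness): drop trailing
    # components until the coefficient system is well posed
    while (ncomp > 1 &&
           rcond(crossprod(P[, seq_len(ncomp), drop = FALSE],
                           W[, seq_len(ncomp), drop = FALSE])) < 1e-12)
      ncomp <- ncomp - 1L
    W <- W[, seq_len(ncomp), drop = FALSE]
    P <- P[, seq_len(ncomp), drop = FALSE]
    Q <- Q[, seq_len(ncomp), drop = FALSE]
    Tm <- Tm[, seq_len(ncomp), drop = FALSE]
    ssY <- ssY[seq_len(ncomp)]
    r2x <- r2x[seq_len(ncomp)]
    r2y <- r2y[seq_len(ncomp)]
    PW <- crossprod(P, W)
  }
  B <- W %*% solve(PW, t(Q))

  model <- new("PLSModel", ncomp = ncomp, weights = W, loadingsX = P,
               loadingsY = Q, scores = Tm, coefficients = B,
               xCenter = xs$center, xScale = xs$scale,
               yCenter = ys$center, yScale = ys$scale,
               ssY = ssY, fitted = matrix(0, n, r))
  model@fitted <- predictPLS(model, X)
  attr(model@fitted, "r2x") <- NULL
  model@fitted <- unname(model@fitted) * 1  # plain matrix
  dimnames(model@fitted) <- list(NULL, colnames(Y))
  attr(model, "r2x") <- r2x
  attr(model, "r2y") <- r2y
  model
}

.newScores <- function(model, Xnew) {
  vars <- rownames(model@weights)
  Xnew <- .asMatrix(Xnew, "V")
  extra <- setdiff(colnames(Xnew), vars)
  missing <- setdiff(vars, colnames(Xnew))
  if (length(extra) || length(missing))
    stop("prediction columns must match training variables",
         if (length(missing)) paste0("; missing: ",
                                     paste(head(missing, 5), collapse = ", ")),
         if (length(extra)) paste0("; unknown: ",
                                   paste(head(extra, 5), collapse = ", ")))
  Xnew <- Xnew[, vars, drop = FALSE]
  E <- sweep(sweep(Xnew, 2, model@xCenter), 2, model@xScale, "/")
  M <- !is.na(E)
  E0 <- ifelse(M, E, 0)
  A <- model@ncomp
  Tn <- matrix(0, nrow(E0), A)
  for (a in seq_len(A)) {
    w <- model@weights[, a]
    den <- as.vector(M %*% w^2)
    tv <- as.vector(E0 %*% w)
    tv <- ifelse(den > 0, tv / den, 0)
    E0 <- E0 - (tv %*% t(model@loadingsX[, a])) * M
    Tn[, a] <- tv
  }
  Tn
}

#' Predict responses for new observations
#'
#' Applies the training centering/scaling, estimates component scores
#' sequentially (missing entries contribute through available-data
#' projections), and returns responses on the original scale. A row with no
#' observed entries predicts the training response mean.
#'
#' @param model a \linkS4class{PLSModel}.
#' @param Xnew matrix/data.frame whose columns match the training variables.
#' @param ncomp predict with the first `ncomp` components (default: all).
#' @return n x r matrix of predictions.
#' @export
predictPLS <- function(model, Xnew, ncomp = model@ncomp) {
  Tn <- .newScores(model, Xnew)
  ncomp <- as.integer(ncomp)
  stopifnot(ncomp >= 1, ncomp <= model@ncomp)
  Ysc <- Tn[, seq_len(ncomp), drop = FALSE] %*%
    t(model@loadingsY[, seq_len(ncomp), drop = FALSE])
  out <- sweep(sweep(Ysc, 2, model@yScale, "*"), 2, model@yCenter, "+")
  colnames(out) <- rownames(model@loadingsY)
  out
}

#' @describeIn predictPLS S4 method dispatching on PLSModel.
#' @param object,newdata standard predict arguments.
#' @param ... passed to `predictPLS`.
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
  predictPLS(object, newdata, ...)
})

#' Cross-validated predictive ability (Q2) and fit diagnostics
#'
#' Splits the rows into `folds` deterministic folds (seeded shuffle,
#' round-robin), refits on each training partition and accumulates the
#' prediction error sum of squares of the held-out rows, cumulatively per
#' component: Q2(A) = 1 - PRESS(A)/SS, with residuals measured in
#' full-data unit-variance Y units so multi-response panels weigh their
#' responses comparably.
#'
#' @param X,Y as in [fitPLS()].
#' @param ncomp maximum number of components to evaluate.
#' @param folds number of cross-validation folds (default 7).
#' @param seed seed for the fold shuffle.
#' @param scale see [fitPLS()].
#' @return a \linkS4class{PLSDiagnostics}.
#' @export
q2PLS <- function(X, Y, ncomp, folds = 7L, seed = 1L, scale = TRUE) {
  X <- .asMatrix(X, "V"); Y <- .asMatrix(Y, "Y")
  n <- nrow(X)
  fold <- assignFolds(n, folds, seed)
  ys <- .scaleParams(Y, TRUE)
  ys$scale[!is.finite(ys$scale) | ys$scale == 0] <- 1

  press <- numeric(ncomp)
  ssTot <- 0
  for (f in unique(fold)) {
    test <- fold == f
    Xtr <- X[!test, , drop = FALSE]
    keep <- colSums(!is.na(Xtr)) > 0
    a_f <- min(ncomp, sum(!test) - 1, sum(keep))
    fit <- suppressWarnings(
      fitPLS(Xtr[, keep, drop = FALSE], Y[!test, , drop = FALSE],
             ncomp = a_f, scale = scale))
    vars <- rownames(fit@weights)
    Xte <- X[test, vars, drop = FALSE]
    yMeanTr <- colMeans(Y[!test, , drop = FALSE])
    for (a in seq_len(ncomp)) {
      pred <- if (a <= fit@ncomp) predictPLS(fit, Xte, ncomp = a)
              else predictPLS(fit, Xte, ncomp = fit@ncomp)
      resid <- sweep(Y[test, , drop = FALSE] - pred, 2, ys$scale, "/")
      press[a] <- press[a] + sum(resid^2)
    }
    base <- sweep(sweep(Y[test, , drop = FALSE], 2, yMeanTr), 2, ys$scale, "/")
    ssTot <- ssTot + sum(base^2)
  }
  q2 <- 1 - press / ssTot

  full <- suppressWarnings(fitPLS(X, Y, ncomp = ncomp, scale = scale))
  new("PLSDiagnostics",
      r2x = attr(full, "r2x"), r2y = attr(full, "r2y"),
      q2 = q2, q2Increment = diff(c(0, q2)),
      cvFolds = as.integer(folds), cvSeed = as.integer(seed))
}

#' Choose the number of components by the marginal-Q2 rule
#'
#' Components are added while each one improves cumulative Q2 by more than
#' `minGain` (so a returned model never carries a component with negative
#' marginal Q2), up to min(n-1, p, maxComp).
#'
#' @inheritParams q2PLS
#' @param maxComp hard cap on components (default 10).
#' @param minGain minimal marginal Q2 gain to keep a component (default 0.01).
#' @return list with `ncomp` and the full \linkS4class{PLSDiagnostics}.
#' @export
chooseNcomp <- function(X, Y, folds = 7L, seed = 1L, maxComp = 10L,
                        minGain = 0.01, scale = TRUE) {
  X <- .asMatrix(X, "V")
  cap <- max(1L, min(nrow(X) - 1L, ncol(X), as.integer(maxComp)))
  diag <- q2PLS(X, Y, ncomp = cap, folds = folds, seed = seed, scale = scale)
  a <- 1L
  while (a < cap && diag@q2Increment[a + 1L] > minGain) a <- a + 1L
  list(ncomp = a, diagnostics = diag)
}

#' @describeIn vipScores Variable importance in projection for a fitted
#'   model: VIP_j = sqrt(p * sum_a SS_a w_aj^2 / sum_a SS_a) with unit-norm
#'   per-component weights; mean squared VIP over variables is 1.
#' @export
setMethod("vipScores", "PLSModel", function(object, ...) {
  W <- object@weights
  p <- nrow(W)
  ss <- object@ssY
  wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  v <- sqrt(p * as.vector(wn^2 %*% ss) / sum(ss))
  setNames(v, rownames(W))
})

#' Select variables by VIP cutoff and refit
#'
#' Fits the full model (choosing components by the marginal-Q2 rule when
#' `ncomp` is NULL), keeps variables with VIP strictly above `cutoff`, and
#' refits on the reduced matrix.
#'
#' @inheritParams q2PLS
#' @param cutoff VIP threshold (default 1, the greater-than-average rule).
#' @param ncomp components for the full model; NULL to choose by Q2.
#' @return list with `selected` (variable names), `model` and `diagnostics`
#'   of the refit, and `preModel` / `preDiagnostics` of the all-variable
#'   model.
#' @export
selectAndRefit <- function(X, Y, ncomp = NULL, cutoff = 1, folds = 7L,
                           seed = 1L, scale = TRUE) {
  X <- .asMatrix(X, "V"); Y <- .asMatrix(Y, "Y")
  if (is.null(ncomp)) {
    ch <- chooseNcomp(X, Y, folds = folds, seed = seed, scale = scale)
    ncomp <- ch$ncomp
    preDiag <- ch$diagnostics
  } else {
    preDiag <- q2PLS(X, Y, ncomp = ncomp, folds = folds, seed = seed,
                     scale = scale)
  }
  pre <- suppressWarnings(fitPLS(X, Y, ncomp = ncomp, scale = scale))
  vip <- vipScores(pre)
  selected <- names(vip)[vip > cutoff]
  if (length(selected) == 0)
    stop("no variable has VIP above the cutoff (", cutoff,
         "); consider a lower cutoff")
  Xsel <- X[, selected, drop = FALSE]
  ncomp2 <- min(ncomp, ncol(Xsel))
  reDiag <- q2PLS(Xsel, Y, ncomp = ncomp2, folds = min(folds, nrow(Xsel)),
                  seed = seed, scale = scale)
  refit <- suppressWarnings(fitPLS(Xsel, Y, ncomp = ncomp2, scale = scale))
  list(selected = selected, model = refit, diagnostics = reDiag,
       preModel = pre, preDiagnostics = preDiag, vip = vip)
}
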