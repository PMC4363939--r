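test_that("a response equal to one predictor column is fit perfectly", {
  set.seed(1)
  # centered orthogonal columns so one weight vector isolates the response
  X <- qr.Q(qr(scale(matrix(rnorm(8 * 5), 8, 5), scale = FALSE)))
  colnames(X) <- paste0("g", 1:5)
  m <- fitPLS(X, X[, 2], ncomp = 1)
  expect_equal(attr(m, "r2y"), 1, tolerance = 1e-10)
  expect_equal(as.vector(m@fitted), unname(X[, 2]), tolerance = 1e-8)
})

test_that("score vectors are mutually orthogonal", {
  set.seed(2)
  for (r in c(1, 3)) {
    X <- matrix(rnorm(10 * 20), 10)
    Y <- matrix(rnorm(10 * r), 10)
    m <- fitPLS(X, Y, ncomp = 4)
    G <- crossprod(m@scores)
    expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  }
})

test_that("predictions are invariant to positive rescaling of a column", {
  set.seed(3)
  X <- matrix(rnorm(8 * 10), 8, dimnames = list(NULL, paste0("g", 1:10)))
  y <- rnorm(8)
  m1 <- fitPLS(X, y, ncomp = 2)
  X2 <- X; X2[, 4] <- 100 * X2[, 4]
  m2 <- fitPLS(X2, y, ncomp = 2)
  Xn <- matrix(rnorm(3 * 10), 3, dimnames = list(NULL, paste0("g", 1:10)))
  Xn2 <- Xn; Xn2[, 4] <- 100 * Xn2[, 4]
  expect_equal(predictPLS(m1, Xn), predictPLS(m2, Xn2), tolerance = 1e-8)
})

test_that("predicting the training rows returns the fitted values", {
  fx <- rank1Fixture()
  m <- fitPLS(fx$X, fx$y, ncomp = 1)
  expect_equal(predictPLS(m, fx$X), m@fitted, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(as.vector(m@fitted), fx$y, tolerance = 1e-8)
})

test_that("an all-missing row predicts the training response mean", {
  set.seed(4)
  X <- matrix(rnorm(8 * 6), 8, dimnames = list(NULL, paste0("g", 1:6)))
  Y <- cbind(a = rnorm(8), b = rnorm(8))
  m <- fitPLS(X, Y, ncomp = 2)
  blank <- matrix(NA_real_, 1, 6, dimnames = list(NULL, paste0("g", 1:6)))
  expect_equal(as.vector(predictPLS(m, blank)), unname(colMeans(Y)),
               tolerance = 1e-10)
})

test_that("predictions move linearly along a perturbation of a training row", {
  fx <- rank1Fixture()
  m <- fitPLS(fx$X, fx$y, ncomp = 1)
  base <- fx$X[3, , drop = FALSE]
  dir <- fx$w0 / sqrt(sum(fx$w0^2))
  p0 <- predictPLS(m, base)
  p1 <- predictPLS(m, base + matrix(dir, 1))
  p2 <- predictPLS(m, base + matrix(2 * dir, 1))
  expect_equal(as.vector(p2 - p0), as.vector(2 * (p1 - p0)),
               tolerance = 1e-8)
})

test_that("prediction rejects mismatched variable sets", {
  set.seed(5)
  X <- matrix(rnorm(16), 8, 2, dimnames = list(NULL, c("a", "b")))
  m <- fitPLS(X, rnorm(8), ncomp = 1)
  bad <- matrix(0, 1, 2, dimnames = list(NULL, c("a", "zz")))
  expect_error(predictPLS(m, bad), "zz")
})

test_that("missing cells are tolerated in fitting and prediction", {
  fx <- rank1Fixture(n = 10, p = 12, seed = 6)
  X <- fx$X
  set.seed(7)
  X[sample(length(X), 12)] <- NA
  m <- fitPLS(X, fx$y, ncomp = 1)
  expect_equal(as.vector(m@fitted), fx$y, tolerance = 0.15)
  expect_equal(as.vector(predictPLS(m, fx$X)), fx$y, tolerance = 0.05)
})

test_that("component and fold limits raise errors", {
  set.seed(8)
  X <- matrix(rnorm(5 * 10), 5)
  y <- rnorm(5)
  expect_error(fitPLS(X, y, ncomp = 5), "ncomp")
  expect_error(q2PLS(X, y, ncomp = 1, folds = 6), "folds")
  Xc <- X; Xc[, 3] <- 7
  expect_warning(fitPLS(Xc, y, ncomp = 2), "zero-variance")
})

test_that("leave-one-out Q2 matches a from-first-principles computation", {
  set.seed(9)
  X <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("a", "b")))
  y <- c(1.2, -0.4, 0.9, -2.0)
  got <- q2PLS(X, y, ncomp = 1, folds = 4, seed = 1)

  # independent oracle: explicit single-component PLS per held-out row
  sdAll <- sd(y)
  press <- 0; ss <- 0
  for (i in 1:4) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    xc <- colMeans(Xtr); xs <- apply(Xtr, 2, sd)
    yc <- mean(ytr); ysd <- sd(ytr)
    Xs <- sweep(sweep(Xtr, 2, xc), 2, xs, "/")
    ys <- (ytr - yc) / ysd
    w <- as.vector(crossprod(Xs, ys)); w <- w / sqrt(sum(w^2))
    tt <- as.vector(Xs %*% w)
    q <- sum(tt * ys) / sum(tt^2)
    tNew <- sum((X[i, ] - xc) / xs * w)
    pred <- yc + ysd * q * tNew
    press <- press + ((y[i] - pred) / sdAll)^2
    ss <- ss + ((y[i] - yc) / sdAll)^2
  }
  expect_equal(got@q2, 1 - press / ss, tolerance = 1e-10)
})

test_that("Q2 is perfect on noiseless latent data and null on permuted data", {
  fx <- rank1Fixture()
  expect_gte(q2PLS(fx$X, fx$y, ncomp = 1, seed = 1)@q2[1], 0.99)

  q2s <- vapply(1:30, function(s) {
    set.seed(s)
    X <- matrix(rnorm(8 * 50), 8)
    q2PLS(X, rnorm(8), ncomp = 1, folds = 7, seed = s)@q2[1]
  }, numeric(1))
  expect_lte(mean(q2s), 0)
})

test_that("VIP obeys its algebraic identities", {
  set.seed(10)
  X <- matrix(rnorm(8 * 20), 8, dimnames = list(NULL, paste0("g", 1:20)))
  Y <- cbind(rnorm(8), rnorm(8))
  m <- fitPLS(X, Y, ncomp = 3)
  v <- vipScores(m)
  expect_equal(mean(v^2), 1, tolerance = 1e-8)

  # A = 1, single response: VIP_j = sqrt(p) |w_j| / ||w||
  m1 <- fitPLS(X, Y[, 1], ncomp = 1)
  w <- m1@weights[, 1]
  expect_equal(unname(vipScores(m1)),
               unname(sqrt(20) * abs(w) / sqrt(sum(w^2))), tolerance = 1e-10)

  # brute-force evaluation of the formula from the stored slots
  W <- m@weights; ss <- m@ssY
  brute <- vapply(seq_len(nrow(W)), function(j) {
    num <- sum(ss * (W[j, ]^2 / colSums(W^2)))
    sqrt(nrow(W) * num / sum(ss))
  }, numeric(1))
  expect_equal(unname(v), brute, tolerance = 1e-10)
})

test_that("VIP selection behaves at the cutoff extremes", {
  fx <- plantedMatrix(p = 40, nSignal = 8, seed = 12)
  all_kept <- selectAndRefit(fx$X, fx$y, ncomp = 2, cutoff = 0, seed = 1)
  expect_setequal(all_kept$selected, colnames(fx$X))
  expect_equal(all_kept$model@fitted, all_kept$preModel@fitted,
               tolerance = 1e-6)
  expect_error(selectAndRefit(fx$X, fx$y, ncomp = 2, cutoff = 1e6, seed = 1),
               "cutoff")
})

test_that("marginal-Q2 component choice never keeps a negative increment", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(10 * 15), 10)
    y <- X[, 1] - X[, 2] + rnorm(10, sd = 0.3)
    ch <- chooseNcomp(X, y, seed = s)
    expect_true(all(ch$diagnostics@q2Increment[seq_len(ch$ncomp)][-1] > 0.01) ||
                  ch$ncomp == 1)
  }
})
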