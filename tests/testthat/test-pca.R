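test_that("a rank-1 table is explained exactly by one component", {
  set.seed(1)
  X <- outer(rnorm(12), rnorm(5))
  m <- fitPca(X, k = 1)
  expect_equal(m@r2x[1], 1, tolerance = 1e-10)
  expect_lt(m@residualSsq, 1e-16 * m@totalSsq)
})

test_that("NIPALS agrees with the SVD oracle up to sign", {
  set.seed(23)
  X <- matrix(rnorm(20 * 30), 20, 30)
  m <- fitPca(X, k = 3)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  for (a in 1:3) {
    sgn <- sign(sum(m@loadings[, a] * sv$v[, a]))
    expect_lt(max(abs(m@loadings[, a] - sgn * sv$v[, a])), 1e-6)
    expect_lt(max(abs(m@scores[, a] - sgn * sv$u[, a] * sv$d[a])), 1e-6)
  }
  # r2x equals squared singular values over the total sum of squares
  expect_equal(m@r2x, sv$d[1:3]^2 / sum(sv$d^2), tolerance = 1e-9)
  expect_equal(r2xReport(m)$r2xCum, cumsum(m@r2x), tolerance = 1e-12)
})

test_that("the model reproduces X as mean + T P' + E", {
  set.seed(5)
  X <- matrix(rnorm(15 * 8), 15, 8)
  m <- fitPca(X, k = 3)
  E <- sweep(X, 2, m@center) - m@scores %*% t(m@loadings)
  rec <- sweep(m@scores %*% t(m@loadings) + E, 2, m@center, "+")
  expect_lt(max(abs(rec - X)) / max(abs(X)), 1e-8)
  expect_equal(sum(E^2), m@residualSsq, tolerance = 1e-8)
})

test_that("loadings are orthonormal and scores orthogonal", {
  set.seed(9)
  m <- fitPca(matrix(rnorm(25 * 12), 25, 12), k = 4)
  G <- crossprod(m@loadings)
  expect_lt(max(abs(G - diag(4))), 1e-8)
  Tg <- crossprod(m@scores)
  offdiag <- Tg - diag(diag(Tg))
  expect_lt(max(abs(offdiag)) / max(diag(Tg)), 1e-6)
  # deterministic sign: largest-magnitude loading entry positive
  for (a in 1:4) expect_gt(m@loadings[which.max(abs(m@loadings[, a])), a], 0)
})

test_that("component a+1 equals component 1 of the deflated matrix", {
  set.seed(31)
  X <- matrix(rnorm(18 * 10), 18, 10)
  m <- fitPca(X, k = 2)
  Xc <- sweep(X, 2, colMeans(X))
  X_defl <- Xc - tcrossprod(m@scores[, 1], m@loadings[, 1])
  # refit on the deflated matrix (already centred: deflation preserves
  # column means at zero)
  m2 <- fitPca(X_defl, k = 1)
  expect_lt(max(abs(abs(m2@loadings[, 1]) - abs(m@loadings[, 2]))), 1e-6)
})

test_that("k beyond min(n-1, p) raises a rank error", {
  X <- matrix(rnorm(5 * 3), 5, 3)
  expect_error(fitPca(X, k = 4), "rank error")
  expect_error(fitPca(matrix(rnorm(9), 3, 3), k = 3), "rank error")
})

test_that("DModX is zero for observations in the model plane", {
  set.seed(2)
  # build data exactly in a 2-D plane plus centre
  Tm <- matrix(rnorm(30 * 2), 30, 2)
  P <- qr.Q(qr(matrix(rnorm(6 * 2), 6, 2)))
  X <- Tm %*% t(P)
  m <- fitPca(X, k = 2)
  d <- dmodx(m, X)
  expect_lt(max(d@dmodx), 1e-6)
})

test_that("DModX matches a brute-force residual computation on a hand-built table", {
  X <- matrix(c(1, 2, 3, 4, 5, 6,
                2, 1, 4, 3, 6, 5,
                0.5, 1.5, 2.5, 3.5, 4.5, 5.5,
                3, 2, 5, 4, 7, 6), 6, 4)
  k <- 1L
  m <- fitPca(X, k = k)
  d <- dmodx(m, X)
  # explicit residual matrix from the model equation
  Xc <- sweep(X, 2, colMeans(X))
  E <- Xc - (Xc %*% m@loadings) %*% t(m@loadings)
  n <- nrow(X); p <- ncol(X)
  si <- sqrt(rowSums(E^2) / (p - k))
  s0 <- sqrt(sum(E^2) / ((n - k - 1) * (p - k)))
  expect_equal(d@dmodx, sqrt(n / (n - k - 1)) * si / s0, tolerance = 1e-10)
  expect_equal(d@s0, s0, tolerance = 1e-12)
})

test_that("mean squared DModX over training rows is calibrated to 1", {
  set.seed(77)
  for (dims in list(c(200L, 12L), c(80L, 30L))) {
    X <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    m <- fitPca(X, k = 2)
    d <- dmodx(m, X)
    expect_equal(mean(d@dmodx^2), 1, tolerance = 0.05)
  }
})

test_that("the DModX critical limit behaves like an F quantile", {
  set.seed(3)
  X <- matrix(rnorm(40 * 10), 40, 10)
  m <- fitPca(X, k = 2)
  d05 <- dmodx(m, X, alpha = 0.05)
  d01 <- dmodx(m, X, alpha = 0.01)
  expect_gt(d01@dcrit, d05@dcrit)
  expect_gt(d05@dcrit, 1)
  # most training observations sit inside the 5% limit
  expect_lt(mean(d05@dmodx > d05@dcrit), 0.15)
})

test_that("dmodx refuses degenerate residual space", {
  X <- matrix(rnorm(10 * 2), 10, 2)
  m <- fitPca(X, k = 2)
  expect_error(dmodx(m, X), "degenerate-residual")
})

test_that("scaling flag divides columns by their standard deviation", {
  set.seed(8)
  X <- matrix(rnorm(30 * 5), 30, 5) %*% diag(c(100, 10, 1, 0.1, 0.01))
  m <- fitPca(X, k = 2, scale = TRUE)
  expect_equal(m@scale, apply(X, 2, sd), tolerance = 1e-10)
  sv <- svd(scale(X))
  expect_equal(m@r2x, sv$d[1:2]^2 / sum(sv$d^2), tolerance = 1e-8)
})
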