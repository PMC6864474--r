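test_that("one latent variable recovers a single-direction response", {
  set.seed(21)
  n <- 12; p <- 30
  w <- rnorm(p)
  # rank-one problem: every row proportional to one spectral direction
  t0 <- rnorm(n)
  X1 <- t0 %*% t(w)
  y1 <- 3 * t0 + 5
  m <- fitPLS(X1, y1, 1)
  expect_lt(max(abs(predict(m, X1) - y1)), 1e-10)
})

test_that("full-component PLS on full-rank data equals ordinary least squares", {
  set.seed(22)
  X <- matrix(rnorm(200), 20, 10)
  y <- rnorm(20)
  m <- fitPLS(X, y, 10)
  ols <- lm(y ~ X)
  expect_equal(predict(m, X), unname(fitted(ols)), tolerance = 1e-8)
})

test_that("NIPALS matches the independent Krylov-subspace PLS1 oracle", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(8:20, 1); p <- sample(10:40, 1); k <- sample(1:5, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    m <- fitPLS(X, y, k)
    o <- oracle_pls1(X, y, k)
    Xn <- matrix(rnorm(5 * p), 5, p)
    expect_equal(predict(m, Xn), o$predict(Xn), tolerance = 1e-8)
  }
})

test_that("NIPALS scores are mutually orthogonal", {
  set.seed(24)
  X <- matrix(rnorm(25 * 40), 25, 40)
  y <- rnorm(25)
  m <- fitPLS(X, y, 6)
  Xc <- sweep(X, 2, m@xMean, "-")
  # scores reconstructed through the model's own transformation
  R <- m@weights %*% solve(crossprod(m@xLoadings, m@weights))
  Tm <- Xc %*% R
  G <- crossprod(Tm)
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)) / max(diag(G)), 1e-8)
})

test_that("training error never increases with more components", {
  set.seed(25)
  X <- matrix(rnorm(18 * 25), 18, 25)
  y <- rnorm(18)
  rmsec <- vapply(1:8, function(k) {
    m <- fitPLS(X, y, k)
    sqrt(mean((predict(m, X) - y)^2))
  }, numeric(1))
  expect_true(all(diff(rmsec) <= 1e-10))
})

test_that("predictions are equivariant to constant response shifts", {
  set.seed(26)
  X <- matrix(rnorm(15 * 20), 15, 20)
  y <- rnorm(15)
  m1 <- fitPLS(X, y, 3)
  m2 <- fitPLS(X, y + 7, 3)
  expect_equal(predict(m2, X), predict(m1, X) + 7, tolerance = 1e-10)
})

test_that("the model predicts its own centroid and truncates past the rank", {
  set.seed(27)
  X <- matrix(rnorm(10 * 6), 10, 6)
  y <- rnorm(10)
  m <- fitPLS(X, y, 2)
  expect_equal(predict(m, matrix(m@xMean, 1)), m@yMean, tolerance = 1e-10)
  expect_error(predict(m, X[, 1:3]), "columns")
  expect_warning(fitPLS(X, y, 9), "truncated")
  expect_true(validObject(m))
})

test_that("grouped LOOCV equals the per-fold refit oracle", {
  set.seed(28)
  for (i in 1:5) {
    ns <- sample(5:8, 1)              # samples
    reps <- sample(1:3, 1)
    p <- sample(8:15, 1)
    groups <- rep(sprintf("s%d", seq_len(ns)), each = reps)
    X <- matrix(rnorm(length(groups) * p), ncol = p)
    y <- rnorm(ns)[match(groups, unique(groups))] + rnorm(length(groups), 0, .1)
    got <- suppressWarnings(loocv(X, y, groups, max_lv = 4))
    want <- oracle_loocv(X, y, groups, max_lv = 4)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("LOOCV on noise-free single-factor data is exact at one component", {
  set.seed(29)
  t0 <- rnorm(18)
  w <- rnorm(12)
  X <- t0 %*% t(w)
  y <- 2 * t0 + 1
  groups <- rep(sprintf("s%d", 1:6), each = 3)
  # make replicates within a group identical so the held-out group is spanned
  X <- X[rep(seq(1, 18, by = 3), each = 3), ]
  y <- y[rep(seq(1, 18, by = 3), each = 3)]
  curve <- suppressWarnings(loocv(X, y, groups, max_lv = 2))
  expect_lt(curve[1], 1e-8)
})

test_that("LOOCV input contracts hold", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(loocv(X, rnorm(10), rep(c("a", "b"), 5), 2), "3 groups")
})

test_that("the parsimony rule picks the smallest near-minimal component count", {
  expect_equal(selectLV(c(10, 6, 5.90, 5.88, 5.87), tolerance = 0.02), 3L)
  expect_equal(selectLV(c(9, 8, 7, 6, 5), tolerance = 0), 5L)
  curve <- c(9, 8, 7, 6.5, 5, 6.4, 6.6)
  expect_equal(selectLV(curve, tolerance = 0.02), 5L)
  expect_equal(selectLV(c(3, NA, 2), tolerance = 0), 3L)
  expect_error(selectLV(numeric(0)), "empty")
})
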