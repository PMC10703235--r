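test_that("PLSR matches ordinary least squares at full rank", {
  set.seed(1)
  X <- matrix(rnorm(30 * 5), 30)
  y <- rnorm(30)
  m <- fit_pls(X, y, n_components = 5)
  Xc <- scale(X, scale = FALSE)
  beta <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))
  ols <- Xc %*% beta + mean(y)
  expect_equal(as.numeric(predict(m, X)), as.numeric(ols), tolerance = 1e-8)
})

test_that("a rank-1 linear response is captured by one component", {
  set.seed(2)
  t0 <- rnorm(40)
  X <- t0 %o% c(1, -2, 0.5)
  y <- 3 * t0 + 1
  m <- fit_pls(X, y, n_components = 1)
  expect_equal(as.numeric(predict(m, X)), y, tolerance = 1e-8)
})

test_that("scores are orthogonal and projection is self-consistent", {
  set.seed(3)
  X <- matrix(rnorm(50 * 10), 50)
  y <- rnorm(50)
  m <- fit_pls(X, y, n_components = 5)
  G <- crossprod(m$T)
  off <- max(abs(G - diag(diag(G)))) / max(diag(G))
  expect_lt(off, 1e-8)
  # projecting the training rows reproduces the stored scores
  expect_equal(project(m, X), m$T, tolerance = 1e-10)
  # the training mean maps to the zero score vector
  expect_equal(as.numeric(project(m, matrix(m$center, 1))), rep(0, 5),
               tolerance = 1e-10)
  # linearity: the midpoint of two samples scores at the mean score
  mid <- (X[1, ] + X[2, ]) / 2
  expect_equal(as.numeric(project(m, matrix(mid, 1))),
               as.numeric((m$T[1, ] + m$T[2, ]) / 2), tolerance = 1e-10)
})

test_that("explained variance accumulates to one at full rank", {
  set.seed(4)
  X <- matrix(rnorm(40 * 6), 40)
  y <- rnorm(40)
  m <- fit_pls(X, y, n_components = 6)
  ev <- explained_variance(m)
  expect_equal(tail(ev$x_cum, 1), 1, tolerance = 1e-10)
  expect_true(all(diff(ev$x_cum) >= -1e-12))
  expect_true(all(ev$x >= 0 & ev$x <= 1))
})

test_that("explained variance matches the eigenvalue oracle on an orthogonal design", {
  # orthogonal columns with known norms; y loads only the first column,
  # so component 1 is that column and its X-variance share is d1^2/sum
  n <- 32
  # orthonormal columns that are also mean-centred (orthogonal to 1)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 4), n))))[, 2:5]
  d <- c(5, 3, 2, 1)
  X <- Q %*% diag(d)
  norms2 <- colSums(X^2)
  y <- X[, 1]
  m <- fit_pls(X, y, n_components = 4)
  expect_equal(m$expl_var_x[1], norms2[1] / sum(norms2), tolerance = 1e-8)
})

test_that("component selection finds constructed ranks", {
  set.seed(5)
  # noise-free response from exactly 3 orthogonal latent directions
  Tm <- qr.Q(qr(matrix(rnorm(60 * 3), 60)))
  P <- matrix(rnorm(8 * 3), 8)
  X <- Tm %*% t(P)
  y <- Tm %*% c(2, -1, 0.5)
  sel <- select_components(X, y, cv_scheme(k = 5, seed = 1),
                           max_components = 6, min_explained = 0)
  expect_equal(sel$n_components_unconstrained, 3)

  # y equal to the first column of an orthogonal X: one component already
  # captures essentially all of it (fold-wise recentring leaves a tiny
  # residual that later components mop up, so the strict CV minimum can
  # sit above 1; the one-component CV error must already be negligible)
  Q <- qr.Q(qr(matrix(rnorm(40 * 5), 40)))
  sel2 <- select_components(Q, Q[, 1], cv_scheme(k = 5, seed = 1),
                            max_components = 4, min_explained = 0)
  expect_lt(sel2$cv_mse[1], 0.05 * var(Q[, 1]))
})

test_that("the 1% explained-variance restraint can cap the choice", {
  set.seed(6)
  # strong first direction plus faint informative ones
  n <- 60
  t1 <- rnorm(n); t2 <- rnorm(n); t3 <- rnorm(n)
  X <- cbind(10 * t1, 0.1 * t2, 0.1 * t3, matrix(rnorm(n * 3, sd = 0.05), n))
  y <- t1 + t2 + t3
  sel <- select_components(X, y, cv_scheme(k = 5, seed = 2),
                           max_components = 5, min_explained = 0.01)
  expect_lte(sel$n_components, sel$n_components_unconstrained)
})

test_that("the CV driver equals a hand-rolled leave-one-out loop", {
  set.seed(7)
  X <- matrix(rnorm(12 * 4), 12)
  y <- rnorm(12)
  sel <- select_components(X, y, cv_scheme("LOO"), max_components = 3,
                           min_explained = 0)
  press <- matrix(0, 12, 3)
  for (i in 1:12) {
    m <- fit_pls(X[-i, ], y[-i], n_components = 3)
    for (a in 1:3) {
      Ba <- m$W[, 1:a, drop = FALSE] %*%
        solve(crossprod(m$P[, 1:a, drop = FALSE], m$W[, 1:a, drop = FALSE])) %*%
        t(m$Q[, 1:a, drop = FALSE])
      xc <- (X[i, ] - m$center) / m$scale
      press[i, a] <- (y[i] - (sum(xc * Ba) + m$y_center))^2
    }
  }
  expect_equal(sel$cv_mse, colMeans(press), tolerance = 1e-10)
})

test_that("deflation and prediction behave like a linear model", {
  set.seed(8)
  X <- matrix(rnorm(30 * 6), 30)
  y <- rnorm(30)
  # reconstruction residual norm is nonincreasing in the component count
  res_norm <- sapply(1:5, function(a) {
    m <- fit_pls(X, y, a)
    Xc <- scale(X, scale = FALSE)
    norm(Xc - m$T %*% t(m$P), "F")
  })
  expect_true(all(diff(res_norm) <= 1e-8))
  # adding a constant to Y shifts predictions by that constant
  m1 <- fit_pls(X, y, 3); m2 <- fit_pls(X, y + 10, 3)
  expect_equal(predict(m2, X), predict(m1, X) + 10, tolerance = 1e-8)
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(20), 10)
  expect_error(fit_pls(X, rep(1, 10), 1), "zero variance")
  m <- fit_pls(X, rnorm(10), 1)
  expect_error(project(m, matrix(1, 1, 5)), "feature count")
})
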