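test_that("loading importance highlights the informative feature", {
  set.seed(1)
  # orthogonal design, response carried by feature 1 only
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(40 * 5), 40))))[, 2:6]
  y <- Q[, 1]
  m <- fit_pls(Q, y, 2)
  imp <- loading_importance(m, 1)
  expect_length(imp, 5)
  expect_equal(which.max(imp), 1L)
  expect_lt(max(imp[-1]) / imp[1], 1e-6)
  expect_error(loading_importance(m, 5), "out of range")

  # generic one-informative-feature data
  X <- matrix(rnorm(60 * 8), 60)
  y2 <- 3 * X[, 4] + rnorm(60, sd = 0.01)
  m2 <- fit_pls(X, y2, 1)
  expect_equal(which.max(loading_importance(m2)), 4L)
})

test_that("VarGrad matches its analytic variance on gradient toys", {
  # f = x1^2: gradient 2 x1, variance under N(0, sd^2) noise = 4 sd^2
  registerS3method("input_gradient", "quad_toy",
                   function(object, newdata)
                     cbind(2 * newdata[, 1],
                           matrix(0, nrow(newdata), ncol(newdata) - 1)))
  toy <- structure(list(), class = "quad_toy")
  imp <- vargrad_importance(toy, matrix(0, 1, 4), n_repeats = 1000,
                            noise_sd = 0.1, seed = 1)
  expect_equal(imp[1], 4 * 0.1^2, tolerance = 0.2)
  expect_equal(imp[2:4], rep(0, 3))
  # quadratic scaling in the noise level (4:1 for 2:1 noise)
  imp2 <- vargrad_importance(toy, matrix(0, 1, 4), n_repeats = 1000,
                             noise_sd = 0.2, seed = 1)
  expect_equal(imp2[1] / imp[1], 4, tolerance = 0.4)
})

test_that("VarGrad of a linear network is (numerically) zero", {
  set.seed(2)
  X <- matrix(rnorm(200 * 8), 200)
  y <- X %*% c(2, -1, 0, 0, 1, 0, 0, 0)
  set.seed(2)
  f <- fit_regressor(X, y, regressor_spec("RNN", activation = "linear",
                                          epochs = 150,
                                          epoch_selection = "none"))
  imp <- vargrad_importance(f, X[1:5, ], n_repeats = 50, noise_sd = 0.05)
  expect_lt(max(imp), 1e-8)
  expect_error(vargrad_importance(structure(list(kind = "SVR"),
                                            class = "fitted_regressor"),
                                  X[1:2, ]), "differentiable")
})

test_that("permutation importance isolates used and ignored features", {
  registerS3method("predict", "lin_toy",
                   function(object, newdata, ...) newdata[, 1])
  toy <- structure(list(), class = "lin_toy")
  set.seed(3)
  X <- matrix(rnorm(500 * 4), 500)
  y <- X[, 1]
  imp <- permutation_importance(toy, X, y, n_repeats = 20, seed = 1)
  # permuting the only used feature drives R^2 to about -1: drop of 2
  expect_equal(imp[1], 2, tolerance = 0.15)
  expect_lt(max(abs(imp[2:4])), 0.05)

  # a duplicated informative feature the model ignores scores ~ zero
  X2 <- cbind(X[, 1], X[, 1], X[, 2])
  imp2 <- permutation_importance(toy, X2, y, n_repeats = 20, seed = 1)
  expect_gt(imp2[1], 1.5)
  expect_lt(abs(imp2[2]), 0.05)
})

test_that("permutation importance of pure-noise features centres on zero", {
  # a fitted model whose coefficients touch every feature, scored on
  # held-out rows so noise features centre on zero
  set.seed(4)
  X <- matrix(rnorm(400 * 6), 400)
  y <- X[, 1] + rnorm(400, sd = 0.2)
  m <- fit_pls(X[1:200, ], y[1:200], n_components = 6)
  imp <- permutation_importance(m, X[201:400, ], y[201:400],
                                n_repeats = 30, seed = 2)
  noise_imp <- imp[2:6]
  tt <- t.test(noise_imp, mu = 0)
  expect_gt(tt$p.value, 0.01)
})

test_that("importance report recovers planted spectral signals", {
  # two clusters driven by different planted peaks: 1400 vs 1100 cm-1
  mk <- function(centre_resp, centre_id, seed) {
    make_synthetic_spectra(
      n_samples = 60, n_replicates = 1, n_points = 300,
      peaks = list(list(center = centre_id, width = 25, amplitude = 1),
                   list(center = centre_resp, width = 12,
                        amplitude = function(y) 0.2 + 0.8 * y)),
      multiplicative_range = c(1, 1), baseline_poly_order = -1,
      noise_sd = 0.002, seed = seed)
  }
  d1 <- mk(1400, 1650, 5)
  d2 <- mk(1100, 900, 6)
  X <- rbind(d1$X, d2$X)
  ds <- hc_dataset(X, Y = c(d1$Y, d2$Y), feature_axis = d1$feature_axis)
  truth <- rep(1:2, each = 60)

  check_peaks <- function(map, expected) {
    for (cl in names(expected)) {
      v <- map[map$cluster == cl, ]
      expect_lt(abs(v$feature_axis[which.max(v$raw)] - expected[[cl]]), 20)
    }
  }
  cluster_peak <- function(model) {
    lab <- model$assignment$labels
    sapply(sort(unique(lab)), function(c)
      if (mean(truth[lab == c] == 1) > 0.5) 1400 else 1100)
  }

  specs <- list(PLSR = regressor_spec("PLSR"),
                SVR = regressor_spec("SVR", C_grid = c(0.1, 1, 10, 100)),
                CNN = regressor_spec("CNN", epochs = 300,
                                     epoch_selection = "none"))
  for (kind in names(specs)) {
    set.seed(7)
    m <- fit_hc(ds, specs[[kind]], k = 2, classifiers = "FCM",
                scheme = cv_scheme(k = 3, seed = 1), seed = 7)
    expect_equal(m$k, 2)
    rep_ <- importance_report(m, ds, n_repeats = 10, seed = 1)
    expect_true(all(rep_$normalized >= 0 & rep_$normalized <= 1))
    peaks <- cluster_peak(m)
    check_peaks(rep_, setNames(as.list(peaks), as.character(seq_along(peaks))))
  }
})
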