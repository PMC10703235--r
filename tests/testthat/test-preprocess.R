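test_that("replicate averaging is the arithmetic mean and checks responses", {
  X <- rbind(c(1, 2, 3), c(1, 2, 3), c(2, 4, 6), c(4, 6, 8))
  ds <- hc_dataset(X, Y = c(5, 5, 7, 7), sample_ids = c("a", "a", "b", "b"),
                   replicate_id = c(1, 2, 1, 2))
  avg <- average_replicates(ds)
  expect_equal(nrow(avg$X), 2)
  expect_equal(avg$X[1, ], c(1, 2, 3))      # identical replicates unchanged
  expect_equal(avg$X[2, ], c(3, 5, 7))      # (s + s + delta)/2
  bad <- hc_dataset(X[1:2, ], Y = c(5, 6), sample_ids = c("a", "a"),
                    replicate_id = 1:2)
  expect_error(average_replicates(bad), "differing")
})

test_that("Savitzky-Golay derivative reproduces polynomial derivatives", {
  # constant spectrum -> all zeros
  Xc <- matrix(7, 2, 40)
  expect_equal(max(abs(savgol_derivative(Xc))), 0, tolerance = 1e-10)

  # f(i) = i^2 at unit spacing, 2nd derivative = 2 everywhere (the filter
  # reproduces polynomials up to its order, including at the edges)
  x <- (1:40)^2
  out <- savgol_derivative(matrix(x, 1), feature_axis = 1:40)
  expect_equal(as.numeric(out), rep(2, 40), tolerance = 1e-6)

  # linearity of the filter
  set.seed(1)
  a <- rnorm(40); b <- rnorm(40)
  lhs <- savgol_derivative(matrix(2 * a + 3 * b, 1))
  rhs <- 2 * savgol_derivative(matrix(a, 1)) + 3 * savgol_derivative(matrix(b, 1))
  expect_equal(lhs, rhs, tolerance = 1e-10)

  expect_error(savgol_derivative(matrix(1, 1, 5), window = 11), "window")
})

test_that("EMSC recovers known distortions in closed form", {
  axis <- seq(1800, 700, length.out = 200)
  ref <- exp(-(axis - 1400)^2 / (2 * 40^2)) + 0.4 * exp(-(axis - 1000)^2 / (2 * 60^2))
  lambda <- (axis - mean(range(axis))) / (diff(range(axis)) / 2)

  # the reference itself is a fixed point with a=d=0, b=1
  em <- emsc_correct(matrix(ref, 1), axis, reference = ref)
  expect_equal(as.numeric(em$corrected), ref, tolerance = 1e-10)
  expect_equal(unname(em$coefficients[1, "b"]), 1, tolerance = 1e-10)
  expect_equal(unname(em$coefficients[1, "a"]), 0, tolerance = 1e-10)

  # z = 2 ref + 3 + 0.01 lambda corrects back to the reference
  z <- 2 * ref + 3 + 0.01 * lambda
  em2 <- emsc_correct(matrix(z, 1), axis, reference = ref)
  expect_equal(as.numeric(em2$corrected), ref, tolerance = 1e-10)
  expect_equal(unname(em2$coefficients[1, c("a", "b", "d1")]), c(3, 2, 0.01),
               tolerance = 1e-8)

  # idempotence: correcting corrected spectra changes nothing
  set.seed(2)
  Z <- t(sapply(1:5, function(i)
    runif(1, 0.5, 2) * ref + rnorm(1) + rnorm(1, sd = 0.1) * lambda))
  c1 <- emsc_correct(Z, axis, reference = ref)$corrected
  c2 <- emsc_correct(c1, axis, reference = ref)$corrected
  expect_lt(max(abs(c1 - c2)), 1e-10)

  # near-zero multiplicative coefficient is flagged, not corrected
  flat <- matrix(0.001 * lambda, 1)
  expect_warning(em3 <- emsc_correct(flat, axis, reference = ref), "uncorrected")
  expect_true(em3$flagged[1])
})

test_that("EMSC removes the injected distortions of the spectra generator", {
  ds <- make_synthetic_spectra(n_samples = 6, n_replicates = 2,
                               peaks = list(list(center = 1650, width = 25,
                                                 amplitude = 1)),
                               baseline_poly_order = 2, noise_sd = 0, seed = 2)
  em <- emsc_correct(ds$X, ds$feature_axis, poly_order = 2)
  # all rows share one pure signal; after correction they coincide
  spread <- apply(em$corrected, 2, function(col) diff(range(col)))
  expect_lt(max(spread), 1e-8)
})

test_that("cropping keeps the closed wavenumber interval", {
  axis <- seq(4000, 400, by = -2)
  X <- matrix(rnorm(2 * length(axis)), 2)
  cr <- crop_region(X, axis, 700, 1800)
  expect_equal(ncol(cr$X), 551)
  expect_true(all(cr$feature_axis >= 700 & cr$feature_axis <= 1800))
  # bounds spanning the whole axis are the identity
  cr2 <- crop_region(X, axis, 0, 5000)
  expect_equal(cr2$X, X)
  expect_error(crop_region(X, axis, 1800, 700), "low < high")
})

test_that("centring/scaling round-trips through its statistics", {
  set.seed(3)
  X <- matrix(rnorm(100, sd = 4), 20)
  cs <- center_scale(X, "center")
  expect_lt(max(abs(colMeans(cs$X))), 1e-12)
  cz <- center_scale(X, "center+standardize")
  expect_equal(apply(cz$X, 2, sd), rep(1, 5), tolerance = 1e-12)
  # test rows transformed with train statistics invert exactly
  Xn <- matrix(rnorm(25), 5)
  t1 <- center_scale(Xn, fit_stats = cz$stats)
  expect_equal(uncenter_scale(t1$X, cz$stats), Xn, tolerance = 1e-12)
  # zero-variance column under standardization
  Xz <- cbind(X, 1)
  expect_warning(center_scale(Xz, "center+standardize"), "zero-variance")
})

test_that("a fitted chain re-applies identically to new data", {
  ds <- spectra_fixture(noise_sd = 0.001)
  fc <- fit_chain(ds, crop = c(800, 1700), scaling = "center")
  again <- apply_chain(fc$chain, ds)
  expect_equal(again$X, fc$dataset$X, tolerance = 1e-12)
  expect_equal(again$feature_axis, fc$dataset$feature_axis)
})
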