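test_that("R-squared matches hand computations", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)  # SSE 1, SST 2
  expect_true(is.na(r_squared(rep(1, 3), c(1, 1, 1))))
})

test_that("a one-cluster hierarchy equals the global model exactly", {
  ds <- sim_small()
  sp <- split_train_test(ds, 0.5, seed = 1)
  for (kind in c("PLSR", "SVR", "CNN", "RNN")) {
    spec <- regressor_spec(kind, epochs = 30, epoch_selection = "none",
                           C_grid = c(0.1, 1, 10))
    m <- fit_hc(sp$train, spec, k = 1, scheme = cv_scheme(k = 3, seed = 1),
                seed = 2)
    out <- predict_hc(m, sp$test$X)
    expect_identical(out$predictions, predict(m$global_model, sp$test$X))
    # weighted and closest modes coincide for one cluster
    out_w <- predict_hc(m, sp$test$X, mode = "weighted")
    expect_identical(out$predictions, out_w$predictions)
  }
})

test_that("the hierarchy recovers the simulated clusters and routes consistently", {
  ds <- sim_small()
  sp <- split_train_test(ds, 0.5, seed = 3)
  m <- fit_hc(sp$train, regressor_spec("PLSR"), k = 3,
              scheme = cv_scheme(k = 5, seed = 1), seed = 3)
  expect_gt(rand_index(sp$train$true_cluster, m$assignment$labels), 0.95)
  expect_true(all(tabulate(m$assignment$labels, m$k) >= 10))
  # a training sample re-presented routes to its training cluster
  out <- predict_hc(m, sp$train$X, "FCM")
  expect_gt(mean(out$cluster == m$assignment$labels), 0.99)
  # closest mode: exactly one local model per sample; weighted mode:
  # membership weights sum to one
  expect_true(all(out$cluster %in% seq_len(m$k)))
  U <- fcm_membership(m$fcm_model,
                      sweep(project(m$global_pls, sp$test$X), 2,
                            m$score_scale, "/"))
  expect_equal(rowSums(U), rep(1, nrow(sp$test$X)), tolerance = 1e-9)
  expect_error(predict_hc(m, sp$test$X, "FCM", mode = "weighted"), NA)
})

test_that("weighted prediction requires FCM clustering", {
  ds <- sim_small()
  sp <- split_train_test(ds, 0.5, seed = 4)
  m <- fit_hc(sp$train, regressor_spec("PLSR"), k = 3, clustering = "HAC",
              classifiers = c("LDA", "QDA"),
              scheme = cv_scheme(k = 5, seed = 1), seed = 1)
  expect_false("FCM" %in% names(m$classifiers))
  expect_error(predict_hc(m, sp$test$X, "LDA", mode = "weighted"), "FCM")
})

test_that("a piecewise-linear two-regime toy needs the hierarchy", {
  set.seed(5)
  n <- 120
  x1 <- c(runif(n, 0, 1), runif(n, 10, 11))
  X <- cbind(x1, matrix(rnorm(2 * n * 2, sd = 0.2), 2 * n))
  y <- c(2 * x1[1:n], -3 * x1[(n + 1):(2 * n)] + 40)
  ds <- hc_dataset(X, Y = y)
  sp <- split_train_test(ds, 0.5, seed = 5)
  m <- fit_hc(sp$train, regressor_spec("PLSR"), k = 2,
              scheme = cv_scheme(k = 5, seed = 1), seed = 5)
  rep_ <- evaluate(m, sp$test, classifier = "FCM")
  expect_gt(rep_$r2, 0.999)
  expect_lt(rep_$global_r2, rep_$r2)
})

test_that("the fitted hierarchy is deterministic end to end", {
  ds <- sim_small()
  sp <- split_train_test(ds, 0.5, seed = 6)
  m1 <- fit_hc(sp$train, regressor_spec("PLSR"), k = 3,
               scheme = cv_scheme(k = 5, seed = 2), seed = 7)
  m2 <- fit_hc(sp$train, regressor_spec("PLSR"), k = 3,
               scheme = cv_scheme(k = 5, seed = 2), seed = 7)
  e1 <- evaluate(m1, sp$test, "FCM")
  e2 <- evaluate(m2, sp$test, "FCM")
  expect_identical(e1$r2, e2$r2)
  expect_identical(e1$predictions, e2$predictions)
})

test_that("evaluation reports per-cluster breakdowns that add up", {
  ds <- sim_small()
  sp <- split_train_test(ds, 0.5, seed = 8)
  m <- fit_hc(sp$train, regressor_spec("PLSR"), k = 3,
              scheme = cv_scheme(k = 5, seed = 1), seed = 8)
  rep_ <- evaluate(m, sp$test, "FCM")
  expect_equal(sum(rep_$cluster_sizes), nrow(sp$train$X))
  expect_equal(sum(vapply(rep_$per_cluster, `[[`, numeric(1), "n")),
               nrow(sp$test$X))
  expect_lte(rep_$r2, 1)
})

test_that("cluster-number selection finds three simulated clusters", {
  ds <- simulate_hc_dataset(sim_config(n_samples = 600, seed = 21))
  train <- split_train_test(ds, 0.5, seed = 21)$train
  sel <- select_n_clusters(train, regressor_spec("PLSR"), k_range = 2:5,
                           scheme = cv_scheme(k = 4, seed = 1), seed = 21)
  expect_equal(sel$k_star, 3)
  expect_equal(dim(sel$table), c(4, 5))  # k rows x (4 classifiers + mean)
})

test_that("a homogeneous regime gives a flat selection curve", {
  set.seed(9)
  X <- matrix(rnorm(300 * 6), 300)
  y <- X %*% c(1, -2, 0.5, 0, 0, 0) + rnorm(300, sd = 0.1)
  ds <- hc_dataset(X, Y = y)
  sel <- select_n_clusters(ds, regressor_spec("PLSR"), k_range = 2:4,
                           scheme = cv_scheme(k = 4, seed = 1), seed = 9)
  means <- sel$table[, "mean"]
  expect_lt(diff(range(means, na.rm = TRUE)), 0.05)
})
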