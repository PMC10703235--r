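test_that("FCM basics: k = 1, membership normalization, objective descent", {
  set.seed(1)
  X <- matrix(rnorm(60), 30)
  f1 <- fcm_fit(X, 1)
  expect_true(all(f1$membership == 1))
  expect_equal(as.numeric(f1$centroids), colMeans(X), tolerance = 1e-12)

  f3 <- fcm_fit(X, 3, seed = 2)
  expect_equal(rowSums(f3$membership), rep(1, 30), tolerance = 1e-9)
  expect_true(all(f3$membership >= 0 & f3$membership <= 1))
  expect_true(all(diff(f3$objective) <= 1e-8))
})

test_that("FCM separates far blobs with near-crisp memberships", {
  tb <- two_blobs(sep = 50)
  f <- fcm_fit(tb$X, 2, seed = 1)
  own <- apply(f$membership, 1, max)
  expect_true(all(own > 0.99))
  lab <- fcm_assignment(f)$labels
  expect_equal(rand_index(tb$labels, lab), 1)
})

test_that("FCM agrees with the e1071 reference implementation on blobs", {
  tb <- two_blobs(sep = 30, seed = 9)
  f <- fcm_fit(tb$X, 2, seed = 1)
  set.seed(1)
  ref <- e1071::cmeans(tb$X, 2, m = 2)
  expect_equal(rand_index(fcm_assignment(f)$labels, ref$cluster), 1)
  # centroids coincide up to cluster order
  d <- sq_dist_test(f$centroids, ref$centers)
  expect_lt(min(d[1, ]) + min(d[2, ]), 1e-4)
})

test_that("membership prediction honours the model geometry", {
  tb <- two_blobs(sep = 20, seed = 2)
  f <- fcm_fit(tb$X, 2, seed = 1)
  # a centroid itself gets membership one
  u <- fcm_membership(f, f$centroids[1, , drop = FALSE])
  expect_equal(as.numeric(u), c(1, 0), tolerance = 1e-12)
  # a point equidistant from both centroids splits 50/50
  mid <- colMeans(f$centroids)
  expect_equal(as.numeric(fcm_membership(f, matrix(mid, 1))), c(0.5, 0.5),
               tolerance = 1e-9)
  # training rows keep their crisp labels
  lab2 <- max.col(fcm_membership(f, tb$X))
  expect_equal(lab2, fcm_assignment(f)$labels)
  expect_error(fcm_membership(f, matrix(0, 1, 5)), "dimension")
})

test_that("FCM near the crisp limit agrees with k-means", {
  tb <- two_blobs(sep = 10, seed = 3)
  f <- fcm_fit(tb$X, 2, fuzzifier = 1.05, seed = 1)
  set.seed(1)
  km <- kmeans(tb$X, 2, nstart = 10)
  expect_gte(rand_index(fcm_assignment(f)$labels, km$cluster), 0.99)
})

test_that("FCM crisp labels are invariant under rotation of the score space", {
  tb <- two_blobs(sep = 25, seed = 5)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  f1 <- fcm_fit(tb$X, 2, seed = 1)
  f2 <- fcm_fit(tb$X %*% R, 2, seed = 1)
  expect_equal(rand_index(fcm_assignment(f1)$labels,
                          fcm_assignment(f2)$labels), 1)
})

test_that("HAC and spectral clustering recover exact partitions", {
  tb <- two_blobs(sep = 50, seed = 6)
  for (meth in c("HAC", "SPC")) {
    a <- alt_cluster(tb$X, 2, meth, seed = 1)
    expect_equal(rand_index(tb$labels, a$labels), 1)
    expect_true(all(rowSums(a$membership) == 1))
    expect_true(all(a$membership %in% c(0, 1)))
  }
  # HAC with k = n puts every sample in its own cluster
  Xs <- matrix(rnorm(12), 6)
  a_n <- alt_cluster(Xs, 6, "HAC")
  expect_equal(sort(unique(a_n$labels)), 1:6)
  expect_error(alt_cluster(Xs, 7, "HAC"), "exceed")
})

test_that("spectral clustering splits disconnected affinity components", {
  # two groups so remote that the Gaussian affinity is block-diagonal;
  # the graph components are the oracle partition
  set.seed(7)
  X <- rbind(matrix(rnorm(20, sd = 0.1), 10), matrix(rnorm(20, 500, 0.1), 10))
  a <- alt_cluster(X, 2, "SPC", seed = 1)
  expect_equal(rand_index(rep(1:2, each = 10), a$labels), 1)
})

test_that("small-cluster reassignment follows the membership rule", {
  # all clusters already large enough: identity
  lab <- rep(1:3, each = 20)
  U <- matrix(0, 60, 3); U[cbind(1:60, lab)] <- 1
  a <- cluster_assignment(lab, U, "FCM")
  r <- reassign_small_clusters(a, 10)
  expect_equal(r$labels, lab)
  expect_equal(r$k, 3)

  # hand-traced case: sizes (30, 30, 4); the 4 undersized samples move to
  # their second-best cluster (cluster 2 by construction), k drops to 2
  lab2 <- c(rep(1L, 30), rep(2L, 30), rep(3L, 4))
  U2 <- matrix(0.05, 64, 3)
  U2[cbind(1:64, lab2)] <- 0.9
  U2[61:64, 2] <- 0.3; U2[61:64, 1] <- 0.1   # second-best is cluster 2
  U2 <- U2 / rowSums(U2)
  a2 <- cluster_assignment(lab2, U2, "FCM")
  r2 <- reassign_small_clusters(a2, 10)
  expect_equal(r2$k, 2)
  expect_equal(r2$labels[61:64], rep(2L, 4))
  expect_true(all(tabulate(r2$labels, r2$k) >= 10))

  # cascade: sizes (12, 9, 9) terminates with all survivors >= 10
  lab3 <- c(rep(1L, 12), rep(2L, 9), rep(3L, 9))
  set.seed(8)
  U3 <- matrix(runif(30 * 3), 30); U3[cbind(1:30, lab3)] <- 2
  U3 <- U3 / rowSums(U3)
  a3 <- cluster_assignment(lab3, U3, "FCM")
  r3 <- reassign_small_clusters(a3, 10)
  expect_true(all(tabulate(r3$labels, r3$k) >= 10))

  # fewer samples than the minimum collapses to one cluster with warning
  expect_warning(r4 <- reassign_small_clusters(
    cluster_assignment(1:3, diag(3), "FCM"), 10), "single cluster")
  expect_equal(r4$k, 1)
})

test_that("reassignment is monotone over random memberships", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(25:60, 1); k <- sample(2:5, 1)
    U <- matrix(runif(n * k), n); U <- U / rowSums(U)
    lab <- max.col(U)
    r <- reassign_small_clusters(cluster_assignment(lab, U, "FCM"), 10)
    expect_true(all(tabulate(r$labels, r$k) >= 10) || r$k == 1)
    expect_lte(r$k, k)
  }
})
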