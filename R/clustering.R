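#' Fuzzy c-means and alternative cluster assigners
#'
#' Clustering of global PLS X-scores: fuzzy c-means (FCM) with Euclidean
#' distance as the primary method, Ward-linkage hierarchical agglomerative
#' clustering (HAC) and normalized-cuts spectral clustering (SPC) as
#' crisp alternatives, plus the rule that reassigns members of clusters
#' smaller than a minimum size by their membership probabilities.
#'
#' @name clustering
NULL

fcm_update_membership <- function(D2, m) {
  # D2: n x k squared Euclidean distances; returns membership rows
  n <- nrow(D2); k <- ncol(D2)
  U <- matrix(0, n, k)
  expo <- 1 / (m - 1)
  zero_hit <- D2 < 1e-300
  any_zero <- rowSums(zero_hit) > 0
  for (i in which(any_zero)) U[i, ] <- zero_hit[i, ] / sum(zero_hit[i, ])
  idx <- which(!any_zero)
  if (length(idx)) {
    Dm <- D2[idx, , drop = FALSE]^expo
    U[idx, ] <- (1 / Dm) / rowSums(1 / Dm)
  }
  U
}

sq_dist <- function(X, V) {
  # squared Euclidean distances between rows of X and rows of V
  outer(rowSums(X^2), rep(1, nrow(V))) +
    outer(rep(1, nrow(X)), rowSums(V^2)) - 2 * X %*% t(V)
}

fcm_single <- function(X, k, m, tol, max_iter) {
  n <- nrow(X)
  # random initial membership rows (Dirichlet-uniform)
  U <- matrix(runif(n * k), n, k)
  U <- U / rowSums(U)
  obj <- numeric(0)
  converged <- FALSE
  V <- NULL
  for (it in seq_len(max_iter)) {
    Um <- U^m
    V <- crossprod(Um, X) / colSums(Um)
    D2 <- pmax(sq_dist(X, V), 0)
    U_new <- fcm_update_membership(D2, m)
    obj <- c(obj, sum(U_new^m * D2))
    delta <- max(abs(U_new - U))
    U <- U_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(centroids = V, membership = U, objective = obj, converged = converged)
}

#' Fit fuzzy c-means
#'
#' Alternating optimisation of centroids and memberships with Euclidean
#' distance: `u_ik = 1 / sum_j (d_ik/d_ij)^(2/(m-1))` and
#' `v_k = sum_i u_ik^m x_i / sum_i u_ik^m`, stopping when the largest
#' membership change falls below `tol`.  Runs `n_restarts` seeded random
#' initialisations and keeps the lowest-objective fit.
#'
#' @param scores numeric matrix (samples x score dimensions).
#' @param k number of clusters.
#' @param fuzzifier fuzziness exponent `m > 1` (Bezdek default 2).
#' @param tol convergence threshold on `max |dU|`.
#' @param max_iter iteration cap per restart.
#' @param n_restarts random restarts.
#' @param seed integer seed.
#' @return object of class `fcm_model` with `centroids`, `membership`,
#'   `fuzzifier`, `objective` (per-iteration trace of the kept restart),
#'   `converged`, `seed`.
#' @export
fcm_fit <- function(scores, k, fuzzifier = 2, tol = 1e-6, max_iter = 300,
                    n_restarts = 10, seed = 1L) {
  X <- as.matrix(scores)
  if (k < 1) stop("k must be >= 1")
  if (nrow(X) < k) stop("need at least k samples")
  if (fuzzifier <= 1) stop("fuzzifier must be > 1")
  if (k == 1) {
    return(structure(list(centroids = matrix(colMeans(X), 1),
                          membership = matrix(1, nrow(X), 1),
                          fuzzifier = fuzzifier, objective = 0,
                          converged = TRUE, seed = seed),
                     class = "fcm_model"))
  }
  best <- NULL
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    fit <- fcm_single(X, k, fuzzifier, tol, max_iter)
    if (is.null(best) || min(fit$objective) < min(best$objective)) best <- fit
  }
  structure(list(centroids = best$centroids, membership = best$membership,
                 fuzzifier = fuzzifier, objective = best$objective,
                 converged = best$converged, seed = seed),
            class = "fcm_model")
}

#' @export
print.fcm_model <- function(x, ...) {
  cat(sprintf("<fcm_model> k=%d, m=%.2f, %sconverged in %d iterations\n",
              ncol(x$membership), x$fuzzifier,
              if (x$converged) "" else "NOT ", length(x$objective)))
  invisible(x)
}

#' Membership of new points under a fitted FCM model
#'
#' Evaluates the FCM membership formula at the fixed centroids.  A point
#' coinciding with a centroid gets membership 1 for that centroid.
#'
#' @param model an `fcm_model`.
#' @param new_scores matrix of points in the same score space.
#' @return membership matrix (rows sum to 1).
#' @export
fcm_membership <- function(model, new_scores) {
  X <- as.matrix(new_scores)
  if (ncol(X) != ncol(model$centroids))
    stop("score dimension does not match the model")
  D2 <- pmax(sq_dist(X, model$centroids), 0)
  fcm_update_membership(D2, model$fuzzifier)
}

#' Cluster assignment container
#' @param labels integer crisp labels in `1..k`.
#' @param membership n x k membership matrix (one-hot for crisp methods).
#' @param method one of `"FCM"`, `"HAC"`, `"SPC"`.
#' @return object of class `cluster_assignment`.
#' @export
cluster_assignment <- function(labels, membership, method) {
  membership <- as.matrix(membership)
  stopifnot(length(labels) == nrow(membership))
  structure(list(labels = as.integer(labels), membership = membership,
                 method = method, k = ncol(membership)),
            class = "cluster_assignment")
}

#' Crisp labels from an FCM model
#' @param model an `fcm_model`.
#' @return `cluster_assignment` with argmax labels.
#' @export
fcm_assignment <- function(model) {
  cluster_assignment(max.col(model$membership, ties.method = "first"),
                     model$membership, "FCM")
}

# soft memberships for crisp partitions: normalized inverse distances
# to cluster centroids (used by the reassignment rule)
soft_membership_from_labels <- function(X, labels) {
  ks <- sort(unique(labels))
  V <- t(vapply(ks, function(k) colMeans(X[labels == k, , drop = FALSE]),
                numeric(ncol(X))))
  D2 <- pmax(sq_dist(X, V), 0)
  fcm_update_membership(D2, 2)
}

#' Alternative crisp clustering (HAC / spectral)
#'
#' HAC: Ward linkage on Euclidean distance, cut at `k` clusters.
#' SPC: Gaussian affinity with bandwidth equal to the median pairwise
#' distance, symmetric-normalized Laplacian embedding (first `k`
#' eigenvectors, row-normalized), k-means on the embedding.
#'
#' @param scores numeric matrix.
#' @param k number of clusters (`>= 2`).
#' @param method `"HAC"` or `"SPC"`.
#' @param seed seed (k-means inside SPC).
#' @return `cluster_assignment` with one-hot memberships plus
#'   distance-derived soft memberships in `$soft_membership`.
#' @export
alt_cluster <- function(scores, k, method = c("HAC", "SPC"), seed = 1L) {
  X <- as.matrix(scores)
  method <- match.arg(method)
  if (k < 2) stop("k must be >= 2 for crisp alternatives")
  if (k > nrow(X)) stop("k cannot exceed the sample count")
  if (method == "HAC") {
    labels <- cutree(hclust(dist(X), method = "ward.D2"), k = k)
  } else {
    D <- as.matrix(dist(X))
    sigma <- median(D[upper.tri(D)])
    if (sigma == 0) sigma <- 1
    A <- exp(-D^2 / (2 * sigma^2))
    diag(A) <- 0
    ddeg <- pmax(rowSums(A), 1e-12)
    L <- diag(nrow(A)) - sweep(sweep(A, 1, sqrt(ddeg), "/"), 2, sqrt(ddeg), "/")
    ev <- eigen(L, symmetric = TRUE)
    emb <- ev$vectors[, ncol(ev$vectors) - seq_len(k) + 1, drop = FALSE]
    norms <- sqrt(rowSums(emb^2)); norms[norms == 0] <- 1
    emb <- emb / norms
    set.seed(seed)
    labels <- kmeans(emb, centers = k, nstart = 10)$cluster
  }
  onehot <- matrix(0, nrow(X), k)
  onehot[cbind(seq_len(nrow(X)), labels)] <- 1
  out <- cluster_assignment(labels, onehot, method)
  out$soft_membership <- soft_membership_from_labels(X, labels)
  out
}

#' Reassign members of undersized clusters
#'
#' Iteratively moves each member of a cluster with fewer than `min_size`
#' samples to its highest-membership cluster among those that meet
#' `min_size`, until every surviving cluster has at least `min_size`
#' members.  Emptied clusters are dropped and labels are compacted to
#' `1..k'`.
#'
#' @param assignment a `cluster_assignment` (or `fcm_model`).
#' @param min_size minimum cluster size (default 10).
#' @return updated `cluster_assignment`; `$kept_clusters` maps new labels
#'   to original ones.
#' @export
reassign_small_clusters <- function(assignment, min_size = 10) {
  if (inherits(assignment, "fcm_model")) assignment <- fcm_assignment(assignment)
  U <- if (!is.null(assignment$soft_membership)) assignment$soft_membership
       else assignment$membership
  labels <- assignment$labels
  n <- length(labels); k <- ncol(U)
  if (n < min_size) {
    warning("fewer samples than min_size; returning a single cluster")
    return(cluster_assignment(rep(1L, n), matrix(1, n, 1), assignment$method))
  }
  alive <- seq_len(k)
  repeat {
    sizes <- vapply(alive, function(c) sum(labels == c), integer(1))
    small <- alive[sizes > 0 & sizes < min_size]
    if (!length(small)) break
    # process the smallest undersized cluster first
    c_small <- small[which.min(vapply(small, function(c) sum(labels == c),
                                      integer(1)))]
    dest_ok <- alive[alive != c_small &
                       vapply(alive, function(c) sum(labels == c),
                              integer(1)) >= min_size]
    if (!length(dest_ok)) {
      # no cluster is large enough: fall back to the largest other cluster
      others <- alive[alive != c_small]
      if (!length(others)) break
      sz <- vapply(others, function(c) sum(labels == c), integer(1))
      dest_ok <- others[which.max(sz)]
    }
    for (i in which(labels == c_small)) {
      labels[i] <- dest_ok[which.max(U[i, dest_ok])]
    }
    alive <- alive[vapply(alive, function(c) sum(labels == c) > 0, logical(1))]
  }
  kept <- sort(unique(labels))
  new_labels <- match(labels, kept)
  U_new <- U[, kept, drop = FALSE]
  U_new <- U_new / rowSums(U_new)
  out <- cluster_assignment(new_labels, U_new, assignment$method)
  out$kept_clusters <- kept
  out
}
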