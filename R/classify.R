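#' Cluster-membership classifiers on X-scores
#'
#' Gaussian discriminant classifiers (LDA: pooled covariance, QDA:
#' per-class covariance, NB: per-class diagonal covariance) and the FCM
#' membership rule, all predicting the cluster of a new sample from its
#' projected global X-scores.
#'
#' @name cluster_classify
NULL

ridge_if_singular <- function(S, dim) {
  # regularize a (near-)singular covariance by a small diagonal bump
  ok <- tryCatch({ solve(S); TRUE }, error = function(e) FALSE)
  if (!ok || min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 1e-12) {
    warning("singular covariance; ridge-regularized")
    S <- S + diag(1e-8 * sum(diag(S)) / dim, dim)
  }
  S
}

#' Fit a cluster classifier
#'
#' @param scores training X-scores (n x A).
#' @param labels integer cluster labels in `1..k`.
#' @param method `"LDA"`, `"QDA"`, `"NB"` or `"FCM"`.
#' @param fcm_model required when `method = "FCM"`: the `fcm_model` whose
#'   memberships define the rule (only valid when clustering was FCM).
#' @return object of class `cluster_classifier`.
#' @export
fit_classifier <- function(scores, labels, method = c("LDA", "QDA", "NB", "FCM"),
                           fcm_model = NULL) {
  method <- match.arg(method)
  X <- as.matrix(scores)
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  if (method == "FCM") {
    if (is.null(fcm_model))
      stop("FCM classification requires the fitted fcm_model (FCM clustering only)")
    return(structure(list(method = "FCM", fcm_model = fcm_model,
                          classes = seq_len(ncol(fcm_model$membership))),
                     class = "cluster_classifier"))
  }
  if (length(classes) < 2) stop("need at least 2 classes")
  A <- ncol(X)
  means <- list(); covs <- list(); priors <- numeric(length(classes))
  pooled <- matrix(0, A, A)
  for (j in seq_along(classes)) {
    idx <- labels == classes[j]
    if (sum(idx) < 2 && method != "NB")
      stop("covariance-based classifiers need >= 2 samples per class")
    Xi <- X[idx, , drop = FALSE]
    means[[j]] <- colMeans(Xi)
    priors[j] <- mean(idx)
    S <- if (nrow(Xi) > 1) cov(Xi) else diag(1e-8, A)
    covs[[j]] <- S
    pooled <- pooled + S * (nrow(Xi) - 1)
  }
  pooled <- pooled / (nrow(X) - length(classes))
  if (method == "LDA") {
    pooled <- ridge_if_singular(pooled, A)
    covs <- NULL
  } else if (method == "QDA") {
    covs <- lapply(covs, ridge_if_singular, dim = A)
  } else {  # NB: diagonal per-class variances
    covs <- lapply(covs, function(S) {
      v <- diag(as.matrix(S))
      v[v < 1e-12] <- max(1e-12, 1e-8 * mean(v))
      v
    })
  }
  structure(list(method = method, classes = classes, means = means,
                 covs = covs, pooled = if (method == "LDA") pooled,
                 priors = priors),
            class = "cluster_classifier")
}

log_gauss_density <- function(X, mu, S) {
  # multivariate normal log-density for rows of X
  A <- length(mu)
  Xc <- sweep(X, 2, mu)
  if (is.matrix(S)) {
    ch <- chol(S)
    z <- Xc %*% chol2inv(ch) * Xc
    -0.5 * rowSums(z) - sum(log(diag(ch))) - 0.5 * A * log(2 * pi)
  } else {  # diagonal variances
    -0.5 * rowSums(sweep(Xc^2, 2, S, "/")) - 0.5 * sum(log(S)) -
      0.5 * A * log(2 * pi)
  }
}

#' Predict cluster labels for new scores
#'
#' @param classifier a `cluster_classifier`.
#' @param new_scores matrix of projected X-scores.
#' @return list with `labels` (argmax) and `posterior` (rows sum to 1;
#'   FCM memberships for the FCM rule).
#' @export
predict_cluster <- function(classifier, new_scores) {
  X <- as.matrix(new_scores)
  if (classifier$method == "FCM") {
    post <- fcm_membership(classifier$fcm_model, X)
  } else {
    k <- length(classifier$classes)
    logp <- matrix(0, nrow(X), k)
    for (j in seq_len(k)) {
      S <- if (classifier$method == "LDA") classifier$pooled
           else classifier$covs[[j]]
      logp[, j] <- log(classifier$priors[j]) +
        log_gauss_density(X, classifier$means[[j]], S)
    }
    logp <- logp - apply(logp, 1, max)
    post <- exp(logp) / rowSums(exp(logp))
  }
  labels <- max.col(post, ties.method = "first")
  if (classifier$method != "FCM")
    labels <- classifier$classes[labels]
  list(labels = labels, posterior = post)
}

#' Best label-permutation match between two partitions
#'
#' Finds the relabelling of `pred` maximizing agreement with `ref`
#' (exhaustive over permutations for k <= 7, greedy above).
#'
#' @param ref,pred integer label vectors of equal length.
#' @return list with `accuracy` and the permutation `map` (index = pred
#'   label, value = matched ref label).
#' @export
match_labels <- function(ref, pred) {
  kr <- max(ref); kp <- max(pred)
  k <- max(kr, kp)
  overlap <- matrix(0, k, k)
  for (i in seq_along(ref)) overlap[pred[i], ref[i]] <- overlap[pred[i], ref[i]] + 1
  if (k <= 7) {
    perms <- permutations_of(k)
    best <- 0; best_map <- seq_len(k)
    for (r in seq_len(nrow(perms))) {
      s <- sum(overlap[cbind(seq_len(k), perms[r, ])])
      if (s > best) { best <- s; best_map <- perms[r, ] }
    }
  } else {
    best_map <- integer(k); taken <- logical(k); ord <- order(-apply(overlap, 1, max))
    for (i in ord) {
      cand <- order(-overlap[i, ])
      j <- cand[!taken[cand]][1]
      best_map[i] <- j; taken[j] <- TRUE
    }
    best <- sum(overlap[cbind(seq_len(k), best_map)])
  }
  list(accuracy = best / length(ref), map = best_map)
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1))
  sub <- permutations_of(k - 1)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    right <- if (pos <= k - 1) sub[, pos:(k - 1), drop = FALSE] else NULL
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], k, right)
    out <- rbind(out, block)
  }
  out
}

#' Cross-validated cluster-classification accuracy
#'
#' For each CV fold: refit the global PLS model and the clustering on the
#' kept-in samples, fit each classifier, project the kept-out samples and
#' classify them; agreement is measured against the full-data cluster
#' labels after best-permutation label matching.
#'
#' @param X,Y training data.
#' @param k number of clusters.
#' @param methods classifier methods to evaluate.
#' @param scheme a [cv_scheme()].
#' @param n_components PLS components (selected by CV when `NULL`).
#' @param seed seed for clustering restarts.
#' @return data.frame with per-method CV accuracy.
#' @export
cv_classification_accuracy <- function(X, Y, k,
                                       methods = c("FCM", "LDA", "QDA", "NB"),
                                       scheme = cv_scheme(k = 5),
                                       n_components = NULL, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (is.null(n_components))
    n_components <- select_components(X, Y, scheme)$n_components
  full_pls <- fit_pls(X, Y, n_components)
  unit_scores <- function(m) sweep(m$T, 2, sqrt(colSums(m$R^2)), "/")
  full_fcm <- fcm_fit(unit_scores(full_pls), k, seed = seed)
  full_labels <- fcm_assignment(full_fcm)$labels
  folds <- cv_folds(scheme, n)
  hits <- setNames(numeric(length(methods)), methods)
  tried <- setNames(numeric(length(methods)), methods)
  for (f in sort(unique(folds))) {
    out_idx <- which(folds == f); in_idx <- which(folds != f)
    pls_f <- fit_pls(X[in_idx, , drop = FALSE], Y[in_idx, , drop = FALSE],
                     n_components)
    sc_f <- unit_scores(pls_f)
    fcm_f <- fcm_fit(sc_f, k, seed = seed)
    lab_f <- fcm_assignment(fcm_f)$labels
    if (length(unique(lab_f)) < k) {
      warning(sprintf("fold %d lost a cluster; skipped", f))
      next
    }
    mp <- match_labels(full_labels[in_idx], lab_f)
    scores_out <- sweep(project(pls_f, X[out_idx, , drop = FALSE]), 2,
                        sqrt(colSums(pls_f$R^2)), "/")
    for (meth in methods) {
      clf <- fit_classifier(sc_f, lab_f, meth, fcm_model = fcm_f)
      pred <- predict_cluster(clf, scores_out)$labels
      mapped <- mp$map[pred]
      hits[meth] <- hits[meth] + sum(mapped == full_labels[out_idx])
      tried[meth] <- tried[meth] + length(out_idx)
    }
  }
  data.frame(method = methods, accuracy = as.numeric(hits / pmax(tried, 1)),
             row.names = NULL)
}
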