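#' Per-cluster feature importance
#'
#' Three complementary importance measures over the feature axis:
#' PLS X-loadings (linear models), VarGrad input-gradient variance
#' (networks) and permutation importance (any regressor), plus a
#' report that assembles one map per local model and the global model.
#'
#' @name importance
NULL

#' PLS loading importance
#'
#' Absolute X-loadings of one component, the direct linear measure of
#' which features carry the explained response variation.
#'
#' @param model a `pls_model` (or PLSR `fitted_regressor`).
#' @param component component index (default 1).
#' @return nonnegative numeric vector, length = feature count.
#' @export
loading_importance <- function(model, component = 1) {
  if (inherits(model, "fitted_regressor")) {
    if (model$kind != "PLSR") stop("loading importance requires a PLSR model")
    model <- model$fit
  }
  stopifnot(inherits(model, "pls_model"))
  if (component < 1 || component > model$n_components)
    stop("component out of range")
  abs(model$P[, component])
}

#' VarGrad importance
#'
#' Adds small Gaussian noise to reference inputs, computes the gradient
#' of the network output with respect to each input feature for every
#' noisy copy, and reports the per-feature variance of those gradients
#' (averaged over reference samples).  Features with strongly non-linear
#' influence have gradients that vary under the noise; features the
#' network is linear in (or ignores) have near-zero gradient variance.
#'
#' @param object a differentiable regressor (CNN/RNN `fitted_regressor`,
#'   or anything with an [input_gradient()] method).
#' @param X_ref reference samples (matrix, rows).
#' @param n_repeats noisy copies per reference sample (>= 2).
#' @param noise_sd noise standard deviation on the standardized input
#'   scale (default 0.05).
#' @param seed integer seed.
#' @return nonnegative importance vector, length = feature count.
#' @export
vargrad_importance <- function(object, X_ref, n_repeats = 200,
                               noise_sd = 0.05, seed = 1L) {
  X_ref <- as.matrix(X_ref)
  if (n_repeats < 2) stop("n_repeats must be >= 2")
  if (inherits(object, "fitted_regressor") &&
      !object$kind %in% c("CNN", "RNN"))
    stop("VarGrad requires a differentiable network regressor")
  n <- nrow(X_ref); p <- ncol(X_ref)
  # noise is applied on the standardized input scale when available
  x_scale <- if (inherits(object, "fitted_regressor") &&
                 !is.null(object$x_stats)) object$x_stats$scale else rep(1, p)
  set.seed(seed)
  total <- rep(0, p)
  for (i in seq_len(n)) {
    base <- X_ref[rep(i, n_repeats), , drop = FALSE]
    noise <- matrix(rnorm(n_repeats * p, sd = noise_sd), n_repeats, p)
    G <- input_gradient(object, base + sweep(noise, 2, x_scale, "*"))
    total <- total + apply(G, 2, var)
  }
  total / n
}

#' Permutation importance
#'
#' Importance of feature `j` is the mean drop in R-squared when column
#' `j` is randomly permuted, over `n_repeats` permutations.
#'
#' @param object any fitted regressor with a `predict` method.
#' @param X,y evaluation data (held-out data when available).
#' @param n_repeats permutations per feature.
#' @param seed integer seed.
#' @return numeric importance vector (can be slightly negative for
#'   uninformative features by Monte-Carlo error).
#' @export
permutation_importance <- function(object, X, y, n_repeats = 10, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) < 3) stop("need at least 3 samples")
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  baseline <- r_squared(y, predict(object, X))
  set.seed(seed)
  p <- ncol(X)
  imp <- numeric(p)
  for (j in seq_len(p)) {
    drop_sum <- 0
    for (r in seq_len(n_repeats)) {
      Xp <- X
      Xp[, j] <- X[sample.int(nrow(X)), j]
      drop_sum <- drop_sum + (baseline - r_squared(y, predict(object, Xp)))
    }
    imp[j] <- drop_sum / n_repeats
  }
  imp
}

default_importance_method <- function(kind) {
  switch(kind, PLSR = "loadings", CNN = "vargrad", RNN = "vargrad",
         SVR = "permutation")
}

importance_for <- function(object, method, X, y, n_repeats, noise_sd, seed) {
  switch(method,
         loadings = loading_importance(object),
         vargrad = vargrad_importance(object, X, n_repeats = max(n_repeats, 2),
                                      noise_sd = noise_sd, seed = seed),
         permutation = permutation_importance(object, X, y,
                                              n_repeats = n_repeats,
                                              seed = seed),
         stop("unknown importance method: ", method))
}

#' Importance report for a hierarchical model
#'
#' Computes one importance map per local model plus the global model,
#' using the method matched to the learner kind by default (loadings for
#' PLSR, VarGrad for CNN/RNN, permutation for SVR).  Maps are min-max
#' normalized per model for display next to the cluster mean spectra.
#'
#' @param model an `hc_model`.
#' @param data `hc_dataset` used for the reference/evaluation rows
#'   (training data; held-out data preferred for permutation maps).
#' @param method importance method; `NULL` picks the learner default.
#' @param n_repeats repeats for VarGrad / permutation.
#' @param noise_sd VarGrad noise level.
#' @param seed integer seed.
#' @return data.frame of class `importance_map` with columns
#'   `feature_axis`, `cluster` (`"global"` or cluster id), `method`,
#'   `raw`, `normalized`, `mean_spectrum`.
#' @export
importance_report <- function(model, data, method = NULL, n_repeats = 10,
                              noise_sd = 0.05, seed = 1L) {
  stopifnot(inherits(model, "hc_model"))
  kind <- model$spec$kind
  if (is.null(method)) method <- default_importance_method(kind)
  valid <- list(PLSR = c("loadings", "permutation"),
                SVR = "permutation",
                CNN = c("vargrad", "permutation"),
                RNN = c("vargrad", "permutation"))
  if (!method %in% valid[[kind]])
    stop(sprintf("method '%s' is not available for %s models", method, kind))
  y <- as.numeric(data$Y[, 1])
  rows <- list()
  add_map <- function(tag, object, X_sub, y_sub) {
    raw <- importance_for(object, method, X_sub, y_sub, n_repeats,
                          noise_sd, seed)
    rng <- range(raw)
    normalized <- if (diff(rng) > 0) (raw - rng[1]) / diff(rng)
                  else rep(0, length(raw))
    rows[[length(rows) + 1L]] <<- data.frame(
      feature_axis = data$feature_axis, cluster = tag, method = method,
      raw = raw, normalized = normalized,
      mean_spectrum = colMeans(X_sub), stringsAsFactors = FALSE)
  }
  labels <- predict_hc(model, data$X,
                       classifier = if (model$k > 1)
                         names(model$classifiers)[1] else "FCM")$cluster
  for (c in seq_len(model$k)) {
    idx <- which(labels == c)
    if (length(idx) < 3) next
    obj <- model$local_models[[c]]
    add_map(as.character(c), obj, data$X[idx, , drop = FALSE], y[idx])
  }
  global_obj <- if (!is.null(model$global_model)) model$global_model
                else if (kind == "PLSR") model$global_pls
  if (!is.null(global_obj)) add_map("global", global_obj, data$X, y)
  out <- do.call(rbind, rows)
  class(out) <- c("importance_map", class(out))
  out
}

#' Write an importance map as a delimited table
#' @param map an `importance_map`.
#' @param path output file path (CSV).
#' @return the path, invisibly.
#' @export
write_importance <- function(map, path) {
  write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}
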