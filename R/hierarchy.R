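#' Hierarchical cluster-based regression
#'
#' The full procedure: (1) a global PLSR model is calibrated with
#' CV-selected components; (2) its X-scores are clustered (FCM by
#' default); (3) clusters smaller than a minimum size are dissolved by
#' membership-based reassignment; (4) one local regressor is calibrated
#' per cluster with its own CV-selected hyperparameters; (5) classifiers
#' are fitted on scores vs. crisp labels and route new samples to the
#' local model that predicts them.
#'
#' @name hierarchy
NULL

#' Test-set R-squared
#' @param y observed responses.
#' @param pred predictions.
#' @return `1 - SSE/SST` with SST about the mean of `y`; `NA` when `y`
#'   has zero variance.
#' @export
r_squared <- function(y, pred) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((y - pred)^2) / sst
}

#' Fit a hierarchical cluster-based model
#'
#' @param train an `hc_dataset` with responses (the training half).
#' @param spec a [regressor_spec()] for the local (and global) learner.
#' @param k number of clusters (k = 1 degenerates to the global model).
#' @param clustering `"FCM"`, `"HAC"` or `"SPC"`.
#' @param classifiers classifier methods to calibrate for routing.
#' @param scheme CV scheme for global component selection; local models
#'   use LOO below `small_cluster_cv` samples and this scheme otherwise.
#' @param min_cluster_size clusters below this are dissolved (default 10).
#' @param fuzzifier FCM fuzziness exponent.
#' @param small_cluster_cv size threshold under which local model
#'   selection falls back to LOO.
#' @param fit_global also fit a global regressor of the same kind
#'   (needed for global-vs-hierarchical comparisons; default `TRUE`).
#' @param score_scaling metric for the clustering/classification score
#'   space: `"unit-direction"` (default) divides each score column by the
#'   norm of its projection direction, so isotropic within-cluster noise
#'   in the feature space keeps unit spread on every score axis;
#'   `"none"` uses the raw NIPALS scores.
#' @param min_explained incremental explained-X-variance floor for the
#'   component count (0 disables the restraint; the restraint is an
#'   option used for ill-conditioned spectral data).
#' @param seed integer seed controlling clustering restarts and training.
#' @return object of class `hc_model`.
#' @export
fit_hc <- function(train, spec = regressor_spec("PLSR"), k = 3,
                   clustering = c("FCM", "HAC", "SPC"),
                   classifiers = c("FCM", "LDA", "QDA", "NB"),
                   scheme = cv_scheme(k = 10), min_cluster_size = 10,
                   fuzzifier = 2, small_cluster_cv = 30,
                   fit_global = TRUE,
                   score_scaling = c("unit-direction", "none"),
                   min_explained = 0, seed = 1L) {
  stopifnot(inherits(train, "hc_dataset"), !is.null(train$Y))
  clustering <- match.arg(clustering)
  score_scaling <- match.arg(score_scaling)
  if (k < 1) stop("k must be >= 1")
  X <- train$X; y <- as.numeric(train$Y[, 1])
  set.seed(seed)
  sel <- select_components(X, y, scheme, max_components = spec$max_components,
                           min_explained = min_explained)
  global_pls <- fit_pls(X, y, sel$n_components)
  score_scale <- if (score_scaling == "unit-direction")
    sqrt(colSums(global_pls$R^2)) else rep(1, global_pls$n_components)
  scores <- sweep(global_pls$T, 2, score_scale, "/")

  if (k == 1) {
    assignment <- cluster_assignment(rep(1L, nrow(X)),
                                     matrix(1, nrow(X), 1), clustering)
    fcm_model <- NULL
  } else if (clustering == "FCM") {
    fcm_model <- fcm_fit(scores, k, fuzzifier = fuzzifier, seed = seed)
    assignment <- fcm_assignment(fcm_model)
  } else {
    fcm_model <- NULL
    assignment <- alt_cluster(scores, k, clustering, seed = seed)
  }
  assignment <- reassign_small_clusters(assignment, min_cluster_size)
  k_eff <- assignment$k
  if (!is.null(fcm_model) && k_eff < k) {
    # refit centroids on the surviving partition so routing stays consistent
    fcm_model <- fcm_fit(scores, k_eff, fuzzifier = fuzzifier, seed = seed)
    assignment <- reassign_small_clusters(fcm_assignment(fcm_model),
                                          min_cluster_size)
    k_eff <- assignment$k
  }

  local_models <- vector("list", k_eff)
  for (c in seq_len(k_eff)) {
    idx <- which(assignment$labels == c)
    local_scheme <- if (length(idx) < small_cluster_cv) cv_scheme("LOO")
                    else scheme
    set.seed(seed + c)
    local_models[[c]] <- fit_regressor(X[idx, , drop = FALSE], y[idx],
                                       spec, local_scheme)
  }

  clf <- list()
  if (k_eff > 1) {
    for (meth in classifiers) {
      if (meth == "FCM" && (clustering != "FCM" || is.null(fcm_model))) next
      clf[[meth]] <- fit_classifier(scores, assignment$labels, meth,
                                    fcm_model = fcm_model)
    }
  }

  global_model <- NULL
  if (fit_global) {
    if (k_eff == 1) {
      # degenerate hierarchy: the single local model IS the global model
      global_model <- local_models[[1]]
    } else if (spec$kind == "PLSR") {
      global_model <- new_fitted_regressor("PLSR", global_pls,
        list(n_components = global_pls$n_components), NULL, NULL,
        cv_mse = sel$cv_mse)
    } else {
      set.seed(seed + 1000L)
      global_model <- fit_regressor(X, y, spec, scheme)
    }
  }

  structure(list(global_pls = global_pls, global_model = global_model,
                 assignment = assignment, fcm_model = fcm_model,
                 local_models = local_models, classifiers = clf,
                 spec = spec, clustering = clustering, k = k_eff,
                 score_scale = score_scale,
                 component_selection = sel, seed = seed),
            class = "hc_model")
}

#' @export
print.hc_model <- function(x, ...) {
  sizes <- tabulate(x$assignment$labels, x$k)
  cat(sprintf("<hc_model> learner=%s, clustering=%s, k=%d (sizes: %s), %d PLS components\n",
              x$spec$kind, x$clustering, x$k,
              paste(sizes, collapse = ", "), x$global_pls$n_components))
  invisible(x)
}

#' Predict with a hierarchical model
#'
#' Projects new samples into the global PLS score space, classifies them
#' into clusters and predicts each with its cluster's local model
#' (`mode = "closest"`).  `mode = "weighted"` (FCM clustering only)
#' returns the FCM-membership-weighted sum of all local predictions.
#'
#' @param model an `hc_model`.
#' @param X_new feature matrix (or `hc_dataset`).
#' @param classifier routing method (must have been calibrated).
#' @param mode `"closest"` (default) or `"weighted"`.
#' @return list with `predictions`, `cluster` (assigned label per
#'   sample) and `posterior`.
#' @export
predict_hc <- function(model, X_new, classifier = "FCM",
                       mode = c("closest", "weighted")) {
  mode <- match.arg(mode)
  if (inherits(X_new, "hc_dataset")) X_new <- X_new$X
  X_new <- as.matrix(X_new)
  n <- nrow(X_new)
  if (model$k == 1) {
    pred <- predict(model$local_models[[1]], X_new)
    return(list(predictions = pred, cluster = rep(1L, n),
                posterior = matrix(1, n, 1)))
  }
  if (mode == "weighted" && model$clustering != "FCM")
    stop("weighted prediction requires FCM clustering")
  if (!classifier %in% names(model$classifiers))
    stop("classifier not calibrated for this model: ", classifier)
  scores <- sweep(project(model$global_pls, X_new), 2, model$score_scale, "/")
  cl <- predict_cluster(model$classifiers[[classifier]], scores)
  if (mode == "closest") {
    pred <- numeric(n)
    for (c in seq_len(model$k)) {
      idx <- which(cl$labels == c)
      if (length(idx))
        pred[idx] <- predict(model$local_models[[c]],
                             X_new[idx, , drop = FALSE])
    }
  } else {
    U <- fcm_membership(model$fcm_model, scores)
    pred <- rep(0, n)
    for (c in seq_len(model$k))
      pred <- pred + U[, c] * predict(model$local_models[[c]], X_new)
  }
  list(predictions = pred, cluster = cl$labels, posterior = cl$posterior)
}

#' Evaluate a model on a held-out test set
#'
#' @param model an `hc_model` or `fitted_regressor`.
#' @param test an `hc_dataset` with responses, disjoint from training.
#' @param classifier routing method for `hc_model`s.
#' @param mode prediction mode for `hc_model`s.
#' @return list of class `eval_report`: `r2`, `mse`, `global_r2` (when a
#'   global model is attached), per-cluster breakdown, cluster sizes.
#' @export
evaluate <- function(model, test, classifier = "FCM", mode = "closest") {
  stopifnot(inherits(test, "hc_dataset"), !is.null(test$Y))
  y <- as.numeric(test$Y[, 1])
  if (inherits(model, "fitted_regressor")) {
    pred <- predict(model, test$X)
    return(structure(list(r2 = r_squared(y, pred),
                          mse = mean((y - pred)^2), predictions = pred),
                     class = "eval_report"))
  }
  stopifnot(inherits(model, "hc_model"))
  out <- predict_hc(model, test$X, classifier, mode)
  per_cluster <- lapply(seq_len(model$k), function(c) {
    idx <- which(out$cluster == c)
    if (length(idx) < 2) return(list(n = length(idx), r2 = NA_real_))
    list(n = length(idx), r2 = r_squared(y[idx], out$predictions[idx]))
  })
  global_r2 <- NULL
  if (!is.null(model$global_model)) {
    gp <- predict(model$global_model, test$X)
    global_r2 <- r_squared(y, gp)
  }
  structure(list(r2 = r_squared(y, out$predictions),
                 mse = mean((y - out$predictions)^2),
                 global_r2 = global_r2, per_cluster = per_cluster,
                 cluster_sizes = tabulate(model$assignment$labels, model$k),
                 k = model$k, classifier = classifier,
                 predictions = out$predictions),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> test R2 = %.3f, MSE = %.4g", x$r2, x$mse))
  if (!is.null(x$global_r2)) cat(sprintf(" (global model R2 = %.3f)", x$global_r2))
  cat("\n")
  invisible(x)
}

#' Select the number of clusters
#'
#' Splits the training data 50/50 into calibration and validation halves,
#' fits hierarchical models for each candidate `k` on the calibration
#' half and scores validation-half predictions per classifier method.
#' The chosen `k*` is the smallest `k` whose mean R-squared across
#' classifier methods lies within one standard error of the maximum
#' (the usual one-standard-error parsimony rule, using the asymptotic
#' standard error of R-squared on the validation half); exact ties also
#' resolve to the smallest `k`.
#'
#' @param train training `hc_dataset`.
#' @param spec learner [regressor_spec()].
#' @param k_range candidate cluster counts.
#' @param clustering clustering method.
#' @param classifiers classifier methods averaged over.
#' @param scheme CV scheme forwarded to [fit_hc()].
#' @param seed integer seed (controls the calibration/validation split).
#' @return list with `k_star` and `table` (k x classifier R-squared,
#'   plus the mean; infeasible cells are `NA`).
#' @export
select_n_clusters <- function(train, spec = regressor_spec("PLSR"),
                              k_range = 2:10,
                              clustering = "FCM",
                              classifiers = c("FCM", "LDA", "QDA", "NB"),
                              scheme = cv_scheme(k = 10), seed = 1L) {
  halves <- split_train_test(train, 0.5, seed = seed)
  calib <- halves$train; valid <- halves$test
  y_val <- as.numeric(valid$Y[, 1])
  tab <- matrix(NA_real_, length(k_range), length(classifiers),
                dimnames = list(paste0("k", k_range), classifiers))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    model <- tryCatch(
      fit_hc(calib, spec, k, clustering, classifiers, scheme,
             fit_global = FALSE, seed = seed),
      error = function(e) NULL)
    if (is.null(model)) next
    for (j in seq_along(classifiers)) {
      meth <- classifiers[j]
      if (model$k > 1 && !meth %in% names(model$classifiers)) next
      r2 <- tryCatch({
        out <- predict_hc(model, valid$X, classifier = meth)
        r_squared(y_val, out$predictions)
      }, error = function(e) NA_real_)
      tab[i, j] <- r2
    }
  }
  mean_r2 <- rowMeans(tab, na.rm = TRUE)
  mean_r2[is.nan(mean_r2)] <- -Inf
  best <- max(mean_r2)
  # asymptotic SE of R^2 at the maximum; the smallest k within one SE
  # of the best mean R^2 wins (parsimony under validation noise)
  n_val <- length(y_val)
  se <- if (best > 0 && best < 1)
    sqrt(4 * best * (1 - best)^2 / n_val) else 0
  k_star <- k_range[which(mean_r2 >= best - se)[1]]
  list(k_star = k_star, table = cbind(tab, mean = ifelse(is.finite(mean_r2),
                                                         mean_r2, NA_real_)))
}
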