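#' NIPALS partial least squares regression
#'
#' PLSR decomposes centred `X` and `Y` into latent components maximizing
#' X-Y covariance: scores `T`, X-weights `W`, X-loadings `P`, Y-loadings
#' `Q`.  Fitting uses the classical NIPALS algorithm with deflation of
#' `X`; regression coefficients are `B = W (P'W)^{-1} Q'`.
#'
#' @param X numeric matrix (samples x features).
#' @param Y numeric vector or matrix of responses.
#' @param n_components number of components to extract.
#' @param scaling_mode `"center"` (default) or `"center+standardize"`
#'   applied to `X`; `Y` is always centred.
#' @param tol NIPALS convergence tolerance on the weight vector.
#' @param max_iter maximum NIPALS inner iterations per component.
#' @return object of class `pls_model` with fields `center`, `scale`,
#'   `y_center`, `W`, `T`, `P`, `Q`, `B`, `expl_var_x`, `expl_var_y`
#'   (per-component fractions), `n_components`.
#' @export
fit_pls <- function(X, Y, n_components, scaling_mode = "center",
                    tol = 1e-10, max_iter = 500) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (n < 2) stop("need at least 2 samples")
  if (n_components < 1) stop("n_components must be >= 1")
  A_max <- min(n - 1, p)
  A <- min(n_components, A_max)
  cs <- center_scale(X, scaling_mode)
  E <- cs$X
  y_center <- colMeans(Y)
  Fm <- sweep(Y, 2, y_center)
  if (all(apply(Fm, 2, sd) == 0)) stop("Y has zero variance")
  ssx_tot <- sum(E^2); ssy_tot <- sum(Fm^2)
  W <- matrix(0, p, A); P <- matrix(0, p, A); Q <- matrix(0, q, A)
  Tm <- matrix(0, n, A)
  evx <- numeric(A); evy <- numeric(A)
  A_eff <- 0L
  for (a in seq_len(A)) {
    # start u as the Y column with largest variance
    u <- Fm[, which.max(apply(Fm, 2, var)), drop = FALSE]
    if (sum(u^2) < 1e-300) break
    w_old <- rep(0, p)
    for (it in seq_len(max_iter)) {
      w <- crossprod(E, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) break
      w <- w / nw
      t_scores <- E %*% w
      qv <- crossprod(Fm, t_scores) / sum(t_scores^2)
      if (q == 1L) { u_new <- Fm } else { u_new <- Fm %*% qv / sum(qv^2) }
      if (sqrt(sum((w - w_old)^2)) < tol) { u <- u_new; break }
      w_old <- w; u <- u_new
      if (it == max_iter)
        warning("NIPALS did not converge; component truncated at max_iter")
    }
    if (sqrt(sum(w^2)) < 1e-300) break
    t_scores <- E %*% w
    tt <- sum(t_scores^2)
    if (tt < 1e-12 * ssx_tot / n) break
    pv <- crossprod(E, t_scores) / tt
    qv <- crossprod(Fm, t_scores) / tt
    E <- E - t_scores %*% t(pv)
    Fm <- Fm - t_scores %*% t(qv)
    A_eff <- a
    W[, a] <- w; P[, a] <- pv; Q[, a] <- qv; Tm[, a] <- t_scores
    evx[a] <- tt * sum(pv^2) / ssx_tot
    evy[a] <- tt * sum(qv^2) / ssy_tot
  }
  if (A_eff == 0L) stop("no PLS component could be extracted")
  if (A_eff < A) {
    W <- W[, seq_len(A_eff), drop = FALSE]
    P <- P[, seq_len(A_eff), drop = FALSE]
    Q <- Q[, seq_len(A_eff), drop = FALSE]
    Tm <- Tm[, seq_len(A_eff), drop = FALSE]
    evx <- evx[seq_len(A_eff)]; evy <- evy[seq_len(A_eff)]
  }
  R <- W %*% solve(crossprod(P, W))
  B <- R %*% t(Q)
  structure(list(center = cs$stats$center, scale = cs$stats$scale,
                 scaling_mode = cs$stats$mode, y_center = y_center,
                 W = W, T = Tm, P = P, Q = Q, R = R, B = B,
                 expl_var_x = evx, expl_var_y = evy,
                 n_components = A_eff),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d components, cumulative X-var %.2f%%, Y-var %.2f%%\n",
              x$n_components, 100 * sum(x$expl_var_x), 100 * sum(x$expl_var_y)))
  invisible(x)
}

#' Project new samples into a PLS model's score space
#'
#' @param model a `pls_model`.
#' @param X_new matrix of new samples (training feature count).
#' @return score matrix `T_new = X_c W (P'W)^{-1}`.
#' @export
project <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$center))
    stop("feature count does not match the model")
  Xc <- sweep(sweep(X_new, 2, model$center), 2, model$scale, "/")
  Xc %*% model$R
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$center))
    stop("feature count does not match the model")
  Xc <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  pred <- Xc %*% object$B
  sweep(pred, 2, object$y_center, "+")
}

#' Cumulative explained variance
#' @param model a `pls_model`.
#' @return list with per-component and cumulative fractions for X and Y.
#' @export
explained_variance <- function(model) {
  list(x = model$expl_var_x, y = model$expl_var_y,
       x_cum = cumsum(model$expl_var_x), y_cum = cumsum(model$expl_var_y))
}

#' Cross-validation scheme
#' @param kind `"kfold"` or `"LOO"`.
#' @param k number of folds (k-fold only).
#' @param seed seed for fold shuffling.
#' @return list of class `cv_scheme`.
#' @export
cv_scheme <- function(kind = c("kfold", "LOO"), k = 10, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "kfold" && k < 2) stop("k must be >= 2")
  structure(list(kind = kind, k = k, seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Fold index assignment for a CV scheme
#' @param scheme a `cv_scheme`.
#' @param n number of samples.
#' @return integer vector of fold labels, length `n`.
#' @export
cv_folds <- function(scheme, n) {
  if (scheme$kind == "LOO") return(seq_len(n))
  k <- min(scheme$k, n)
  set.seed(scheme$seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Select the number of PLS components by cross-validation
#'
#' Chooses the component count minimizing the cross-validated MSE,
#' optionally truncated so every retained component adds at least
#' `min_explained` incremental explained X-variance (fitted on the full
#' data).  Both the unconstrained and constrained choices are reported.
#'
#' @param X,Y training data.
#' @param scheme a [cv_scheme()].
#' @param max_components largest component count tried (default
#'   `min(n-1, p, 30)`).
#' @param min_explained incremental explained-X-variance floor; set to 0
#'   to disable the restraint.
#' @param scaling_mode passed to [fit_pls()].
#' @return list with `n_components` (constrained choice),
#'   `n_components_unconstrained`, `cv_mse` (per count), `expl_var_x`.
#' @export
select_components <- function(X, Y, scheme = cv_scheme(), max_components = NULL,
                              min_explained = 0.01, scaling_mode = "center") {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X)
  if (is.null(max_components)) max_components <- min(n - 1, p, 30)
  max_components <- max(min(max_components, n - 1, p), 1)
  folds <- cv_folds(scheme, n)
  press <- matrix(0, length(unique(folds)), max_components)
  counts <- numeric(length(unique(folds)))
  for (f in sort(unique(folds))) {
    out_idx <- which(folds == f); in_idx <- which(folds != f)
    A_f <- min(max_components, length(in_idx) - 1, p)
    m <- fit_pls(X[in_idx, , drop = FALSE], Y[in_idx, , drop = FALSE],
                 n_components = A_f, scaling_mode = scaling_mode)
    Xo <- sweep(sweep(X[out_idx, , drop = FALSE], 2, m$center), 2, m$scale, "/")
    # cumulative predictions per component count
    Tn <- Xo %*% m$R
    for (a in seq_len(max_components)) {
      aa <- min(a, m$n_components)
      Ba <- m$W[, 1:aa, drop = FALSE] %*%
        solve(crossprod(m$P[, 1:aa, drop = FALSE], m$W[, 1:aa, drop = FALSE])) %*%
        t(m$Q[, 1:aa, drop = FALSE])
      pred <- sweep(Xo %*% Ba, 2, m$y_center, "+")
      press[f, a] <- sum((Y[out_idx, , drop = FALSE] - pred)^2)
    }
    counts[f] <- length(out_idx)
  }
  cv_mse <- colSums(press) / (sum(counts) * ncol(Y))
  # smallest component count within float tolerance of the minimum
  thr <- min(cv_mse) * (1 + 1e-8) + 1e-15
  a_star <- which(cv_mse <= thr)[1]
  full <- fit_pls(X, Y, n_components = max_components,
                  scaling_mode = scaling_mode)
  ok <- full$expl_var_x >= min_explained
  a_cap <- if (any(ok)) max(which(ok)) else 1L
  list(n_components = min(a_star, a_cap),
       n_components_unconstrained = a_star,
       cv_mse = cv_mse, expl_var_x = full$expl_var_x)
}
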