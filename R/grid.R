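#' Activation / learning-rate search grid
#'
#' Fits the global and hierarchical network model for every combination
#' of activation function and learning rate and records both test-set
#' R-squared values.  Cells whose training diverges are recorded as
#' failures rather than raised.
#'
#' @param train,test training and test `hc_dataset`s.
#' @param kind `"CNN"` or `"RNN"`.
#' @param activations character vector of activations (default the five
#'   canonical ones).
#' @param learning_rates numeric vector (default `0.1, 0.01, 0.001,
#'   0.0001`).
#' @param k number of clusters for the hierarchical fits.
#' @param base_spec template [regressor_spec()] supplying the
#'   architecture, epoch budget and selection mode for every cell.
#' @param classifier routing method for the hierarchical predictions.
#' @param scheme CV scheme forwarded to the fits.
#' @param seed integer seed.
#' @return data.frame with columns `activation`, `learning_rate`,
#'   `global_r2`, `hc_r2`, `status`; attribute `n_hc_wins` counts cells
#'   where the hierarchical model beats the global one.
#' @export
activation_lr_grid <- function(train, test, kind = c("CNN", "RNN"),
                               activations = c("sigmoid", "relu", "elu",
                                               "tanh", "linear"),
                               learning_rates = c(0.1, 0.01, 0.001, 1e-4),
                               k = 3, base_spec = NULL, classifier = "FCM",
                               scheme = cv_scheme(k = 10), seed = 1L) {
  kind <- match.arg(kind)
  if (!length(activations) || !length(learning_rates))
    stop("activation and learning-rate grids must be non-empty")
  if (is.null(base_spec)) base_spec <- regressor_spec(kind)
  y_test <- as.numeric(test$Y[, 1])
  rows <- list()
  for (a in activations) for (lr in learning_rates) {
    spec <- base_spec
    spec$kind <- kind; spec$activation <- a; spec$learning_rate <- lr
    status <- "ok"; g_r2 <- NA_real_; h_r2 <- NA_real_
    res <- tryCatch({
      model <- fit_hc(train, spec, k = k, classifiers = classifier,
                      scheme = scheme, fit_global = TRUE, seed = seed)
      rep_ <- evaluate(model, test, classifier = classifier)
      list(g = rep_$global_r2, h = rep_$r2)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status <- conditionMessage(res)
    } else {
      g_r2 <- res$g; h_r2 <- res$h
    }
    rows[[length(rows) + 1L]] <-
      data.frame(activation = a, learning_rate = lr, global_r2 = g_r2,
                 hc_r2 = h_r2, status = status, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "n_hc_wins") <- sum(out$hc_r2 > out$global_r2, na.rm = TRUE)
  out
}
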