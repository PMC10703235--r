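#' FT-IR style preprocessing chain
#'
#' Replicate averaging, Savitzky-Golay derivative smoothing, extended
#' multiplicative signal correction (EMSC), region cropping and
#' centring/scaling, in the fixed order used for dry-film FT-IR
#' calibration work:
#' replicate average -> SavGol -> EMSC -> crop -> centre/scale.
#'
#' @name spectra_prep
NULL

#' Average replicate spectra
#'
#' Collapses replicate rows to one arithmetic-mean spectrum per unique
#' sample id.  Responses must be identical across a sample's replicates.
#'
#' @param dataset `hc_dataset` with `replicate_id` and repeated
#'   `sample_ids`.
#' @return `hc_dataset` with one row per unique sample id (in order of
#'   first appearance) and no replicate ids.
#' @export
average_replicates <- function(dataset) {
  if (is.null(dataset$replicate_id))
    stop("dataset has no replicate ids")
  ids <- dataset$sample_ids
  uid <- unique(ids)
  Xm <- matrix(0, length(uid), ncol(dataset$X))
  ym <- if (!is.null(dataset$Y)) matrix(0, length(uid), ncol(dataset$Y))
  for (i in seq_along(uid)) {
    rows <- which(ids == uid[i])
    Xm[i, ] <- colMeans(dataset$X[rows, , drop = FALSE])
    if (!is.null(dataset$Y)) {
      yy <- dataset$Y[rows, , drop = FALSE]
      if (any(abs(sweep(yy, 2, yy[1, ])) > 1e-12))
        stop(sprintf("replicates of sample %s have differing responses", uid[i]))
      ym[i, ] <- yy[1, ]
    }
  }
  hc_dataset(Xm, Y = ym, feature_axis = dataset$feature_axis,
             sample_ids = uid)
}

#' Savitzky-Golay derivative smoothing
#'
#' Local least-squares polynomial filtering of each spectrum, returning
#' the derivative of the fitted polynomial at the window centre, scaled by
#' the feature-axis step so values are per axis unit.  Edge points come
#' from the one-sided window fits, so the feature count is preserved.
#'
#' @param X spectra matrix (samples in rows).
#' @param feature_axis equally spaced axis (ascending or descending).
#' @param window odd window width in points.
#' @param polyorder polynomial order (`< window`).
#' @param deriv derivative order (`<= polyorder`).
#' @return filtered matrix of the same dimension.
#' @export
savgol_derivative <- function(X, feature_axis = NULL, window = 11,
                              polyorder = 3, deriv = 2) {
  X <- as.matrix(X)
  if (window %% 2 != 1) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be < window")
  if (deriv > polyorder) stop("deriv must be <= polyorder")
  if (ncol(X) < window) stop("fewer features than the filter window")
  ts <- if (is.null(feature_axis)) 1 else abs(mean(diff(feature_axis)))
  t(apply(X, 1, function(z)
    signal::sgolayfilt(z, p = polyorder, n = window, m = deriv, ts = ts)))
}

#' Extended multiplicative signal correction
#'
#' Least-squares decomposition of each spectrum `z` against a reference
#' `m`, a constant, and polynomial terms in the axis rescaled to `[-1,1]`:
#' `z = a + b m + d1 L + d2 L^2 + ... + e`.  The corrected spectrum is
#' `(z - a - d1 L - ...) / b`, removing additive, multiplicative and
#' smooth baseline effects relative to the reference.
#'
#' @param X spectra matrix.
#' @param feature_axis axis used for the polynomial basis.
#' @param reference reference spectrum; defaults to the column mean of `X`.
#' @param poly_order polynomial order (`>= 0`).
#' @param b_tol minimum `|b|`; spectra below it are flagged and returned
#'   uncorrected.
#' @return list with `corrected` (matrix), `coefficients` (matrix with
#'   columns `a`, `b`, `d1`, ...), `reference`, `flagged` (logical).
#' @export
emsc_correct <- function(X, feature_axis = NULL, reference = NULL,
                         poly_order = 2, b_tol = 1e-8) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(feature_axis)) feature_axis <- seq_len(p)
  if (is.null(reference)) reference <- colMeans(X)
  if (length(reference) != p) stop("reference length must match feature count")
  if (poly_order < 0) stop("poly_order must be >= 0")
  lambda <- (feature_axis - mean(range(feature_axis))) /
    (diff(range(feature_axis)) / 2)
  basis <- cbind(1, reference)
  if (poly_order >= 1)
    for (q in seq_len(poly_order)) basis <- cbind(basis, lambda^q)
  colnames(basis) <- c("a", "b", if (poly_order >= 1)
    paste0("d", seq_len(poly_order)))
  qrB <- qr(basis)
  coefs <- t(qr.coef(qrB, t(X)))
  corrected <- X
  flagged <- abs(coefs[, "b"]) < b_tol
  for (i in which(!flagged)) {
    additive <- basis[, -2, drop = FALSE] %*% coefs[i, -2]
    corrected[i, ] <- (X[i, ] - additive) / coefs[i, "b"]
  }
  if (any(flagged))
    warning(sprintf("%d spectra with |b| < tolerance left uncorrected",
                    sum(flagged)))
  list(corrected = corrected, coefficients = coefs, reference = reference,
       flagged = flagged)
}

#' Crop a wavenumber region
#'
#' Keeps columns whose axis value lies in `[low, high]` (inclusive),
#' preserving axis order.
#'
#' @param X spectra matrix.
#' @param feature_axis axis values per column.
#' @param low,high crop bounds, `low < high`.
#' @return list with `X` and `feature_axis` cropped.
#' @export
crop_region <- function(X, feature_axis, low = 700, high = 1800) {
  if (low >= high) stop("crop bounds must satisfy low < high")
  keep <- feature_axis >= low & feature_axis <= high
  if (!any(keep)) stop("crop region contains no features")
  list(X = as.matrix(X)[, keep, drop = FALSE],
       feature_axis = feature_axis[keep])
}

#' Column centring and scaling
#'
#' Centres (and optionally standardizes) columns using statistics from the
#' fitting data, or applies previously computed statistics to new data.
#' Zero-variance columns keep a scale of 1 with a warning.
#'
#' @param X numeric matrix.
#' @param mode one of `"center"`, `"center+standardize"`, `"none"`.
#' @param fit_stats optional statistics from a previous call, to transform
#'   new data consistently.
#' @return list with `X` (transformed), `stats` (list with `mode`,
#'   `center`, `scale`).
#' @export
center_scale <- function(X, mode = c("center", "center+standardize", "none"),
                         fit_stats = NULL) {
  X <- as.matrix(X)
  if (is.null(fit_stats)) {
    mode <- match.arg(mode)
    ctr <- if (mode == "none") rep(0, ncol(X)) else colMeans(X)
    scl <- rep(1, ncol(X))
    if (mode == "center+standardize") {
      scl <- apply(X, 2, sd)
      if (any(scl == 0)) {
        warning("zero-variance column(s); scale left at 1")
        scl[scl == 0] <- 1
      }
    }
    fit_stats <- list(mode = mode, center = ctr, scale = scl)
  }
  Xt <- sweep(sweep(X, 2, fit_stats$center), 2, fit_stats$scale, "/")
  list(X = Xt, stats = fit_stats)
}

#' Invert a centring/scaling transform
#' @param X transformed matrix.
#' @param stats statistics from [center_scale()].
#' @return matrix on the original scale.
#' @export
uncenter_scale <- function(X, stats) {
  sweep(sweep(as.matrix(X), 2, stats$scale, "*"), 2, stats$center, "+")
}

#' Fit-and-apply preprocessing chain
#'
#' Runs the fixed chain (replicate average if replicate ids are present,
#' Savitzky-Golay derivative, EMSC, crop, centre/scale) on a training
#' dataset and returns both the processed data and a chain object that
#' re-applies identical statistics (EMSC reference, centring statistics)
#' to new data via [apply_chain()].
#'
#' @param dataset `hc_dataset` of raw spectra.
#' @param window,polyorder,deriv Savitzky-Golay parameters.
#' @param emsc_poly_order EMSC polynomial order.
#' @param crop crop bounds `c(low, high)` or `NULL` to skip.
#' @param scaling `"center"`, `"center+standardize"` or `"none"`.
#' @return list with `dataset` (processed) and `chain` (reusable).
#' @export
fit_chain <- function(dataset, window = 11, polyorder = 3, deriv = 2,
                      emsc_poly_order = 2, crop = c(700, 1800),
                      scaling = "center") {
  if (!is.null(dataset$replicate_id)) dataset <- average_replicates(dataset)
  axis <- dataset$feature_axis
  Xs <- savgol_derivative(dataset$X, axis, window, polyorder, deriv)
  em <- emsc_correct(Xs, axis, poly_order = emsc_poly_order)
  Xe <- em$corrected
  if (!is.null(crop)) {
    cr <- crop_region(Xe, axis, crop[1], crop[2])
    Xe <- cr$X; axis_out <- cr$feature_axis
  } else axis_out <- axis
  cs <- center_scale(Xe, scaling)
  chain <- list(window = window, polyorder = polyorder, deriv = deriv,
                emsc_poly_order = emsc_poly_order,
                emsc_reference = em$reference, crop = crop,
                axis_in = axis, scaling_stats = cs$stats)
  class(chain) <- "preproc_chain"
  out <- hc_dataset(cs$X, Y = dataset$Y, feature_axis = axis_out,
                    sample_ids = dataset$sample_ids,
                    true_cluster = dataset$true_cluster)
  list(dataset = out, chain = chain)
}

#' Apply a fitted preprocessing chain to new data
#' @param chain a `preproc_chain` from [fit_chain()].
#' @param dataset new raw `hc_dataset` on the same axis.
#' @return processed `hc_dataset`.
#' @export
apply_chain <- function(chain, dataset) {
  stopifnot(inherits(chain, "preproc_chain"))
  if (!is.null(dataset$replicate_id)) dataset <- average_replicates(dataset)
  if (!isTRUE(all.equal(dataset$feature_axis, chain$axis_in)))
    stop("new data is not on the chain's feature axis")
  Xs <- savgol_derivative(dataset$X, chain$axis_in, chain$window,
                          chain$polyorder, chain$deriv)
  em <- emsc_correct(Xs, chain$axis_in, reference = chain$emsc_reference,
                     poly_order = chain$emsc_poly_order)
  Xe <- em$corrected
  axis_out <- chain$axis_in
  if (!is.null(chain$crop)) {
    cr <- crop_region(Xe, chain$axis_in, chain$crop[1], chain$crop[2])
    Xe <- cr$X; axis_out <- cr$feature_axis
  }
  cs <- center_scale(Xe, fit_stats = chain$scaling_stats)
  hc_dataset(cs$X, Y = dataset$Y, feature_axis = axis_out,
             sample_ids = dataset$sample_ids,
             true_cluster = dataset$true_cluster)
}
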