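#' Simulated benchmark and spectral fixture generators
#'
#' Generators for (i) the three-cluster Friedman-function regression
#' benchmark used throughout the package's examples and tests, and (ii)
#' synthetic FT-IR-like spectra with replicate structure, multiplicative
#' and baseline distortions and a peak-linked response.
#'
#' @name simdata
NULL

# canonical input boxes of the Friedman test functions:
# variant 1 uses five U[0,1] inputs; variants 2 and 3 share a four-input box.
friedman_box <- function(variant) {
  if (variant == 1L) {
    list(lower = rep(0, 5), upper = rep(1, 5))
  } else {
    list(lower = c(0, 40 * pi, 0, 1), upper = c(100, 560 * pi, 1, 11))
  }
}

#' Construct a dataset container
#'
#' Light container holding a feature matrix `X`, response `Y`, the feature
#' axis (wavenumbers for spectra, indices otherwise), sample ids and
#' optional known cluster labels or replicate ids.
#'
#' @param X numeric matrix, samples in rows.
#' @param Y numeric vector or single-column matrix of responses (or `NULL`).
#' @param feature_axis numeric vector of feature coordinates, strictly
#'   monotone, length `ncol(X)`. Defaults to the column index.
#' @param sample_ids character or integer ids, length `nrow(X)`.
#' @param true_cluster optional integer cluster labels (simulations only).
#' @param replicate_id optional replicate identifier per row.
#' @return An object of class `hc_dataset`.
#' @export
hc_dataset <- function(X, Y = NULL, feature_axis = NULL, sample_ids = NULL,
                       true_cluster = NULL, replicate_id = NULL) {
  X <- as.matrix(X)
  if (is.null(feature_axis)) feature_axis <- seq_len(ncol(X))
  if (length(feature_axis) != ncol(X))
    stop("feature_axis length must equal ncol(X)")
  d <- diff(feature_axis)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("feature_axis must be strictly monotone")
  if (is.null(sample_ids)) sample_ids <- seq_len(nrow(X))
  if (length(sample_ids) != nrow(X))
    stop("sample_ids length must equal nrow(X)")
  if (!is.null(Y)) {
    Y <- as.matrix(Y)
    if (nrow(Y) != nrow(X)) stop("X and Y must have the same number of rows")
    if (anyNA(Y) || any(!is.finite(Y))) stop("Y contains NaN/Inf")
  }
  if (anyNA(X) || any(!is.finite(X))) stop("X contains NaN/Inf")
  structure(list(X = X, Y = Y, feature_axis = feature_axis,
                 sample_ids = sample_ids, true_cluster = true_cluster,
                 replicate_id = replicate_id),
            class = "hc_dataset")
}

#' @export
print.hc_dataset <- function(x, ...) {
  cat(sprintf("<hc_dataset> %d samples x %d features", nrow(x$X), ncol(x$X)))
  if (!is.null(x$Y)) cat(sprintf(", %d response(s)", ncol(x$Y)))
  if (!is.null(x$true_cluster))
    cat(sprintf(", %d known clusters", length(unique(x$true_cluster))))
  if (!is.null(x$replicate_id))
    cat(sprintf(", %d replicate groups", length(unique(x$sample_ids))))
  cat("\n")
  invisible(x)
}

#' Simulation configuration
#'
#' @param n_samples total number of samples.
#' @param n_features number of features (at least 5; the first Friedman
#'   variant consumes five inputs).
#' @param n_clusters number of Gaussian blobs.
#' @param cluster_std isotropic standard deviation of each blob.
#' @param noise_sd standard deviation of additive response noise (applied
#'   on the per-cluster standardized scale when standardization is on).
#' @param response_variants integer vector, one Friedman variant id
#'   (1, 2 or 3) per cluster.
#' @param per_cluster_standardize rescale each cluster's responses to mean
#'   0, sd 1 before assembly (default `TRUE`, giving the clusters
#'   commensurate response scales).
#' @param center_box range from which blob centres are drawn uniformly.
#' @param seed integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 1500, n_features = 20, n_clusters = 3,
                       cluster_std = 1, noise_sd = 0,
                       response_variants = c(1L, 2L, 3L),
                       per_cluster_standardize = TRUE,
                       center_box = c(-10, 10), seed = 1L) {
  if (n_clusters != length(response_variants))
    stop("n_clusters must equal length(response_variants)")
  if (n_samples < n_clusters) stop("n_samples must be >= n_clusters")
  if (n_features < 5) stop("n_features must be >= 5")
  if (cluster_std < 0 || noise_sd < 0) stop("dispersions must be nonnegative")
  if (!all(response_variants %in% 1:3)) stop("variants must be in 1..3")
  structure(list(n_samples = n_samples, n_features = n_features,
                 n_clusters = n_clusters, cluster_std = cluster_std,
                 noise_sd = noise_sd,
                 response_variants = as.integer(response_variants),
                 per_cluster_standardize = per_cluster_standardize,
                 center_box = center_box, seed = as.integer(seed)),
            class = "sim_config")
}

#' Gaussian blob features
#'
#' Draws `n_samples` points from `n_clusters` isotropic Gaussians with
#' centres placed uniformly at random in `center_box` (each coordinate
#' independently), with cluster sizes as equal as possible.
#'
#' @inheritParams sim_config
#' @param center_box numeric length-2 range for the blob centres.
#' @param min_center_sep minimum pairwise centre distance; candidate
#'   centre sets are redrawn until both the full-space distance and the
#'   distance restricted to the first `sep_block` coordinates (scaled by
#'   `sqrt(sep_block / n_features)`) meet it, guaranteeing clusters that
#'   are well separated also in the coordinates that later carry the
#'   response.  Set to 0 to disable.
#' @param sep_block number of leading coordinates the block criterion
#'   applies to (the response-coupled features; default 5).
#' @param seed integer seed.
#' @return `hc_dataset` without `Y`, with `true_cluster` labels in
#'   `1..n_clusters`.
#' @export
make_blob_features <- function(n_samples, n_features, n_clusters,
                               cluster_std = 1, center_box = c(-10, 10),
                               min_center_sep = 20, sep_block = 5,
                               seed = 1L) {
  if (n_samples < n_clusters) stop("n_samples must be >= n_clusters")
  if (n_samples <= 0 || n_features <= 0 || n_clusters <= 0)
    stop("counts must be positive")
  if (cluster_std < 0) stop("cluster_std must be nonnegative")
  set.seed(seed)
  sep_block <- min(sep_block, n_features)
  block_sep <- min_center_sep * sqrt(sep_block / n_features)
  draw_centers <- function() {
    matrix(runif(n_clusters * n_features, center_box[1], center_box[2]),
           nrow = n_clusters)
  }
  centers <- draw_centers()
  if (min_center_sep > 0 && n_clusters > 1) {
    for (try in seq_len(1000)) {
      d_full <- min(dist(centers))
      d_block <- min(dist(centers[, seq_len(sep_block), drop = FALSE]))
      if (d_full >= min_center_sep && d_block >= block_sep) break
      centers <- draw_centers()
      if (try == 1000)
        stop("could not draw well-separated centres; loosen min_center_sep")
    }
  }
  base <- n_samples %/% n_clusters
  sizes <- rep(base, n_clusters)
  extra <- n_samples - base * n_clusters
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- rep(seq_len(n_clusters), times = sizes)
  X <- centers[labels, , drop = FALSE] +
    matrix(rnorm(n_samples * n_features, sd = cluster_std), nrow = n_samples)
  hc_dataset(X, feature_axis = seq_len(n_features), true_cluster = labels)
}

#' Friedman benchmark responses
#'
#' Evaluates one of the three classical Friedman regression test functions
#' on inputs already living in the variant's canonical box:
#' \itemize{
#'   \item variant 1: `10 sin(pi u1 u2) + 20 (u3 - 0.5)^2 + 10 u4 + 5 u5`
#'   \item variant 2: `sqrt(u1^2 + (u2 u3 - 1/(u2 u4))^2)`
#'   \item variant 3: `atan((u2 u3 - 1/(u2 u4)) / u1)`
#' }
#' with additive `Normal(0, noise_sd^2)` noise.
#'
#' @param U numeric matrix whose first `d` columns are the variant's inputs
#'   (`d = 5` for variant 1, `d = 4` for variants 2 and 3).
#' @param variant integer in 1..3.
#' @param noise_sd nonnegative noise standard deviation.
#' @param seed integer seed (only consumed when `noise_sd > 0`).
#' @return numeric response vector of length `nrow(U)`.
#' @export
friedman_response <- function(U, variant, noise_sd = 0, seed = 1L) {
  U <- as.matrix(U)
  variant <- as.integer(variant)
  if (!variant %in% 1:3) stop("variant must be 1, 2 or 3")
  d <- if (variant == 1L) 5L else 4L
  if (ncol(U) < d)
    stop(sprintf("variant %d needs at least %d input columns", variant, d))
  y <- switch(variant,
    10 * sin(pi * U[, 1] * U[, 2]) + 20 * (U[, 3] - 0.5)^2 +
      10 * U[, 4] + 5 * U[, 5],
    sqrt(U[, 1]^2 + (U[, 2] * U[, 3] - 1 / (U[, 2] * U[, 4]))^2),
    atan((U[, 2] * U[, 3] - 1 / (U[, 2] * U[, 4])) / U[, 1]))
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(nrow(U), sd = noise_sd)
  }
  y
}

# min-max map columns of X onto [lower, upper] per column
minmax_map <- function(X, lower, upper) {
  X <- as.matrix(X)
  for (j in seq_len(ncol(X))) {
    r <- range(X[, j])
    span <- r[2] - r[1]
    X[, j] <- if (span == 0) rep((lower[j] + upper[j]) / 2, nrow(X))
              else lower[j] + (X[, j] - r[1]) / span * (upper[j] - lower[j])
  }
  X
}

#' Simulate the three-cluster Friedman benchmark
#'
#' Draws blob features, then per cluster min-max maps the first `d`
#' features onto the cluster's Friedman variant input box, evaluates the
#' variant's response, and (by default) standardizes each cluster's
#' responses to mean 0, sd 1.  The remaining features act as distractors
#' that carry cluster location but no response information.
#'
#' @param config a [sim_config()].
#' @return `hc_dataset` with `Y` and `true_cluster`.
#' @export
simulate_hc_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  ds <- make_blob_features(config$n_samples, config$n_features,
                           config$n_clusters, config$cluster_std,
                           config$center_box, seed = config$seed)
  y <- numeric(config$n_samples)
  for (k in seq_len(config$n_clusters)) {
    idx <- which(ds$true_cluster == k)
    variant <- config$response_variants[k]
    box <- friedman_box(variant)
    d <- length(box$lower)
    U <- minmax_map(ds$X[idx, seq_len(d), drop = FALSE], box$lower, box$upper)
    yk <- friedman_response(U, variant, noise_sd = 0)
    if (config$per_cluster_standardize) {
      s <- sd(yk)
      yk <- if (s > 0) (yk - mean(yk)) / s else yk - mean(yk)
    }
    y[idx] <- yk
  }
  if (config$noise_sd > 0) {
    set.seed(config$seed + 1L)
    y <- y + rnorm(config$n_samples, sd = config$noise_sd)
  }
  hc_dataset(ds$X, Y = y, feature_axis = ds$feature_axis,
             true_cluster = ds$true_cluster)
}

#' Synthetic FT-IR-like spectra with replicates
#'
#' Builds absorbance-like spectra as a sum of Gaussian peaks times a
#' per-replicate multiplicative factor, plus a random polynomial baseline
#' and white noise.  One peak's amplitude may be linked to the response via
#' its `amplitude` function, making that spectral region the only
#' informative one (the planted-signal fixture for the importance module).
#'
#' @param n_samples number of distinct samples.
#' @param n_replicates replicate spectra per sample.
#' @param wn_range numeric length-2 wavenumber range; descending order
#'   (e.g. `c(1800, 700)`) follows FT-IR convention.
#' @param n_points number of wavenumber grid points.
#' @param peaks list of peaks, each `list(center=, width=, amplitude=)`;
#'   `amplitude` is either a constant or a `function(y)` linking the peak
#'   height to the response.
#' @param response_range range from which sample responses are drawn
#'   uniformly.
#' @param multiplicative_range range of the per-replicate multiplicative
#'   scattering factor `b`.
#' @param baseline_poly_order order of the random per-replicate polynomial
#'   baseline (coefficients drawn from `Normal(0, baseline_sd^2)`).
#' @param baseline_sd scale of baseline coefficients.
#' @param noise_sd white-noise standard deviation.
#' @param seed integer seed.
#' @return `hc_dataset` with one row per replicate, `replicate_id` set and
#'   `sample_ids` repeating per sample.
#' @export
make_synthetic_spectra <- function(n_samples = 60, n_replicates = 3,
                                   wn_range = c(1800, 700), n_points = 300,
                                   peaks = list(
                                     list(center = 1650, width = 25, amplitude = 1),
                                     list(center = 1400, width = 20,
                                          amplitude = function(y) 0.2 + 0.8 * y),
                                     list(center = 1100, width = 30, amplitude = 0.5)),
                                   response_range = c(0, 1),
                                   multiplicative_range = c(0.7, 1.3),
                                   baseline_poly_order = 2, baseline_sd = 0.05,
                                   noise_sd = 0, seed = 1L) {
  axis <- seq(wn_range[1], wn_range[2], length.out = n_points)
  lo <- min(wn_range); hi <- max(wn_range)
  for (p in peaks)
    if (p$center < lo || p$center > hi)
      stop(sprintf("peak centre %g outside wavenumber range", p$center))
  set.seed(seed)
  y <- runif(n_samples, response_range[1], response_range[2])
  n_rows <- n_samples * n_replicates
  lambda <- (axis - mean(axis)) / (diff(range(axis)) / 2)  # axis in [-1, 1]
  X <- matrix(0, n_rows, n_points)
  row <- 0L
  for (i in seq_len(n_samples)) {
    pure <- rep(0, n_points)
    for (p in peaks) {
      amp <- if (is.function(p$amplitude)) p$amplitude(y[i]) else p$amplitude
      pure <- pure + amp * exp(-(axis - p$center)^2 / (2 * p$width^2))
    }
    for (r in seq_len(n_replicates)) {
      row <- row + 1L
      b <- runif(1, multiplicative_range[1], multiplicative_range[2])
      baseline <- rep(0, n_points)
      if (baseline_poly_order >= 0) {
        coefs <- rnorm(baseline_poly_order + 1, sd = baseline_sd)
        for (q in 0:baseline_poly_order)
          baseline <- baseline + coefs[q + 1] * lambda^q
      }
      X[row, ] <- b * pure + baseline +
        if (noise_sd > 0) rnorm(n_points, sd = noise_sd) else 0
    }
  }
  hc_dataset(X, Y = rep(y, each = n_replicates), feature_axis = axis,
             sample_ids = rep(seq_len(n_samples), each = n_replicates),
             replicate_id = rep(seq_len(n_replicates), times = n_samples))
}

#' Seeded 50/50 train/test split
#'
#' @param dataset an `hc_dataset`.
#' @param frac_train fraction of samples assigned to training.
#' @param seed integer seed.
#' @return list with `train` and `test` datasets.
#' @export
split_train_test <- function(dataset, frac_train = 0.5, seed = 1L) {
  n <- nrow(dataset$X)
  set.seed(seed)
  idx <- sample.int(n, size = floor(n * frac_train))
  list(train = subset_dataset(dataset, idx),
       test = subset_dataset(dataset, setdiff(seq_len(n), idx)))
}

#' Row-subset a dataset
#' @param dataset an `hc_dataset`.
#' @param idx integer row indices.
#' @return the subset `hc_dataset`.
#' @export
subset_dataset <- function(dataset, idx) {
  hc_dataset(dataset$X[idx, , drop = FALSE],
             Y = if (!is.null(dataset$Y)) dataset$Y[idx, , drop = FALSE],
             feature_axis = dataset$feature_axis,
             sample_ids = dataset$sample_ids[idx],
             true_cluster = dataset$true_cluster[idx],
             replicate_id = dataset$replicate_id[idx])
}
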