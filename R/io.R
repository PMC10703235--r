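#' Delimited-table input/output
#'
#' Datasets travel as flat tables: leading columns `sample_id`, optional
#' `replicate_id`, optional `true_cluster`, the response column(s), then
#' one column per feature named by its feature-axis value.
#'
#' @name io
NULL

#' Write a dataset as a delimited table
#' @param dataset an `hc_dataset`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  df <- data.frame(sample_id = dataset$sample_ids)
  if (!is.null(dataset$replicate_id)) df$replicate_id <- dataset$replicate_id
  if (!is.null(dataset$true_cluster)) df$true_cluster <- dataset$true_cluster
  if (!is.null(dataset$Y))
    for (j in seq_len(ncol(dataset$Y)))
      df[[if (ncol(dataset$Y) == 1) "response" else paste0("response", j)]] <-
        dataset$Y[, j]
  feat <- as.data.frame(dataset$X)
  names(feat) <- format(dataset$feature_axis, trim = TRUE)
  write.csv(cbind(df, feat), path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#' @param path CSV path.
#' @return an `hc_dataset`.
#' @export
read_dataset <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta <- intersect(c("sample_id", "replicate_id", "true_cluster"), names(df))
  resp <- grep("^response", names(df), value = TRUE)
  feat_cols <- setdiff(names(df), c(meta, resp))
  axis <- suppressWarnings(as.numeric(feat_cols))
  if (anyNA(axis)) axis <- seq_along(feat_cols)
  hc_dataset(as.matrix(df[feat_cols]),
             Y = if (length(resp)) as.matrix(df[resp]),
             feature_axis = axis,
             sample_ids = df$sample_id,
             true_cluster = df$true_cluster,
             replicate_id = df$replicate_id)
}

#' Export PLS loadings keyed by the feature axis
#' @param model a `pls_model`.
#' @param feature_axis feature coordinates (defaults to indices).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_loadings <- function(model, feature_axis = NULL, path) {
  stopifnot(inherits(model, "pls_model"))
  if (is.null(feature_axis)) feature_axis <- seq_len(nrow(model$P))
  df <- data.frame(feature_axis = feature_axis)
  for (a in seq_len(model$n_components)) df[[paste0("PC", a)]] <- model$P[, a]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a fitted model
#'
#' Models round-trip through `saveRDS`/`readRDS`; predictions after a
#' round trip are bit-identical.
#'
#' @param model any fitted object from this package.
#' @param path file path.
#' @return `save_model`: the path, invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
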