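# Supervised counterpart to the PCA overview: a random-forest classifier of
# treatment vs control, whose out-of-bag permutation importance (mean
# decrease accuracy, MDA) ranks metabolites by how much they carry the group
# separation, and whose tree-proximity matrix gives an ordination of the
# samples via classical multidimensional scaling.

#' Random-forest classification of samples with MDA importance
#'
#' Fits a random forest (bootstrap per tree, sqrt(m) candidate features per
#' split, Gini impurity) to the metabolite-ratio profiles via the
#' randomForest package. Reports the out-of-bag (OOB) error, per-metabolite
#' mean decrease accuracy (the drop in OOB accuracy when that metabolite's
#' values are permuted, averaged over trees, unscaled), the sample proximity
#' matrix (fraction of trees placing two samples in the same terminal node),
#' and a two-dimensional classical MDS embedding of `1 - proximity`.
#'
#' @param ratio_tbl Imputed long ratio table ([impute_missing()]).
#' @param n_trees Number of trees (>= 100). Default 500.
#' @param seed Integer seed; the fit is fully deterministic given it.
#' @param mtry Candidate features per split; default `floor(sqrt(m))`.
#' @param log_transform Use log2 ratios (default `TRUE`).
#' @return An object of class `iroa_rf`: list with `oob_error`, `votes`,
#'   `proximity`, `mds` (tibble `sample_id`, `group`, `mds1`, `mds2`),
#'   `importance` (tibble `row_id`, `mda`, `direction`), `n_trees`, `mtry`,
#'   `seed`, and the underlying `forest`.
#' @export
rf_classify <- function(ratio_tbl, n_trees = 500L, seed = 1L, mtry = NULL,
                        log_transform = TRUE) {
  if (n_trees < 100L) rlang::abort("`n_trees` must be >= 100")
  X <- ratio_matrix(ratio_tbl, log_transform = log_transform)
  groups <- dplyr::distinct(ratio_tbl, .data$sample_id, .data$group)
  g <- factor(groups$group[match(rownames(X), groups$sample_id)],
              levels = c("control", "treatment"))
  if (any(table(g) < 3L)) rlang::abort("need >= 3 samples per group")
  features <- colnames(X)
  Xdf <- as.data.frame(X)
  colnames(Xdf) <- make.names(features)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(Xdf))))
  set.seed(as.integer(seed))
  forest <- randomForest::randomForest(
    x = Xdf, y = g, ntree = as.integer(n_trees), mtry = mtry,
    importance = TRUE, proximity = TRUE
  )
  oob_error <- unname(forest$err.rate[n_trees, "OOB"])
  prox <- forest$proximity
  dimnames(prox) <- list(rownames(X), rownames(X))
  mds_xy <- stats::cmdscale(stats::as.dist(1 - prox), k = 2)
  mds <- tibble::tibble(sample_id = rownames(X),
                        group = as.character(g),
                        mds1 = mds_xy[, 1], mds2 = mds_xy[, 2])
  mda <- randomForest::importance(forest, type = 1, scale = FALSE)[, 1]
  direction <- vapply(seq_along(features), function(j) {
    d <- mean(X[g == "treatment", j]) - mean(X[g == "control", j])
    if (d >= 0) "increase" else "decrease"
  }, character(1))
  importance <- tibble::tibble(row_id = features, mda = unname(mda),
                               direction = direction)
  structure(list(
    oob_error = oob_error, votes = forest$votes, proximity = prox,
    mds = mds, importance = importance,
    n_trees = as.integer(n_trees), mtry = mtry, seed = as.integer(seed),
    forest = forest
  ), class = "iroa_rf")
}

#' @export
print.iroa_rf <- function(x, ...) {
  cat(sprintf("<iroa_rf> %d trees, mtry %d, OOB error %.3f\n",
              x$n_trees, x$mtry, x$oob_error))
  invisible(x)
}

#' @rdname rf_classify
#' @param x An `iroa_rf` object.
#' @param ... Unused.
#' @method tidy iroa_rf
#' @export
tidy.iroa_rf <- function(x, ...) dplyr::arrange(x$importance,
                                                dplyr::desc(.data$mda),
                                                .data$row_id)

#' @rdname rf_classify
#' @method glance iroa_rf
#' @export
glance.iroa_rf <- function(x, ...) {
  tibble::tibble(oob_error = x$oob_error, n_trees = x$n_trees,
                 mtry = x$mtry, n_samples = nrow(x$proximity),
                 n_metabolites = nrow(x$importance), seed = x$seed)
}

#' Metabolites most important for the group separation
#'
#' @param rf An `iroa_rf` object from [rf_classify()].
#' @param k Number of metabolites to return (ties broken by `row_id`).
#' @return The top `k` rows of the importance table, sorted by descending
#'   mean decrease accuracy, with the direction of change (increase or
#'   decrease under treatment).
#' @export
top_importance <- function(rf, k = 40L) {
  stopifnot(inherits(rf, "iroa_rf"), k >= 0,
            k <= nrow(rf$importance))
  utils::head(tidy(rf), k)
}
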