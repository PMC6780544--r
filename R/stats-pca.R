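# Unsupervised overview of the ratio matrix: samples in metabolite space.
# Autoscaling (unit variance per metabolite) is the default so that abundant
# metabolites do not dominate the ordination.

#' Principal component analysis of samples in metabolite-ratio space
#'
#' @param ratio_tbl Imputed long ratio table ([impute_missing()]).
#' @param scaling `"autoscale"` (center and unit variance, default) or
#'   `"center"`.
#' @param log_transform Analyse log2 ratios (default `TRUE`).
#' @param n_components Number of components to keep; truncated to the rank
#'   with a warning when larger. Default: all.
#' @return An object of class `iroa_pca`: list with `scores` (tibble
#'   `sample_id`, `group`, `PC1`, ...), `loadings` (metabolites x
#'   components), `var_frac` (non-increasing variance fractions), `scaling`,
#'   `dropped` (constant metabolites removed under autoscaling). Component
#'   signs are fixed so each loading vector's largest-magnitude entry is
#'   positive.
#' @export
pca_samples <- function(ratio_tbl, scaling = c("autoscale", "center"),
                        log_transform = TRUE, n_components = NULL) {
  scaling <- match.arg(scaling)
  X <- ratio_matrix(ratio_tbl, log_transform = log_transform)
  if (nrow(X) < 3L) rlang::abort("PCA needs at least 3 samples")
  dropped <- character(0)
  if (scaling == "autoscale") {
    sds <- apply(X, 2L, stats::sd)
    dropped <- colnames(X)[sds == 0]
    if (length(dropped) > 0) {
      rlang::inform(sprintf("dropping %d constant metabolite(s) under autoscaling",
                            length(dropped)))
      X <- X[, sds > 0, drop = FALSE]
    }
  }
  fit <- stats::prcomp(X, center = TRUE, scale. = scaling == "autoscale")
  rank <- sum(fit$sdev > max(fit$sdev) * 1e-12)
  k <- min(rank, ncol(fit$rotation))
  if (!is.null(n_components)) {
    if (n_components > k) {
      rlang::warn(sprintf("requested %d components but rank is %d; truncating",
                          n_components, k))
    }
    k <- min(k, n_components)
  }
  # deterministic component orientation
  for (j in seq_len(ncol(fit$rotation))) {
    piv <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[piv, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  var_frac <- fit$sdev^2 / sum(fit$sdev^2)
  groups <- dplyr::distinct(ratio_tbl, .data$sample_id, .data$group)
  scores <- tibble::as_tibble(fit$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(X)), scores)
  scores <- dplyr::left_join(scores, groups, by = "sample_id")
  scores <- dplyr::relocate(scores, "sample_id", "group")
  structure(list(
    scores = scores,
    loadings = fit$rotation[, seq_len(k), drop = FALSE],
    var_frac = var_frac[seq_len(k)],
    sdev = fit$sdev,
    center = fit$center, scale = fit$scale,
    scaling = scaling, dropped = dropped, fit = fit
  ), class = "iroa_pca")
}

# samples x metabolites matrix from the long ratio table
ratio_matrix <- function(ratio_tbl, log_transform = TRUE) {
  if (anyNA(ratio_tbl$ratio)) {
    rlang::abort("ratio table has missing cells; run impute_missing() first")
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(ratio_tbl, "row_id", "sample_id", "ratio"),
    names_from = "row_id", values_from = "ratio"
  )
  X <- as.matrix(wide[-1])
  rownames(X) <- wide$sample_id
  if (log_transform) X <- log2(X)
  X
}

#' @export
print.iroa_pca <- function(x, ...) {
  cat(sprintf("<iroa_pca> %d samples x %d metabolites, %s scaling\n",
              nrow(x$scores), nrow(x$loadings), x$scaling))
  cat("variance fractions:",
      paste(sprintf("%.3f", utils::head(x$var_frac, 5)), collapse = " "), "\n")
  invisible(x)
}

#' @rdname pca_samples
#' @param x An `iroa_pca` object.
#' @param ... Unused.
#' @method tidy iroa_pca
#' @export
tidy.iroa_pca <- function(x, ...) x$scores

#' @rdname pca_samples
#' @method glance iroa_pca
#' @export
glance.iroa_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_metabolites = nrow(x$loadings),
    n_components = length(x$var_frac),
    var_pc1 = x$var_frac[1],
    var_pc2 = if (length(x$var_frac) >= 2) x$var_frac[2] else NA_real_,
    cum_var_2 = sum(utils::head(x$var_frac, 2))
  )
}
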