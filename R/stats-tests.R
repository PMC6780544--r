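# Row-wise univariate comparison of treatment vs control ratio profiles.
# The ratios are right-skewed, so tests default to the log2 scale. The
# pooled-variance Student test is the default variant; Welch is a flag.
# Raw p-values are the primary filter (no correction), with Benjamini-
# Hochberg q-values reported alongside.

#' Row-wise unpaired two-sample t-tests on sample:IS ratios
#'
#' @param ratio_tbl Long ratio table with `row_id`, `sample_id`, `group`,
#'   `ratio` (imputed, no missing cells).
#' @param log_transform Test on log2 ratios (default `TRUE`).
#' @param var_equal Pooled-variance Student test (default `TRUE`); `FALSE`
#'   gives Welch.
#' @param adjust Multiple-testing adjustment for the `q` column, passed to
#'   [stats::p.adjust()]. Default `"BH"`.
#' @return A tibble with one row per metabolite: `row_id`, `estimate`
#'   (difference of group means on the tested scale, treatment minus
#'   control), `t`, `df`, `p`, `q`, `degenerate` (zero pooled variance).
#'   The sign of `t` matches the sign of `estimate`.
#' @export
unpaired_t_test <- function(ratio_tbl, log_transform = TRUE, var_equal = TRUE,
                            adjust = "BH") {
  stopifnot(all(c("row_id", "sample_id", "group", "ratio") %in% names(ratio_tbl)))
  if (anyNA(ratio_tbl$ratio)) {
    rlang::abort("ratio table has missing cells; run impute_missing() first")
  }
  check_two_groups(ratio_tbl, min_per_group = 2L)
  values <- if (log_transform) log2(ratio_tbl$ratio) else ratio_tbl$ratio
  split_rows <- split(
    data.frame(value = values, group = ratio_tbl$group),
    ratio_tbl$row_id
  )
  rows <- lapply(names(split_rows), function(id) {
    d <- split_rows[[id]]
    x <- d$value[d$group == "treatment"]
    y <- d$value[d$group == "control"]
    est <- mean(x) - mean(y)
    res <- tryCatch(
      stats::t.test(x, y, var.equal = var_equal),
      error = function(e) NULL
    )
    if (is.null(res)) {
      # zero pooled variance: identical means are indistinguishable (p = 1),
      # different means are separated with certainty (p -> 0)
      if (isTRUE(all.equal(est, 0)) || est == 0) {
        tibble::tibble(row_id = id, estimate = 0, t = 0,
                       df = length(x) + length(y) - 2, p = 1, degenerate = TRUE)
      } else {
        tibble::tibble(row_id = id, estimate = est, t = sign(est) * Inf,
                       df = length(x) + length(y) - 2, p = 0, degenerate = TRUE)
      }
    } else {
      tibble::tibble(row_id = id, estimate = est,
                     t = unname(res$statistic), df = unname(res$parameter),
                     p = res$p.value, degenerate = FALSE)
    }
  })
  out <- purrr::list_rbind(rows)
  out$q <- stats::p.adjust(out$p, method = adjust)
  dplyr::relocate(out, "row_id", "estimate", "t", "df", "p", "q", "degenerate")
}
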