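# Sample:IS ratio quantitation. The pooled internal standard carries a heavy
# isotope of every metabolite from any group, so the ratio
# area_sample / area_is cancels extraction and injection variability, and a
# metabolite absent from one group still has an IS denominator — which is
# what makes "initiated" and "terminated" calls possible at all.

#' Sample-to-internal-standard ratios from an aligned pair table
#'
#' One cell per (metabolite row, run): `area_sample / area_is` when both
#' areas reach the limit of quantitation, otherwise missing. A row whose IS
#' area is below `loq` in at least half of the runs where the pair was
#' detected is flagged unquantifiable (`quantifiable = FALSE`); its cells are
#' kept but downstream imputation drops the row.
#'
#' @param pair_table Long aligned table from [align_pairs_across_samples()].
#' @param design A data frame `sample_id`, `group` with `group` in
#'   `"treatment"` / `"control"`. Every run in `pair_table` must appear.
#' @param loq Limit of quantitation on peak areas. Default 0 (everything
#'   detected is quantifiable).
#' @return A long tibble with one row per (metabolite, sample):
#'   `row_id`, `sample_id`, `group`, `area_sample`, `area_is`, `ratio`
#'   (`NA` when missing), `observed`, `quantifiable`.
#' @export
compute_ratios <- function(pair_table, design, loq = 0) {
  stopifnot(loq >= 0, all(c("sample_id", "group") %in% names(design)))
  design <- dplyr::mutate(tibble::as_tibble(design),
                          group = as.character(.data$group))
  bad <- setdiff(design$group, c("treatment", "control"))
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown group label(s): %s", paste(bad, collapse = ", ")))
  }
  missing_runs <- setdiff(unique(pair_table$sample_id), design$sample_id)
  if (length(missing_runs) > 0) {
    rlang::abort(sprintf("runs missing from design: %s",
                         paste(missing_runs, collapse = ", ")))
  }
  cells <- dplyr::select(pair_table, "row_id", "sample_id",
                         "area_sample", "area_is")
  grid <- tidyr::expand_grid(row_id = unique(pair_table$row_id),
                             sample_id = design$sample_id)
  cells <- dplyr::left_join(grid, cells, by = c("row_id", "sample_id"))
  cells <- dplyr::left_join(cells, design, by = "sample_id")
  cells <- dplyr::mutate(
    cells,
    ratio = dplyr::if_else(
      !is.na(.data$area_sample) & !is.na(.data$area_is) &
        .data$area_sample >= loq & .data$area_is >= loq & .data$area_is > 0,
      .data$area_sample / .data$area_is, NA_real_),
    observed = !is.na(.data$ratio)
  )
  cells <- dplyr::mutate(
    dplyr::group_by(cells, .data$row_id),
    quantifiable = {
      detected <- !is.na(.data$area_is)
      sum(detected & .data$area_is < loq) < pmax(1, sum(detected)) / 2
    }
  )
  dplyr::relocate(dplyr::ungroup(cells), "row_id", "sample_id", "group")
}

#' Impute missing ratio cells
#'
#' Each missing cell of a row is replaced by half the row's minimum observed
#' ratio — a left-censoring surrogate for signals below the limit of
#' quantitation. Rows with no observed cell at all, and rows flagged
#' unquantifiable, are dropped with a message.
#'
#' @param ratio_tbl Long ratio table from [compute_ratios()].
#' @return The table with `ratio` complete and a logical `imputed` column;
#'   the original missingness is preserved in `observed`.
#' @export
impute_missing <- function(ratio_tbl) {
  stopifnot(all(c("row_id", "ratio", "observed") %in% names(ratio_tbl)))
  if (!is.null(ratio_tbl$quantifiable)) {
    drop <- unique(ratio_tbl$row_id[!ratio_tbl$quantifiable])
    if (length(drop) > 0) {
      rlang::inform(sprintf("dropping %d unquantifiable row(s) (IS below LOQ in half the detected runs)",
                            length(drop)))
      ratio_tbl <- dplyr::filter(ratio_tbl, .data$quantifiable)
    }
  }
  empty <- dplyr::group_by(ratio_tbl, .data$row_id)
  empty <- dplyr::filter(dplyr::summarise(empty, any_obs = any(.data$observed)),
                         !.data$any_obs)$row_id
  if (length(empty) > 0) {
    rlang::inform(sprintf("dropping %d fully missing row(s)", length(empty)))
    ratio_tbl <- dplyr::filter(ratio_tbl, !.data$row_id %in% empty)
  }
  if (nrow(ratio_tbl) == 0L) {
    return(dplyr::mutate(ratio_tbl, imputed = logical(0)))
  }
  out <- dplyr::mutate(
    dplyr::group_by(ratio_tbl, .data$row_id),
    ratio = dplyr::if_else(is.na(.data$ratio),
                           min(.data$ratio, na.rm = TRUE) / 2, .data$ratio),
    imputed = !.data$observed
  )
  dplyr::ungroup(out)
}

#' Per-metabolite log2 fold change of treatment versus control ratios
#'
#' `log2(mean treatment ratio / mean control ratio)`, on arithmetic means by
#' default (a geometric-mean variant is available).
#'
#' @param ratio_tbl Imputed long ratio table ([impute_missing()]).
#' @param method `"arithmetic"` (default) or `"geometric"` group means.
#' @return A tibble `row_id`, `mean_treatment`, `mean_control`, `log2fc`.
#' @export
log2_fold_change <- function(ratio_tbl, method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  if (anyNA(ratio_tbl$ratio)) {
    rlang::abort("ratio table has missing cells; run impute_missing() first")
  }
  check_two_groups(ratio_tbl, min_per_group = 2L)
  avg <- if (method == "arithmetic") mean else function(x) exp(mean(log(x)))
  out <- dplyr::summarise(
    dplyr::group_by(ratio_tbl, .data$row_id),
    mean_treatment = avg(.data$ratio[.data$group == "treatment"]),
    mean_control = avg(.data$ratio[.data$group == "control"]),
    .groups = "drop"
  )
  stopifnot(all(out$mean_treatment > 0), all(out$mean_control > 0))
  dplyr::mutate(out, log2fc = log2(.data$mean_treatment / .data$mean_control))
}

check_two_groups <- function(ratio_tbl, min_per_group = 2L) {
  counts <- dplyr::distinct(ratio_tbl, .data$sample_id, .data$group)
  counts <- table(counts$group)
  if (!all(c("treatment", "control") %in% names(counts)) ||
      any(counts[c("treatment", "control")] < min_per_group)) {
    rlang::abort(sprintf("need >= %d samples in each of treatment and control",
                         min_per_group))
  }
  invisible(TRUE)
}

#' Classify the regulation of each metabolite
#'
#' `initiated`: every control cell was imputed from missing while the
#' metabolite was observed under treatment (the pair exists only in
#' treatment runs, so its production started with the treatment);
#' `terminated` is the mirror image. Otherwise `upregulated` /
#' `downregulated` when `|log2fc| >= fc_threshold` and `p <= alpha`, else
#' `unchanged`.
#'
#' @param ratio_tbl Imputed long ratio table ([impute_missing()]).
#' @param tests Optional per-row test table with columns `row_id`, `p`
#'   (e.g. from [unpaired_t_test()]); computed internally when `NULL`.
#' @param fc_threshold Absolute log2 fold-change threshold. Default 1
#'   (two-fold).
#' @param alpha p-value threshold. Default 0.001.
#' @return A tibble `row_id`, `category`, `log2fc`, `p_value` with
#'   `category` a factor with levels initiated, terminated, upregulated,
#'   downregulated, unchanged.
#' @export
classify_regulation <- function(ratio_tbl, tests = NULL, fc_threshold = 1,
                                alpha = 0.001) {
  if (is.null(ratio_tbl$imputed)) {
    rlang::abort("ratio table must be imputed first (impute_missing())")
  }
  if (is.null(tests)) tests <- unpaired_t_test(ratio_tbl)
  fc <- log2_fold_change(ratio_tbl)
  onoff <- dplyr::summarise(
    dplyr::group_by(ratio_tbl, .data$row_id),
    ctrl_all_missing = all(.data$imputed[.data$group == "control"]),
    trt_all_missing = all(.data$imputed[.data$group == "treatment"]),
    ctrl_any_obs = any(.data$observed[.data$group == "control"]),
    trt_any_obs = any(.data$observed[.data$group == "treatment"]),
    .groups = "drop"
  )
  out <- dplyr::left_join(fc, dplyr::select(tests, "row_id", "p"), by = "row_id")
  out <- dplyr::left_join(out, onoff, by = "row_id")
  out <- dplyr::mutate(
    out,
    category = dplyr::case_when(
      .data$ctrl_all_missing & .data$trt_any_obs ~ "initiated",
      .data$trt_all_missing & .data$ctrl_any_obs ~ "terminated",
      .data$log2fc >= fc_threshold & .data$p <= alpha ~ "upregulated",
      .data$log2fc <= -fc_threshold & .data$p <= alpha ~ "downregulated",
      TRUE ~ "unchanged"
    ),
    category = factor(.data$category,
                      levels = c("initiated", "terminated", "upregulated",
                                 "downregulated", "unchanged"))
  )
  dplyr::select(out, "row_id", "category", "log2fc", p_value = "p")
}

#' Extract a targeted compound panel from an IROA dataset
#'
#' For each panel entry (a named formula with candidate adducts), searches
#' the aligned pair table for rows whose carbon count equals the formula's
#' and whose consensus `mz12` matches the adduct m/z within `tol_ppm`, and
#' reports the treatment-versus-control log2 fold change. Entries with no
#' matching row are reported `found = FALSE` — the pathway member was not
#' detected.
#'
#' @param pair_table Aligned table from [align_pairs_across_samples()].
#' @param panel A data frame `name`, `formula`, `adducts` (semicolon-
#'   separated adduct names), and optionally `pathway_position`.
#' @param ratio_tbl Imputed long ratio table for the same dataset.
#' @param tol_ppm Mass tolerance (ppm of m/z). Default 10.
#' @return A tibble `name`, `formula`, `carbon_count`, `adduct`, `found`,
#'   `row_id`, `mass_error_ppm`, `log2fc` (plus `pathway_position` when
#'   given), one row per panel entry (best match across its adducts).
#' @export
targeted_extract <- function(pair_table, panel, ratio_tbl, tol_ppm = 10) {
  stopifnot(all(c("name", "formula", "adducts") %in% names(panel)))
  features <- pair_features(pair_table)
  fc <- log2_fold_change(ratio_tbl)
  panel <- dplyr::mutate(tibble::as_tibble(panel),
                         carbon_count = parse_formula(.data$formula)$C,
                         neutral_mass = monoisotopic_mass(.data$formula))
  rows <- purrr::pmap(panel, function(name, formula, adducts, carbon_count,
                                      neutral_mass, ...) {
    extras <- list(...)
    adduct_names <- stringr::str_trim(stringr::str_split_1(adducts, ";"))
    hits <- purrr::map(adduct_names, function(ad) {
      a <- resolve_adduct(ad)
      mz <- adduct_mz(neutral_mass, a)
      pol <- a$polarity
      cand <- dplyr::filter(features, .data$carbon_count == !!carbon_count,
                            .data$polarity == pol,
                            abs(.data$mz12 - mz) <= tol_ppm * 1e-6 * mz)
      if (nrow(cand) == 0) return(NULL)
      if (nrow(cand) > 1) {
        rlang::inform(sprintf("targeted panel '%s': %d candidate rows, keeping closest m/z",
                              name, nrow(cand)))
      }
      cand <- dplyr::mutate(cand, mass_error_ppm = (.data$mz12 - mz) / mz * 1e6,
                            adduct = ad)
      dplyr::slice_min(cand, abs(.data$mass_error_ppm), n = 1, with_ties = FALSE)
    })
    hits <- purrr::list_rbind(purrr::compact(hits))
    base <- tibble::tibble(name = name, formula = formula,
                           carbon_count = carbon_count)
    if (!is.null(extras$pathway_position)) {
      base$pathway_position <- extras$pathway_position
    }
    if (nrow(hits) == 0) {
      return(dplyr::mutate(base, adduct = NA_character_, found = FALSE,
                           row_id = NA_character_, mass_error_ppm = NA_real_))
    }
    best <- dplyr::slice_min(hits, abs(.data$mass_error_ppm), n = 1,
                             with_ties = FALSE)
    dplyr::mutate(base, adduct = best$adduct, found = TRUE,
                  row_id = best$row_id, mass_error_ppm = best$mass_error_ppm)
  })
  out <- purrr::list_rbind(rows)
  dplyr::left_join(out, dplyr::select(fc, "row_id", "log2fc"), by = "row_id")
}
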