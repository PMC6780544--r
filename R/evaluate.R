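# Scoring of detection results against a simulated study's ground truth:
# which true metabolites were recovered, were their carbon counts read
# correctly, and did any artifact peak leak into a pair.

#' Score a detected pair table against simulated ground truth
#'
#' A true metabolite counts as detectable when at least one run has both its
#' channel areas at or above `detect_factor * loq`. It is recovered when some
#' aligned row falls within `ppm_tol` / `rt_tol` of its monoisotopic m/z and
#' retention time (no carbon gate, so mis-read carbon counts are visible);
#' the carbon count is correct when the closest such row reports the true
#' value. Artifact leakage counts artifact peaks appearing inside any pair.
#'
#' @param study An `iroa_study` from [simulate_iroa_study()].
#' @param pair_table Aligned table from [detect_pairs()] run on
#'   `study$peaks`.
#' @param ppm_tol,rt_tol Match windows for truth lookup (defaults 20 ppm,
#'   15 s, generous against the generator's injected noise).
#' @param detect_factor Detectability threshold as a multiple of the study's
#'   LOQ. Default 10.
#' @return A list with `per_metabolite` (tibble `metabolite_id`,
#'   `detectable`, `recovered`, `carbon_ok`) and `summary` (tibble
#'   `n_detectable`, `recovery_rate`, `carbon_accuracy`,
#'   `artifact_peaks_in_pairs`).
#' @export
evaluate_detection <- function(study, pair_table, ppm_tol = 20, rt_tol = 15,
                               detect_factor = 10) {
  stopifnot(inherits(study, "iroa_study"))
  loq <- study$config$loq
  detectable <- dplyr::summarise(
    dplyr::group_by(study$channel_areas, .data$metabolite_id),
    detectable = any(.data$area_sample >= detect_factor * loq &
                       .data$area_is >= detect_factor * loq),
    .groups = "drop"
  )
  feats <- pair_features(pair_table)
  tr <- study$truth
  per <- purrr::map(seq_len(nrow(tr)), function(i) {
    d_ppm <- abs(feats$mz12 - tr$mono12_mz[i]) / tr$mono12_mz[i] * 1e6
    d_rt <- abs(feats$rt - tr$rt[i])
    hit <- which(d_ppm <= ppm_tol & d_rt <= rt_tol)
    if (length(hit) == 0L) {
      return(tibble::tibble(metabolite_id = tr$metabolite_id[i],
                            recovered = FALSE, carbon_ok = NA))
    }
    best <- hit[which.min(d_ppm[hit])]
    tibble::tibble(metabolite_id = tr$metabolite_id[i], recovered = TRUE,
                   carbon_ok = feats$carbon_count[best] == tr$carbon_count[i])
  })
  per <- dplyr::left_join(detectable, purrr::list_rbind(per),
                          by = "metabolite_id")
  art_ids <- study$peaks$peak_id[study$peaks$channel == "artifact"]
  leaked <- sum(unlist(pair_table$peak_ids) %in% art_ids)
  det <- dplyr::filter(per, .data$detectable)
  summary <- tibble::tibble(
    n_detectable = nrow(det),
    recovery_rate = mean(det$recovered),
    carbon_accuracy = mean(det$carbon_ok[det$recovered]),
    artifact_peaks_in_pairs = leaked
  )
  list(per_metabolite = per, summary = summary)
}

#' Compare estimated and true log2 fold changes of a simulated study
#'
#' Joins the per-row fold-change estimates to ground truth by m/z and
#' retention time and reports the RMSE over metabolites with a defined true
#' fold change (up/down/unchanged; on/off metabolites have none), plus the
#' sensitivity of initiated/terminated calls for the on/off metabolites.
#'
#' @param study An `iroa_study`.
#' @param pair_table Aligned table from [detect_pairs()].
#' @param regulation Output of [classify_regulation()] for the same data.
#' @param fc Output of [log2_fold_change()] for the same data.
#' @param ppm_tol,rt_tol Truth-match windows, as in [evaluate_detection()].
#' @return A tibble `n_matched`, `rmse_log2fc`, `onoff_sensitivity`.
#' @export
evaluate_quantification <- function(study, pair_table, regulation, fc,
                                    ppm_tol = 20, rt_tol = 15) {
  feats <- pair_features(pair_table)
  tr <- study$truth
  match_row <- purrr::map_chr(seq_len(nrow(tr)), function(i) {
    d_ppm <- abs(feats$mz12 - tr$mono12_mz[i]) / tr$mono12_mz[i] * 1e6
    d_rt <- abs(feats$rt - tr$rt[i])
    hit <- which(d_ppm <= ppm_tol & d_rt <= rt_tol &
                   feats$carbon_count == tr$carbon_count[i])
    if (length(hit) == 0L) NA_character_ else feats$row_id[hit[which.min(d_ppm[hit])]]
  })
  tr$row_id <- match_row
  joined <- dplyr::inner_join(
    dplyr::select(tr, "metabolite_id", "row_id", "category", "true_log2fc"),
    dplyr::select(fc, "row_id", "log2fc"), by = "row_id")
  cont <- dplyr::filter(joined, !is.na(.data$true_log2fc))
  rmse <- sqrt(mean((cont$log2fc - cont$true_log2fc)^2))
  # sensitivity over all detectable on/off metabolites: an undetected one is
  # a miss, not a dropped case
  loq <- study$config$loq
  detectable <- dplyr::summarise(
    dplyr::group_by(study$channel_areas, .data$metabolite_id),
    detectable = any(.data$area_sample >= 10 * loq & .data$area_is >= 10 * loq),
    .groups = "drop"
  )
  onoff <- dplyr::filter(tr, .data$category %in% c("on", "off"))
  onoff <- dplyr::semi_join(onoff,
                            dplyr::filter(detectable, .data$detectable),
                            by = "metabolite_id")
  onoff <- dplyr::left_join(
    dplyr::select(onoff, "metabolite_id", "row_id", "category"),
    dplyr::select(regulation, "row_id", called = "category"), by = "row_id")
  sens <- if (nrow(onoff) == 0L) NA_real_ else {
    mean(!is.na(onoff$called) &
           ((onoff$category == "on" & onoff$called == "initiated") |
              (onoff$category == "off" & onoff$called == "terminated")))
  }
  tibble::tibble(n_matched = nrow(joined), rmse_log2fc = rmse,
                 onoff_sensitivity = sens)
}
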