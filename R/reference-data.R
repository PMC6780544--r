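# Bundled reference tables.

#' Per-ionization-mode detection summary of a published dual-isotope
#' actinomycete metabolome
#'
#' Counts of IROA peak pairs and standards-library identifications per
#' electrospray mode reported for a bipyridyl-treated *Nocardiopsis
#' dassonvillei* metabolome study, bundled as reference data. ESI+ and ESI-
#' runs are tabulated separately and totalled with [mode_totals()].
#'
#' @return A tibble `esi_mode`, `peak_pairs`, `identified_metabolites`.
#' @export
reference_detection_summary <- function() {
  readr::read_csv(
    system.file("extdata", "reference_detection_summary.csv",
                package = "iroapairs", mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE
  )
}

#' Totals of a per-mode detection summary
#'
#' @param summary A data frame with an `esi_mode` column and numeric count
#'   columns, e.g. [reference_detection_summary()] or the per-mode tabulation
#'   of a detected pair table.
#' @return One-row tibble with each count column summed across modes.
#' @export
mode_totals <- function(summary) {
  dplyr::summarise(summary,
                   dplyr::across(dplyr::where(is.numeric), sum))
}

#' Example targeted panel for a diketopiperazine pathway
#'
#' Amino-acid precursors and cyclic-dipeptide products of a
#' nocazine-family pathway, with candidate adducts, for use with
#' [targeted_extract()].
#'
#' @return A tibble `name`, `formula`, `adducts`, `pathway_position`.
#' @export
dkp_panel <- function() {
  readr::read_csv(
    system.file("extdata", "dkp_panel.csv", package = "iroapairs",
                mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE
  )
}
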