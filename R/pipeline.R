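# End-to-end orchestration: read -> cluster -> classify -> pair -> align ->
# quantify -> impute -> statistics -> annotation -> targeted panel, with
# per-stage counts logged and every table written as CSV.

#' Detect and align IROA peak pairs across runs
#'
#' Runs clustering, channel classification and pairing independently per
#' (run, polarity), then aligns pairs across runs within each polarity and
#' concatenates polarities (row ids are prefixed `P`/`N`).
#'
#' @param peaks Peak tibble covering one or more runs (columns `sample_id`,
#'   `polarity`, `mz`, `rt`, `intensity`).
#' @param scheme A [labeling_scheme()].
#' @param ppm_tol,rt_tol,charges,n_range,min_score,consistency_min Tuning
#'   parameters passed to the stage functions; see
#'   [cluster_isotopologues()], [classify_cluster_channel()],
#'   [find_peak_pairs()].
#' @return Aligned long pair table (see [align_pairs_across_samples()]).
#' @export
detect_pairs <- function(peaks, scheme = labeling_scheme(), ppm_tol = 10,
                         rt_tol = 6, charges = 1L, n_range = c(2L, 36L),
                         min_score = 0.9, consistency_min = 0.95) {
  peaks <- as_peak_table(peaks)
  runs <- dplyr::group_split(dplyr::group_by(peaks, .data$sample_id,
                                             .data$polarity))
  per_run <- purrr::map(runs, function(run_peaks) {
    clusters <- cluster_isotopologues(run_peaks, ppm_tol = ppm_tol,
                                      rt_tol = rt_tol, charges = charges)
    clusters <- classify_cluster_channel(clusters, scheme = scheme,
                                         min_score = min_score,
                                         n_range = c(n_range[1], 60L))
    find_peak_pairs(clusters, scheme = scheme, ppm_tol = ppm_tol,
                    rt_tol = rt_tol, n_range = n_range,
                    consistency_min = consistency_min)
  })
  pairs <- purrr::list_rbind(per_run)
  align_pairs_across_samples(pairs, ppm_tol = ppm_tol, rt_tol = 2 * rt_tol)
}

#' Assemble a pipeline configuration
#'
#' @param peak_files Character vector of peak-list paths (TSV dialect or
#'   centroided mzML).
#' @param design_file CSV with columns `sample_id`, `group`.
#' @param out_dir Output directory for result CSVs and the run log.
#' @param ... Overrides of the defaults: `ppm_tol` (10), `rt_tol` (6),
#'   `loq` (0), `p13_sample` (0.05), `p13_is` (0.95), `n_range` (2..36),
#'   `fc_threshold` (1), `alpha` (0.001), `n_trees` (500), `seed` (1),
#'   `library_file`, `panel_file`, `library_rt_tol` (30).
#' @return A named list of class `iroa_config`.
#' @export
iroa_config <- function(peak_files = character(), design_file = NULL,
                        out_dir = "iroa_results", ...) {
  defaults <- list(
    peak_files = peak_files, design_file = design_file, out_dir = out_dir,
    ppm_tol = 10, rt_tol = 6, loq = 0,
    p13_sample = 0.05, p13_is = 0.95, n_range = c(2L, 36L),
    min_score = 0.9, consistency_min = 0.95,
    fc_threshold = 1, alpha = 0.001, n_trees = 500L, seed = 1L,
    library_file = NULL, panel_file = NULL, library_rt_tol = 30
  )
  cfg <- utils::modifyList(defaults, list(...))
  if (any(c(cfg$ppm_tol, cfg$rt_tol) <= 0)) {
    rlang::abort("tolerances must be positive")
  }
  structure(cfg, class = "iroa_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [iroa_config()].
#' @return An `iroa_config` list.
#' @export
read_iroa_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(iroa_config, raw)
}

#' Run the full IROA pipeline
#'
#' Executes read, pair detection, alignment, ratio quantitation, imputation,
#' regulation classification, t-tests, PCA, random forest, optional
#' standards-library identification and targeted panel extraction, writing
#' every result as CSV under `config$out_dir` together with a run log (seed,
#' parameters, per-stage counts) and the configuration echoed as YAML.
#'
#' @param config An `iroa_config` list or a path to a YAML config.
#' @return Invisibly, a list with the main tables (`pair_table`, `ratios`,
#'   `regulation`, `tests`, `pca`, `rf`, `identifications`, `targeted`).
#' @export
run_iroa_pipeline <- function(config) {
  if (is.character(config)) config <- read_iroa_config(config)
  stopifnot(inherits(config, "iroa_config"))
  if (length(config$peak_files) == 0L) rlang::abort("no peak files configured")
  if (is.null(config$design_file)) rlang::abort("design_file is required")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_line <- function(...) {
    msg <- sprintf(...)
    rlang::inform(msg)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  }
  cat(sprintf("iroapairs %s | %s\nseed %d\n",
              as.character(utils::packageVersion("iroapairs")),
              format(Sys.time(), "%Y-%m-%d %H:%M:%S"), config$seed),
      file = log_path)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config_echo.yaml"))

  design <- readr::read_csv(config$design_file, show_col_types = FALSE,
                            progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(design)) ||
      !all(c("treatment", "control") %in% design$group)) {
    rlang::abort("design must list sample_id,group with both treatment and control")
  }
  scheme <- labeling_scheme(config$p13_sample, config$p13_is)
  peaks <- purrr::list_rbind(purrr::map(config$peak_files, read_peaks))
  log_line("stage read: %d peaks from %d files", nrow(peaks),
           length(config$peak_files))

  pair_table <- detect_pairs(peaks, scheme = scheme, ppm_tol = config$ppm_tol,
                             rt_tol = config$rt_tol,
                             n_range = config$n_range,
                             min_score = config$min_score,
                             consistency_min = config$consistency_min)
  log_line("stage pairing: %d pair observations in %d aligned rows",
           nrow(pair_table), dplyr::n_distinct(pair_table$row_id))
  readr::write_csv(dplyr::select(pair_table, -"peak_ids"),
                   file.path(out_dir, "pair_table.csv"))

  ratios <- compute_ratios(pair_table, design, loq = config$loq)
  imputed <- impute_missing(ratios)
  log_line("stage quantify: %d rows quantified, %d cells imputed",
           dplyr::n_distinct(imputed$row_id), sum(imputed$imputed))
  readr::write_csv(imputed, file.path(out_dir, "ratios.csv"))

  tests <- unpaired_t_test(imputed)
  regulation <- classify_regulation(imputed, tests,
                                    fc_threshold = config$fc_threshold,
                                    alpha = config$alpha)
  log_line("stage stats: %d rows with p <= %g; categories %s",
           sum(tests$p <= config$alpha), config$alpha,
           paste(names(table(regulation$category)),
                 table(regulation$category), collapse = " ", sep = ":"))
  stats_tbl <- dplyr::left_join(
    dplyr::select(tests, "row_id", "t", "df", "p", "q"),
    dplyr::select(regulation, "row_id", "log2fc", "category"), by = "row_id")
  readr::write_csv(stats_tbl, file.path(out_dir, "stats.csv"))

  pca <- pca_samples(imputed)
  readr::write_csv(tidy(pca), file.path(out_dir, "pca_scores.csv"))
  readr::write_csv(tibble::tibble(component = seq_along(pca$var_frac),
                                  var_frac = pca$var_frac),
                   file.path(out_dir, "pca_variance.csv"))

  rf <- rf_classify(imputed, n_trees = config$n_trees, seed = config$seed)
  log_line("stage rf: OOB error %.3f over %d trees", rf$oob_error, rf$n_trees)
  readr::write_csv(tidy(rf), file.path(out_dir, "rf_importance.csv"))
  readr::write_csv(rf$mds, file.path(out_dir, "mds_coords.csv"))

  identifications <- NULL
  if (!is.null(config$library_file)) {
    library <- readr::read_csv(config$library_file, show_col_types = FALSE,
                               progress = FALSE)
    identifications <- library_match(pair_features(pair_table), library,
                                     tol_ppm = config$ppm_tol,
                                     rt_tol = config$library_rt_tol)
    log_line("stage identify: %d identifications over %d rows",
             nrow(identifications),
             dplyr::n_distinct(identifications$row_id))
    readr::write_csv(identifications, file.path(out_dir, "identifications.csv"))
  }
  targeted <- NULL
  if (!is.null(config$panel_file)) {
    panel <- readr::read_csv(config$panel_file, show_col_types = FALSE,
                             progress = FALSE)
    targeted <- targeted_extract(pair_table, panel, imputed,
                                 tol_ppm = config$ppm_tol)
    log_line("stage targeted: %d/%d panel entries found",
             sum(targeted$found), nrow(targeted))
    readr::write_csv(targeted, file.path(out_dir, "targeted.csv"))
  }
  log_line("pipeline complete")
  invisible(list(pair_table = pair_table, ratios = imputed, tests = tests,
                 regulation = regulation, pca = pca, rf = rf,
                 identifications = identifications, targeted = targeted,
                 design = design, config = config))
}
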