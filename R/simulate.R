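# Seeded generator of dual-labeled LC/MS centroid studies with ground truth.
#
# Emulates the dual-labeling design: treatment and control cultures grown in
# 95:5 12C:13C media (sample channel, ~5% 13C per carbon) analysed against a
# pooled 5:95-labeled internal standard spiked into every run. The IS is one
# physical mixture pooled over both groups, so its per-metabolite abundance
# is a single number shared by all runs — and a metabolite switched on or off
# by treatment still has an IS channel everywhere, which is what makes
# initiated/terminated calls observable.
#
# Both channels of one metabolite share the isotopologue m/z grid
# mono12 + k * delta_c13 (k = 0..n); for low carbon counts the two binomial
# envelopes overlap there and the generator, like a centroiding instrument,
# sums coincident contributions into one peak.

#' Bundled list of plausible CHNO metabolite formulas
#'
#' The formula pool the study generator draws from: common primary
#' metabolites, dipeptides and natural-product-like CHNO formulas spanning 2
#' to 36 carbons, so simulated masses, valences and carbon counts are
#' realistic.
#'
#' @return A tibble `name`, `formula`, `carbon_count`, `neutral_mass`.
#' @export
metabolite_formula_pool <- function() {
  path <- system.file("extdata", "metabolite_formulas.csv",
                      package = "iroapairs", mustWork = TRUE)
  pool <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  pool$carbon_count <- parse_formula(pool$formula)$C
  pool$neutral_mass <- monoisotopic_mass(pool$formula)
  pool
}

#' Simulate a dual-labeled IROA study with ground truth
#'
#' Generates centroided peak lists for `n_treatment + n_control` runs plus
#' complete ground truth. Each metabolite draws a formula from
#' [metabolite_formula_pool()], a retention time, and a lognormal base
#' abundance; treatment effects multiply the sample-channel abundance
#' (`2^effect_log2fc` up or down), `"on"` metabolites have zero control
#' abundance and `"off"` zero treatment abundance. The IS-channel abundance
#' is the pooled mean of the two group means, identical across runs up to
#' measurement noise. Both channels' binomial isotopologue envelopes are
#' emitted as centroid peaks (members below 0.5% of the channel maximum are
#' not emitted; coincident grid positions are summed), with multiplicative
#' replicate noise, m/z noise, retention-time jitter, peak-level censoring
#' below `loq`, and unpaired artifact peaks.
#'
#' @param n_metabolites Number of true metabolites. Default 200.
#' @param n_treatment,n_control Replicates per group. Default 4 and 4.
#' @param frac_up,frac_down,frac_on,frac_off Fractions of metabolites that
#'   are up-/downregulated or switched on/off by treatment; counts are
#'   `round(frac * n_metabolites)`. Defaults 0.10, 0.10, 0.05, 0.05.
#' @param effect_log2fc Absolute log2 fold change of up/down metabolites.
#'   Default 2.
#' @param abund_meanlog,abund_sdlog Lognormal base-abundance parameters (area
#'   units). Defaults 12 and 1.
#' @param replicate_cv Coefficient of variation of multiplicative replicate
#'   noise, applied to both channels. Default 0.10.
#' @param mass_noise_ppm Standard deviation of m/z noise, ppm. Default 3.
#' @param rt_jitter_sec Standard deviation of per-run retention-time jitter,
#'   seconds. Default 2.
#' @param loq Limit of quantitation; emitted peaks below it are censored.
#'   Default 1000.
#' @param artifact_rate Unpaired artifact peaks per run, as a fraction of
#'   `n_metabolites`. Default 0.1.
#' @param scheme A [labeling_scheme()].
#' @param carbon_range Allowed carbon counts of drawn formulas. Default
#'   `c(2, 36)`.
#' @param rt_range Retention-time window, seconds. Default `c(60, 840)`.
#' @param polarity Single polarity per study. Default `"positive"`.
#' @param seed Integer seed; identical seeds give identical studies.
#' @return An object of class `iroa_study`: list with `peaks` (tibble
#'   `peak_id`, `sample_id`, `polarity`, `mz`, `rt`, `intensity`, plus
#'   provenance columns `metabolite_id`, `channel`), `truth` (per-metabolite
#'   ground truth incl. `category` and `true_log2fc`), `channel_areas`
#'   (true per-run channel areas before censoring), `design`, and the echoed
#'   `config`.
#' @export
simulate_iroa_study <- function(n_metabolites = 200L,
                                n_treatment = 4L, n_control = 4L,
                                frac_up = 0.10, frac_down = 0.10,
                                frac_on = 0.05, frac_off = 0.05,
                                effect_log2fc = 2,
                                abund_meanlog = 12, abund_sdlog = 1,
                                replicate_cv = 0.10,
                                mass_noise_ppm = 3, rt_jitter_sec = 2,
                                loq = 1000, artifact_rate = 0.1,
                                scheme = labeling_scheme(),
                                carbon_range = c(2L, 36L),
                                rt_range = c(60, 840),
                                polarity = "positive",
                                seed = 1L) {
  stopifnot(n_metabolites >= 1, n_treatment >= 2, n_control >= 2,
            replicate_cv >= 0, mass_noise_ppm >= 0, rt_jitter_sec >= 0,
            loq >= 0, artifact_rate >= 0, inherits(scheme, "labeling_scheme"))
  fracs <- c(frac_up, frac_down, frac_on, frac_off)
  if (any(fracs < 0) || sum(fracs) > 1) {
    rlang::abort("category fractions must be >= 0 and sum to <= 1")
  }
  set.seed(as.integer(seed))

  pool <- metabolite_formula_pool()
  pool <- pool[pool$carbon_count >= carbon_range[1] &
                 pool$carbon_count <= carbon_range[2], ]
  if (nrow(pool) == 0L) rlang::abort("no formulas in the requested carbon range")

  n <- as.integer(n_metabolites)
  draw <- pool[sample.int(nrow(pool), n, replace = TRUE), ]
  rt <- stats::runif(n, rt_range[1], rt_range[2])
  # Chromatographic resolvability: two metabolites whose isotopologue m/z
  # grids coincide (mass difference an integer number of 13C spacings within
  # instrument accuracy -- isomers are the k = 0 case) are indistinguishable
  # from centroid data when they also co-elute, so the generator keeps such
  # pairs at least `min_sep` apart in retention time. Real isobaric
  # co-elution exists but has no well-defined per-metabolite ground truth.
  min_sep <- 30
  adduct_mass <- monoisotopic_mass(draw$formula)
  grid_overlap <- function(i, j) {
    d <- abs(adduct_mass[i] - adduct_mass[j])
    k <- round(d / delta_c13)
    k <= max(carbon_range) && abs(d - k * delta_c13) <=
      20e-6 * max(adduct_mass[i], adduct_mass[j])
  }
  for (i in seq_len(n)) {
    tries <- 0L
    repeat {
      clash <- FALSE
      for (j in seq_len(i - 1L)) {
        if (abs(rt[j] - rt[i]) < min_sep && grid_overlap(i, j)) {
          clash <- TRUE
          break
        }
      }
      if (!clash || tries >= 100L) break
      rt[i] <- stats::runif(1, rt_range[1], rt_range[2])
      tries <- tries + 1L
    }
  }
  counts <- round(fracs * n)
  categories <- sample(rep(c("up", "down", "on", "off", "unchanged"),
                           c(counts, n - sum(counts))))
  true_log2fc <- dplyr::case_when(
    categories == "up" ~ abs(effect_log2fc),
    categories == "down" ~ -abs(effect_log2fc),
    categories == "unchanged" ~ 0,
    TRUE ~ NA_real_   # on/off: fold change undefined
  )
  base <- stats::rlnorm(n, abund_meanlog, abund_sdlog)
  adduct <- if (polarity == "positive") "[M+H]+" else "[M-H]-"
  mono12 <- adduct_mz(draw$neutral_mass, adduct)

  control_mean <- ifelse(categories == "on", 0, base)
  treatment_mean <- dplyr::case_when(
    categories == "off" ~ 0,
    categories == "on" ~ base,
    TRUE ~ base * 2^true_log2fc
  )
  is_abund <- (treatment_mean + control_mean) / 2   # one pooled mixture

  truth <- tibble::tibble(
    metabolite_id = sprintf("met%04d", seq_len(n)),
    name = draw$name, formula = draw$formula,
    carbon_count = draw$carbon_count, neutral_mass = draw$neutral_mass,
    mono12_mz = mono12,
    mono13_mz = mono12 + draw$carbon_count * delta_c13,
    rt = rt, category = categories, true_log2fc = true_log2fc,
    control_mean = control_mean, treatment_mean = treatment_mean,
    is_abund = is_abund
  )

  design <- tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n_control + n_treatment)),
    group = rep(c("control", "treatment"), c(n_control, n_treatment))
  )

  sdlog_rep <- sqrt(log(1 + replicate_cv^2))
  lnoise <- function(k) stats::rlnorm(k, -sdlog_rep^2 / 2, sdlog_rep)

  peaks_by_run <- vector("list", nrow(design))
  areas_by_run <- vector("list", nrow(design))
  for (r in seq_len(nrow(design))) {
    grp <- design$group[r]
    area_sample <- (if (grp == "treatment") treatment_mean else control_mean) * lnoise(n)
    area_is <- is_abund * lnoise(n)
    rt_run <- rt + stats::rnorm(n, 0, rt_jitter_sec)
    run_rows <- vector("list", n)
    for (i in seq_len(n)) {
      nc <- truth$carbon_count[i]
      env_s <- stats::dbinom(0:nc, nc, scheme$p13_sample)
      env_i <- stats::dbinom(0:nc, nc, scheme$p13_is)
      keep_s <- env_s >= 0.005 * max(env_s)
      keep_i <- env_i >= 0.005 * max(env_i)
      inten_s <- area_sample[i] * env_s * keep_s
      inten_i <- area_is[i] * env_i * keep_i
      inten <- inten_s + inten_i
      k <- which(inten >= loq & inten > 0) - 1L
      if (length(k) == 0L) next
      mz <- mono12[i] + k * delta_c13
      channel <- ifelse(inten_s[k + 1L] > 0 & inten_i[k + 1L] > 0, "both",
                        ifelse(inten_s[k + 1L] > 0, "sample", "is"))
      run_rows[[i]] <- tibble::tibble(
        metabolite_id = truth$metabolite_id[i], channel = channel,
        mz = mz, rt = rep(max(0, rt_run[i]), length(k)),
        intensity = inten[k + 1L]
      )
    }
    run_peaks <- purrr::list_rbind(purrr::compact(run_rows))
    n_art <- round(artifact_rate * n)
    if (n_art > 0) {
      art <- tibble::tibble(
        metabolite_id = NA_character_, channel = "artifact",
        mz = stats::runif(n_art, min(mono12) - 5, max(truth$mono13_mz) + 5),
        rt = stats::runif(n_art, rt_range[1], rt_range[2]),
        intensity = stats::rlnorm(n_art, abund_meanlog, abund_sdlog)
      )
      art <- art[art$intensity >= loq, ]
      run_peaks <- dplyr::bind_rows(run_peaks, art)
    }
    # m/z noise after channel merging, as the instrument would centroid
    run_peaks$mz <- run_peaks$mz *
      (1 + stats::rnorm(nrow(run_peaks), 0, mass_noise_ppm * 1e-6))
    run_peaks <- dplyr::arrange(run_peaks, .data$mz)
    run_peaks <- dplyr::mutate(
      run_peaks,
      sample_id = design$sample_id[r], polarity = polarity,
      peak_id = sprintf("%s_p%05d", design$sample_id[r],
                        seq_len(nrow(run_peaks)))
    )
    peaks_by_run[[r]] <- run_peaks
    areas_by_run[[r]] <- tibble::tibble(
      metabolite_id = truth$metabolite_id,
      sample_id = design$sample_id[r],
      area_sample = area_sample, area_is = area_is
    )
  }
  peaks <- dplyr::relocate(purrr::list_rbind(peaks_by_run),
                           "peak_id", "sample_id", "polarity",
                           "mz", "rt", "intensity")
  config <- list(
    n_metabolites = n, n_treatment = n_treatment, n_control = n_control,
    frac_up = frac_up, frac_down = frac_down, frac_on = frac_on,
    frac_off = frac_off, effect_log2fc = effect_log2fc,
    abund_meanlog = abund_meanlog, abund_sdlog = abund_sdlog,
    replicate_cv = replicate_cv, mass_noise_ppm = mass_noise_ppm,
    rt_jitter_sec = rt_jitter_sec, loq = loq, artifact_rate = artifact_rate,
    p13_sample = scheme$p13_sample, p13_is = scheme$p13_is,
    carbon_range = as.integer(carbon_range), rt_range = rt_range,
    polarity = polarity, seed = as.integer(seed)
  )
  structure(list(peaks = peaks, truth = truth,
                 channel_areas = purrr::list_rbind(areas_by_run),
                 design = design, config = config),
            class = "iroa_study")
}

#' @export
print.iroa_study <- function(x, ...) {
  cat(sprintf("<iroa_study> %d metabolites, %d runs (%d treatment, %d control), %d peaks\n",
              nrow(x$truth), nrow(x$design),
              sum(x$design$group == "treatment"),
              sum(x$design$group == "control"), nrow(x$peaks)))
  print(table(x$truth$category))
  invisible(x)
}

#' Standards library derived from a simulated study's ground truth
#'
#' One entry per distinct simulated metabolite, suitable for
#' [library_match()] round-trip validation.
#'
#' @param study An `iroa_study`.
#' @return A tibble `name`, `formula`, `rt_sec`, `polarity`.
#' @export
study_library <- function(study) {
  stopifnot(inherits(study, "iroa_study"))
  dplyr::distinct(
    tibble::tibble(name = study$truth$name, formula = study$truth$formula,
                   rt_sec = study$truth$rt,
                   polarity = study$config$polarity)
  )
}

#' Write a simulated study to disk
#'
#' One TSV peak list per run in the interchange dialect (`sample_id`,
#' `polarity`, `mz`, `rt_sec`, `intensity`), plus `ground_truth.csv`,
#' `design.csv` and the configuration echoed to `config.yaml`.
#'
#' @param study An `iroa_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "iroa_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in study$design$sample_id) {
    write_peaks_tsv(dplyr::filter(study$peaks, .data$sample_id == s),
                    file.path(dir, paste0("peaks_", s, ".tsv")))
  }
  readr::write_csv(
    dplyr::select(study$truth, "metabolite_id", "name", "formula",
                  "carbon_count", rt_sec = "rt", "category", "true_log2fc"),
    file.path(dir, "ground_truth.csv")
  )
  readr::write_csv(study$design, file.path(dir, "design.csv"))
  yaml::write_yaml(study$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
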