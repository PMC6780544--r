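# Shared fixtures, built in code. The study used by several expensive tests
# is cached per session.

.fixture_env <- new.env(parent = emptyenv())

# 200-metabolite study at the stress conditions used for the recovery and
# artifact-exclusion checks (heavy artifact load, 3 ppm mass noise, CV 0.10)
stress_study <- function() {
  if (is.null(.fixture_env$stress)) {
    .fixture_env$stress <- simulate_iroa_study(
      n_metabolites = 200, artifact_rate = 0.3, mass_noise_ppm = 3,
      replicate_cv = 0.10, seed = 20190910
    )
  }
  .fixture_env$stress
}

stress_pairs <- function() {
  if (is.null(.fixture_env$stress_pairs)) {
    .fixture_env$stress_pairs <-
      suppressMessages(detect_pairs(stress_study()$peaks))
  }
  .fixture_env$stress_pairs
}

stress_ratios <- function() {
  if (is.null(.fixture_env$stress_ratios)) {
    st <- stress_study()
    raw <- compute_ratios(stress_pairs(), st$design, loq = st$config$loq)
    .fixture_env$stress_ratios <- suppressMessages(impute_missing(raw))
  }
  .fixture_env$stress_ratios
}

# noiseless two-channel peak set for one metabolite, emitted on the exact
# isotopologue grid (the generator's emission rule, without noise)
make_pair_peaks <- function(mono12, n_carbons, rt, area_sample, area_is,
                            scheme = labeling_scheme(), sample_id = "run1",
                            min_rel = 0.005) {
  env_s <- dbinom(0:n_carbons, n_carbons, scheme$p13_sample)
  env_i <- dbinom(0:n_carbons, n_carbons, scheme$p13_is)
  inten <- area_sample * env_s * (env_s >= min_rel * max(env_s)) +
    area_is * env_i * (env_i >= min_rel * max(env_i))
  k <- which(inten > 0) - 1L
  tibble::tibble(
    sample_id = sample_id, polarity = "positive",
    mz = mono12 + k * delta_c13, rt = rt, intensity = inten[k + 1L]
  )
}

# independent brute-force formula enumerator: full nested grid over H, N, O
# (S, P fixed at 0), filtered by mass window and plausibility
brute_force_formulas <- function(neutral_mass, n_carbons, tol_ppm,
                                 h_max = 80, n_max = 10, o_max = 15) {
  hits <- list()
  masses <- c(C = 12, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196)
  for (h in 0:h_max) for (nn in 0:n_max) for (o in 0:o_max) {
    mass <- n_carbons * masses["C"] + h * masses["H"] + nn * masses["N"] +
      o * masses["O"]
    if (abs(mass - neutral_mass) > tol_ppm * 1e-6 * neutral_mass) next
    rdbe <- n_carbons - h / 2 + nn / 2 + 1
    if (h > 2 * n_carbons + 2 + nn) next
    if (rdbe < 0 || abs(rdbe - round(rdbe)) > 1e-9) next
    hits[[length(hits) + 1L]] <- sprintf(
      "C%dH%dN%dO%d", n_carbons, h, nn, o)
  }
  unlist(hits)
}

# canonical element-count key for set comparison of formula tables
formula_key <- function(tbl) {
  sort(sprintf("C%dH%dN%dO%d", tbl$C, tbl$H, tbl$N, tbl$O))
}

brute_key <- function(strings) {
  if (length(strings) == 0L) return(character(0))
  counts <- parse_formula(strings)
  sort(sprintf("C%dH%dN%dO%d", counts$C, counts$H, counts$N, counts$O))
}
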