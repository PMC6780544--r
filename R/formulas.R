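# Molecular formula arithmetic over the CHNOSP element space, and
# carbon-count-constrained formula enumeration. The carbon count delivered by
# the isotopic peak pair collapses the usual combinatorial explosion of
# candidate formulas: with C fixed, only H/N/O (and optionally S/P) remain
# free, and the proton count is pinned by the residual mass.

FORMULA_ELEMENTS <- c("C", "H", "N", "O", "S", "P")

#' Parse a molecular formula string
#'
#' Accepts Hill-style formulas over C, H, N, O, S, P such as `"C6H13NO2"`.
#'
#' @param formula Character vector of formula strings.
#' @return A tibble with one row per formula and integer columns `C`, `H`,
#'   `N`, `O`, `S`, `P`.
#' @export
#' @examples
#' parse_formula("C6H13NO2")
parse_formula <- function(formula) {
  stopifnot(is.character(formula))
  rows <- lapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) rlang::abort("empty formula string")
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    tokens <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    if (sum(nchar(tokens)) != nchar(f)) {
      rlang::abort(sprintf("cannot parse formula '%s'", f))
    }
    counts <- stats::setNames(rep(0L, length(FORMULA_ELEMENTS)), FORMULA_ELEMENTS)
    for (tok in tokens) {
      el <- sub("[0-9]*$", "", tok)
      if (!el %in% FORMULA_ELEMENTS) {
        rlang::abort(sprintf("unsupported element '%s' in formula '%s' (CHNOSP only)", el, f))
      }
      num <- sub("^[A-Za-z]+", "", tok)
      counts[el] <- counts[el] + if (nzchar(num)) as.integer(num) else 1L
    }
    counts
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  out$formula <- formula
  dplyr::relocate(out, "formula")
}

#' Write element counts as a Hill-order formula string
#'
#' @param counts A data frame with columns `C`, `H`, `N`, `O`, `S`, `P`
#'   (extra columns ignored), or a named numeric vector.
#' @return Character vector of formula strings (C first, H second, then
#'   alphabetical).
#' @export
#' @examples
#' formula_string(parse_formula("C6H13NO2"))
formula_string <- function(counts) {
  counts <- as_count_table(counts)
  order <- c("C", "H", "N", "O", "P", "S")
  apply(as.matrix(counts[order]), 1L, function(x) {
    parts <- vapply(order, function(el) {
      n <- x[[el]]
      if (n == 0) "" else if (n == 1) el else paste0(el, n)
    }, character(1))
    paste0(parts, collapse = "")
  })
}

as_count_table <- function(x) {
  if (is.character(x)) x <- parse_formula(x)
  if (is.numeric(x) && !is.null(names(x))) {
    x <- tibble::as_tibble(as.list(x))
  }
  if (!is.data.frame(x)) rlang::abort("expected a formula string, named vector or count table")
  for (el in FORMULA_ELEMENTS) if (is.null(x[[el]])) x[[el]] <- 0L
  x[FORMULA_ELEMENTS]
}

#' Monoisotopic (principal-isotope) neutral mass of a formula
#'
#' @param formula Formula string(s), a count table from [parse_formula()], or
#'   a named numeric vector of element counts.
#' @return Neutral monoisotopic mass(es) in Da.
#' @export
#' @examples
#' monoisotopic_mass("C6H13NO2")  # leucine, 131.0946
monoisotopic_mass <- function(formula) {
  counts <- as_count_table(formula)
  if (any(as.matrix(counts) < 0)) rlang::abort("element counts must be non-negative")
  as.numeric(as.matrix(counts) %*% element_masses[FORMULA_ELEMENTS])
}

#' Ring-and-double-bond equivalents of a formula
#'
#' `RDBE = C - H/2 + (N + P)/2 + 1`. A chemically plausible even-electron
#' neutral molecule has a non-negative integer RDBE.
#'
#' @inheritParams monoisotopic_mass
#' @return Numeric RDBE value(s).
#' @export
formula_rdbe <- function(formula) {
  counts <- as_count_table(formula)
  counts$C - counts$H / 2 + (counts$N + counts$P) / 2 + 1
}

# Valence / RDBE plausibility filter for neutral even-electron CHNOSP
# molecules: non-negative counts, H <= 2C + 2 + N, integer RDBE >= 0.
formula_is_plausible <- function(counts) {
  counts <- as_count_table(counts)
  rdbe <- counts$C - counts$H / 2 + (counts$N + counts$P) / 2 + 1
  ok_counts <- rowSums(as.matrix(counts) < 0) == 0
  ok_h <- counts$H <= 2 * counts$C + 2 + counts$N
  ok_rdbe <- rdbe >= 0 & abs(rdbe - round(rdbe)) < 1e-9
  ok_counts & ok_h & ok_rdbe
}

#' Observed m/z of an adduct of a neutral molecule
#'
#' @param neutral_mass Neutral monoisotopic mass(es), Da.
#' @param adduct Adduct name (`"[M+H]+"`, `"[M-H]-"`, `"[M+Na]+"`) or a
#'   one-row subset of [iroa_adducts()].
#' @return m/z value(s) of the charged species.
#' @export
#' @examples
#' adduct_mz(monoisotopic_mass("C6H13NO2"), "[M+H]+")
adduct_mz <- function(neutral_mass, adduct = "[M+H]+") {
  a <- resolve_adduct(adduct)
  if (any(neutral_mass <= 0)) rlang::abort("`neutral_mass` must be positive")
  (neutral_mass + a$mass_delta) / abs(a$charge)
}

#' Neutral mass back-calculated from an adduct m/z
#'
#' Inverse of [adduct_mz()].
#'
#' @param mz Observed m/z value(s).
#' @inheritParams adduct_mz
#' @return Neutral monoisotopic mass(es), Da.
#' @export
neutral_from_mz <- function(mz, adduct = "[M+H]+") {
  a <- resolve_adduct(adduct)
  mz * abs(a$charge) - a$mass_delta
}

resolve_adduct <- function(adduct) {
  if (is.data.frame(adduct)) {
    stopifnot(nrow(adduct) == 1L, all(c("mass_delta", "charge") %in% names(adduct)))
    return(adduct)
  }
  tab <- iroa_adducts()
  hit <- tab[tab$adduct == adduct, ]
  if (nrow(hit) != 1L) {
    rlang::abort(sprintf("unknown adduct '%s'; see iroa_adducts()", adduct))
  }
  hit
}

#' Enumerate molecular formulas for a neutral mass at fixed carbon count
#'
#' Every CHNOSP formula with exactly `n_carbons` carbons, element counts
#' within `element_bounds`, a plausible valence/RDBE, and monoisotopic mass
#' within `tol_ppm` of `neutral_mass`. With the carbon count fixed by the
#' isotopic peak pair, the hydrogen count is pinned by the residual mass, so
#' the search reduces to a small grid over N, O (and optionally S, P).
#'
#' @param neutral_mass Target neutral monoisotopic mass, Da.
#' @param n_carbons Carbon count (integer >= 1), taken from the peak pair.
#' @param tol_ppm Mass tolerance in ppm of `neutral_mass`. Default 10.
#' @param element_bounds Named list of upper bounds for `H`, `N`, `O`, `S`,
#'   `P`. Defaults `list(H = 80, N = 10, O = 15, S = 0, P = 0)`; S and P are
#'   off by default.
#' @return A tibble sorted by absolute mass error with columns `formula`,
#'   `C`, `H`, `N`, `O`, `S`, `P`, `mass`, `error_ppm`, `rdbe`. Zero rows when
#'   nothing matches.
#' @export
#' @examples
#' # carbon count 16 from the peak pair plus the protonated ion's m/z
#' enumerate_formulas(neutral_from_mz(385.1761), 16, tol_ppm = 15)
enumerate_formulas <- function(neutral_mass, n_carbons, tol_ppm = 10,
                               element_bounds = list(H = 80, N = 10, O = 15,
                                                     S = 0, P = 0)) {
  stopifnot(is.numeric(neutral_mass), length(neutral_mass) == 1L,
            neutral_mass > 0, tol_ppm > 0)
  if (!is.numeric(n_carbons) || length(n_carbons) != 1L || n_carbons < 1 ||
      n_carbons != round(n_carbons)) {
    rlang::abort("`n_carbons` must be a single integer >= 1")
  }
  b <- modifyList(list(H = 80, N = 10, O = 15, S = 0, P = 0),
                  as.list(element_bounds))
  tol_da <- tol_ppm * 1e-6 * neutral_mass
  rem0 <- neutral_mass - n_carbons * element_masses[["C"]] + tol_da
  if (rem0 < 0) return(empty_formula_table())
  cap <- function(el, bound) min(bound, floor(rem0 / element_masses[[el]]))
  grid <- expand.grid(
    N = 0:max(0, cap("N", b$N)),
    O = 0:max(0, cap("O", b$O)),
    S = 0:max(0, cap("S", b$S)),
    P = 0:max(0, cap("P", b$P))
  )
  residual <- neutral_mass - n_carbons * element_masses[["C"]] -
    grid$N * element_masses[["N"]] - grid$O * element_masses[["O"]] -
    grid$S * element_masses[["S"]] - grid$P * element_masses[["P"]]
  h0 <- round(residual / element_masses[["H"]])
  cand <- dplyr::bind_rows(lapply(-1:1, function(dh) {
    g <- grid
    g$H <- as.integer(h0 + dh)
    g
  }))
  cand$C <- as.integer(n_carbons)
  cand <- cand[cand$H >= 0 & cand$H <= b$H, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_formula_table())
  cand <- tibble::as_tibble(cand)[FORMULA_ELEMENTS]
  cand$mass <- monoisotopic_mass(cand)
  cand$error_ppm <- (cand$mass - neutral_mass) / neutral_mass * 1e6
  cand <- cand[abs(cand$error_ppm) <= tol_ppm & formula_is_plausible(cand), ,
               drop = FALSE]
  if (nrow(cand) == 0L) return(empty_formula_table())
  cand$rdbe <- formula_rdbe(cand)
  cand$formula <- formula_string(cand)
  cand <- dplyr::distinct(cand)
  dplyr::relocate(dplyr::arrange(cand, abs(.data$error_ppm)), "formula")
}

empty_formula_table <- function() {
  tibble::tibble(
    formula = character(), C = integer(), H = integer(), N = integer(),
    O = integer(), S = integer(), P = integer(),
    mass = numeric(), error_ppm = numeric(), rdbe = numeric()
  )
}

#' Identify aligned peak pairs against a standards library
#'
#' An identification requires simultaneous agreement of (a) the IROA carbon
#' count, (b) the molecular-ion m/z under some polarity-compatible adduct
#' within `tol_ppm`, and (c) retention time within `rt_tol`.
#'
#' @param features A data frame of aligned pair features with columns
#'   `row_id`, `carbon_count`, `mz12`, `rt`, `polarity`.
#' @param library A data frame with columns `name`, `formula`, `rt_sec`,
#'   `polarity`.
#' @param adducts Adduct table; default [iroa_adducts()] restricted to
#'   `[M+H]+` / `[M-H]-`.
#' @param tol_ppm Mass tolerance (ppm of m/z). Default 10.
#' @param rt_tol Retention-time tolerance, seconds. Default 30.
#' @return A tibble `row_id`, `name`, `formula`, `adduct`, `mass_error_ppm`,
#'   `rt_error_sec`, ranked by absolute mass error within each row.
#' @export
library_match <- function(features, library,
                          adducts = dplyr::filter(iroa_adducts(),
                                                  .data$adduct %in% c("[M+H]+", "[M-H]-")),
                          tol_ppm = 10, rt_tol = 30) {
  stopifnot(all(c("row_id", "carbon_count", "mz12", "rt", "polarity") %in% names(features)),
            all(c("name", "formula", "rt_sec", "polarity") %in% names(library)))
  lib <- dplyr::bind_cols(library, parse_formula(library$formula)[-1])
  lib$neutral_mass <- monoisotopic_mass(lib$formula)
  lib <- tidyr::crossing(lib, adducts, .name_repair = "minimal")
  names(lib)[names(lib) == "polarity"] <- c("polarity_lib", "polarity_adduct")
  lib <- dplyr::filter(lib, .data$polarity_lib == .data$polarity_adduct)
  lib$mz_expected <- (lib$neutral_mass + lib$mass_delta) / abs(lib$charge)

  hits <- dplyr::inner_join(
    dplyr::select(features, "row_id", "carbon_count", "mz12", "rt", "polarity"),
    dplyr::select(lib, "name", "formula", "adduct", C_lib = "C",
                  "rt_sec", polarity_lib = "polarity_lib", "mz_expected"),
    by = dplyr::join_by("carbon_count" == "C_lib", "polarity" == "polarity_lib"),
    relationship = "many-to-many"
  )
  hits <- dplyr::mutate(
    hits,
    mass_error_ppm = (.data$mz12 - .data$mz_expected) / .data$mz_expected * 1e6,
    rt_error_sec = .data$rt - .data$rt_sec
  )
  hits <- dplyr::filter(hits, abs(.data$mass_error_ppm) <= tol_ppm,
                        abs(.data$rt_error_sec) <= rt_tol)
  hits <- dplyr::arrange(hits, .data$row_id, abs(.data$mass_error_ppm))
  dplyr::select(hits, "row_id", "name", "formula", "adduct",
                "mass_error_ppm", "rt_error_sec")
}
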