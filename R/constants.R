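# Physical constants used throughout. Monoisotopic masses in Da; fixed,
# read-only. delta_c13 is the 13C - 12C mass difference that sets the
# isotopologue spacing on the m/z axis.

#' Monoisotopic masses of the principal isotopes of C, H, N, O, S, P (Da)
#'
#' Named numeric vector of the principal-isotope (lightest stable) masses used
#' for all exact-mass arithmetic in the package.
#'
#' @format Named numeric vector with elements `C`, `H`, `N`, `O`, `S`, `P`.
#' @export
element_masses <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  P = 30.97376163
)

#' Mass difference between 13C and 12C (Da)
#' @export
delta_c13 <- 1.0033548

#' Proton mass (Da), electron mass already folded in
#'
#' Mass added to a neutral molecule by protonation, i.e. the mass of H minus
#' one electron, so that adduct arithmetic on charged species is consistent.
#' @export
proton_mass <- 1.0072765

electron_mass <- 0.00054857990

#' Supported electrospray adducts
#'
#' Mass deltas are for the charged species (electron mass folded in).
#'
#' @return A tibble with columns `adduct`, `mass_delta`, `charge`, `polarity`.
#' @export
#' @examples
#' iroa_adducts()
iroa_adducts <- function() {
  tibble::tibble(
    adduct     = c("[M+H]+", "[M-H]-", "[M+Na]+"),
    mass_delta = c(proton_mass, -proton_mass, 22.9897693 - electron_mass),
    charge     = c(1L, -1L, 1L),
    polarity   = c("positive", "negative", "positive")
  )
}

#' Dual-labeling scheme of an IROA experiment
#'
#' Describes the per-carbon 13C probability of the two channels: the sample
#' channel (treatment and control cultures, grown in 95:5 12C:13C media, so
#' ~5% 13C per carbon) and the pooled internal-standard channel (5:95 media,
#' ~95% 13C). Every carbon of a biosynthesized metabolite is assumed labeled
#' independently with these probabilities.
#'
#' @param p13_sample Fraction of carbon atoms that are 13C in the sample
#'   channel. Default 0.05.
#' @param p13_is Same for the internal-standard channel. Default 0.95.
#' @return An object of class `labeling_scheme`.
#' @export
#' @examples
#' labeling_scheme()
labeling_scheme <- function(p13_sample = 0.05, p13_is = 0.95) {
  stopifnot(
    is.numeric(p13_sample), length(p13_sample) == 1L,
    is.numeric(p13_is), length(p13_is) == 1L
  )
  if (p13_sample < 0 || p13_sample > 1 || p13_is < 0 || p13_is > 1) {
    rlang::abort("labeling fractions must lie in [0, 1]")
  }
  if (!(p13_sample < 0.5 && p13_is > 0.5)) {
    rlang::abort("expected p13_sample < 0.5 < p13_is (light sample channel, heavy IS channel)")
  }
  structure(list(p13_sample = p13_sample, p13_is = p13_is),
            class = "labeling_scheme")
}

#' @export
print.labeling_scheme <- function(x, ...) {
  cat(sprintf("<labeling_scheme> sample channel p13 = %.3f, IS channel p13 = %.3f\n",
              x$p13_sample, x$p13_is))
  invisible(x)
}
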