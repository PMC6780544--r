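# Carbon isotopologue envelope model. Under uniform labeling each of the n
# carbons of a metabolite is 13C independently with probability p13, so the
# number of 13C atoms is Binomial(n, p13) and the isotopologue envelope over
# k = 0..n is the binomial pmf. Natural-abundance contributions from H/N/O/S
# are ignored: the enforced media labeling dominates the envelope shape.

#' Carbon isotopologue envelope under uniform labeling
#'
#' Probability that a molecule with `n_carbons` carbons carries k = 0..n
#' 13C atoms when each carbon is 13C independently with probability `p13`.
#'
#' @param n_carbons Number of carbon atoms (integer >= 0).
#' @param p13 Per-carbon 13C probability in `[0, 1]`.
#' @return Numeric vector of length `n_carbons + 1`; entry k+1 is the relative
#'   intensity of the isotopologue with k 13C atoms. Sums to 1.
#' @export
#' @examples
#' carbon_isotopologue_envelope(6, 0.05)   # light (sample-channel) envelope
#' carbon_isotopologue_envelope(6, 0.95)   # heavy (IS-channel) mirror
carbon_isotopologue_envelope <- function(n_carbons, p13) {
  if (!is.numeric(n_carbons) || length(n_carbons) != 1L || is.na(n_carbons) ||
      n_carbons < 0 || n_carbons != round(n_carbons)) {
    rlang::abort("`n_carbons` must be a single non-negative integer")
  }
  if (!is.numeric(p13) || length(p13) != 1L || is.na(p13) || p13 < 0 || p13 > 1) {
    rlang::abort("`p13` must be a single value in [0, 1]")
  }
  # evaluate on the light side and mirror, so that envelope(n, p)[k] equals
  # envelope(n, 1 - p)[n - k] exactly, not just to rounding
  if (p13 > 0.5) {
    rev(stats::dbinom(0:n_carbons, size = n_carbons, prob = 1 - p13))
  } else {
    stats::dbinom(0:n_carbons, size = n_carbons, prob = p13)
  }
}

#' m/z spacing between adjacent carbon isotopologues
#'
#' @param charge Charge state (integer >= 1).
#' @return The m/z gap `delta_c13 / charge`.
#' @export
#' @examples
#' isotopologue_spacing(1)
isotopologue_spacing <- function(charge = 1L) {
  if (!is.numeric(charge) || any(is.na(charge)) || any(charge < 1) ||
      any(charge != round(charge))) {
    rlang::abort("`charge` must be integer >= 1")
  }
  delta_c13 / charge
}

#' Carbon count from the monoisotopic m/z gap of a peak pair
#'
#' The gap between the all-12C sample-channel monoisotopic ion and the all-13C
#' IS-channel monoisotopic ion of the same metabolite is `n * delta_c13 /
#' charge`, so the carbon count is read directly off the observed gap.
#'
#' @param delta_mz Observed m/z gap(s), > 0. Vectorized.
#' @param charge Charge state (integer >= 1).
#' @param max_carbons Largest carbon count considered.
#' @param tol_ppm Optional no-call tolerance on the residual, in ppm of the
#'   ideal gap; estimates whose residual exceeds it return `NA`. Default `Inf`
#'   (report only). Note that pair acceptance in [find_peak_pairs()] applies
#'   its tolerance on the m/z scale instead, which is robust to mass noise.
#' @return A tibble with columns `n` (integer, `NA` when out of range or
#'   beyond tolerance) and `residual_ppm` (deviation of `delta_mz` from the
#'   ideal n-carbon gap, in ppm of that gap).
#' @export
#' @examples
#' estimate_carbon_count(6.020129)            # leucine: 6 carbons
#' estimate_carbon_count(18.060387, charge = 2)
estimate_carbon_count <- function(delta_mz, charge = 1L, max_carbons = 60L,
                                  tol_ppm = Inf) {
  if (!is.numeric(delta_mz) || any(is.na(delta_mz)) || any(delta_mz <= 0)) {
    rlang::abort("`delta_mz` must be positive")
  }
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != round(charge)) {
    rlang::abort("`charge` must be a single integer >= 1")
  }
  spacing <- isotopologue_spacing(charge)
  n <- as.integer(round(delta_mz / spacing))
  ideal <- n * spacing
  residual_ppm <- (delta_mz - ideal) / ideal * 1e6
  bad <- n < 1L | n > max_carbons
  residual_ppm[bad] <- NA_real_
  n[bad] <- NA_integer_
  n[!is.na(residual_ppm) & abs(residual_ppm) > tol_ppm] <- NA_integer_
  tibble::tibble(n = n, residual_ppm = residual_ppm)
}

#' Cosine similarity of two isotopologue envelopes
#'
#' The shorter envelope is padded with zeros. Used as a consistency score when
#' assigning clusters to the sample or IS channel.
#'
#' @param observed,template Non-negative numeric vectors, not all zero.
#' @return Cosine similarity in `[0, 1]`.
#' @export
#' @examples
#' envelope_similarity(c(1, 0), carbon_isotopologue_envelope(1, 0.05))
envelope_similarity <- function(observed, template) {
  if (!is.numeric(observed) || !is.numeric(template) ||
      any(is.na(observed)) || any(is.na(template)) ||
      any(observed < 0) || any(template < 0)) {
    rlang::abort("envelopes must be non-negative numeric vectors")
  }
  len <- max(length(observed), length(template))
  observed <- c(observed, rep(0, len - length(observed)))
  template <- c(template, rep(0, len - length(template)))
  no <- sqrt(sum(observed^2))
  nt <- sqrt(sum(template^2))
  if (no == 0 || nt == 0) rlang::abort("zero-length envelope has no direction")
  sum(observed * template) / (no * nt)
}

# Cosine of an observed (possibly truncated) cluster envelope against the
# n-carbon template of one channel. Sample-channel envelopes are anchored at
# the light end (their base peak is the all-12C monoisotopic ion), IS-channel
# envelopes at the heavy end, so the observed vector is padded on the opposite
# side before comparison. Returns NA when the observation is longer than the
# template, or when the observed window would cover less than `min_coverage`
# of the template's mass -- a short window of a long template can mimic many
# shapes, so such comparisons carry no evidence. Clusters emitted above the
# 0.5% centroid floor always cover > 97% of their true template.
channel_template_score <- function(envelope, n, p13, align = c("left", "right"),
                                   min_coverage = 0.9) {
  align <- match.arg(align)
  m <- length(envelope)
  if (m > n + 1L) return(NA_real_)
  template <- stats::dbinom(0:n, size = n, prob = p13)
  window <- if (align == "left") seq_len(m) else seq.int(n + 2L - m, n + 1L)
  if (sum(template[window]) < min_coverage) return(NA_real_)
  pad <- rep(0, n + 1L - m)
  obs <- if (align == "left") c(envelope, pad) else c(pad, envelope)
  envelope_similarity(obs, template)
}
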