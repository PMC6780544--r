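# From centroided peaks of one run to IROA peak pairs.
#
# Stage 1 chains co-eluting peaks spaced by delta_c13/z into isotopologue
# clusters. Stage 2 assigns each cluster to the sample channel (light
# envelope, base peak at the all-12C ion), the IS channel (heavy envelope,
# base peak at the all-13C ion), a "joint" call when the two channels of a
# low-carbon metabolite overlap on the shared m/z grid and centroiding merged
# them into one cluster, or "unclassified". Stage 3 pairs sample clusters
# with IS clusters whose monoisotopic gap is an integer number of carbon
# spacings; everything left unpaired is discarded as a non-biological signal.

#' Chain centroid peaks into isotopologue clusters
#'
#' Greedy chaining within a single run and polarity: peaks are scanned in m/z
#' order and a peak joins an open cluster when its m/z sits one isotopologue
#' spacing above the cluster's last member (within `ppm_tol` of the m/z) and
#' its retention time is within `rt_tol` of the cluster apex. Every peak ends
#' up in exactly one cluster; singletons are allowed.
#'
#' @param peaks A data frame with columns `mz`, `rt`, `intensity` (one run,
#'   one polarity; columns `sample_id`, `polarity`, `peak_id` are carried
#'   through when present).
#' @param ppm_tol m/z tolerance in ppm. Default 10.
#' @param rt_tol Retention-time tolerance in seconds. Default 6.
#' @param charges Charge states to consider. Default `1L`.
#' @return A tibble with one row per cluster: `cluster_id`, `sample_id`,
#'   `polarity`, `charge` (`NA` for singletons), `n_members`, `base_mz`,
#'   `top_mz`, `rt_apex`, `total_area`, and list-columns `envelope`
#'   (normalized member intensities in m/z order), `member_mz`, `peak_ids`.
#' @export
cluster_isotopologues <- function(peaks, ppm_tol = 10, rt_tol = 6,
                                  charges = 1L) {
  peaks <- as_peak_table(peaks, require_one_run = TRUE)
  n <- nrow(peaks)
  if (n == 0L) return(empty_cluster_table())
  ord <- order(peaks$mz, peaks$rt)
  peaks <- peaks[ord, ]

  cluster_of <- integer(n)
  last_mz <- numeric(0)     # per-cluster state
  charge <- integer(0)      # NA_integer_ until a second member fixes it
  apex_rt <- numeric(0)
  apex_int <- numeric(0)
  charges <- sort(as.integer(charges))

  for (i in seq_len(n)) {
    mz <- peaks$mz[i]; rt <- peaks$rt[i]; int <- peaks$intensity[i]
    # a chain link compares two independently measured m/z values, so the
    # per-peak ppm tolerance widens by sqrt(2)
    tol <- sqrt(2) * ppm_tol * 1e-6 * mz
    best <- 0L; best_dev <- Inf; best_z <- NA_integer_
    if (length(last_mz) > 0L) {
      rt_ok <- abs(rt - apex_rt) <= rt_tol
      for (z in charges) {
        z_ok <- rt_ok & (is.na(charge) | charge == z)
        dev <- abs(mz - (last_mz + delta_c13 / z))
        cand <- which(z_ok & dev <= tol)
        if (length(cand) > 0L) {
          ci <- cand[which.min(dev[cand])]
          if (dev[ci] < best_dev) { best <- ci; best_dev <- dev[ci]; best_z <- z }
        }
      }
    }
    if (best > 0L) {
      cluster_of[i] <- best
      last_mz[best] <- mz
      charge[best] <- best_z
      if (int > apex_int[best]) { apex_int[best] <- int; apex_rt[best] <- rt }
    } else {
      last_mz <- c(last_mz, mz); charge <- c(charge, NA_integer_)
      apex_rt <- c(apex_rt, rt); apex_int <- c(apex_int, int)
      cluster_of[i] <- length(last_mz)
    }
  }

  by_cluster <- split(seq_len(n), cluster_of)
  rows <- lapply(seq_along(by_cluster), function(ci) {
    idx <- by_cluster[[ci]]
    p <- peaks[idx, ]
    tibble::tibble(
      cluster_id = ci,
      sample_id = p$sample_id[1],
      polarity = p$polarity[1],
      charge = charge[as.integer(names(by_cluster)[ci])],
      n_members = length(idx),
      base_mz = p$mz[1],
      top_mz = p$mz[nrow(p)],
      rt_apex = p$rt[which.max(p$intensity)],
      total_area = sum(p$intensity),
      envelope = list(p$intensity / sum(p$intensity)),
      member_mz = list(p$mz),
      peak_ids = list(p$peak_id)
    )
  })
  purrr::list_rbind(rows)
}

as_peak_table <- function(peaks, require_one_run = FALSE) {
  stopifnot(is.data.frame(peaks), all(c("mz", "rt", "intensity") %in% names(peaks)))
  peaks <- tibble::as_tibble(peaks)
  if (!"sample_id" %in% names(peaks)) peaks$sample_id <- "run1"
  if (!"polarity" %in% names(peaks)) peaks$polarity <- "positive"
  if (!"peak_id" %in% names(peaks)) {
    peaks$peak_id <- sprintf("%s_p%05d", peaks$sample_id, seq_len(nrow(peaks)))
  }
  if (nrow(peaks) > 0 &&
      (any(peaks$mz <= 0) || any(peaks$rt < 0) || any(peaks$intensity <= 0))) {
    rlang::abort("peaks require mz > 0, rt >= 0, intensity > 0")
  }
  if (require_one_run && nrow(peaks) > 0 &&
      (dplyr::n_distinct(peaks$sample_id) > 1L ||
       dplyr::n_distinct(peaks$polarity) > 1L)) {
    rlang::abort("clustering operates on a single run and polarity; split first")
  }
  peaks
}

empty_cluster_table <- function() {
  tibble::tibble(
    cluster_id = integer(), sample_id = character(), polarity = character(),
    charge = integer(), n_members = integer(), base_mz = numeric(),
    top_mz = numeric(), rt_apex = numeric(), total_area = numeric(),
    envelope = list(), member_mz = list(), peak_ids = list()
  )
}

#' Assign isotopologue clusters to the sample or IS channel
#'
#' Each cluster envelope is scored by cosine similarity against binomial
#' channel templates over candidate carbon counts: sample-channel templates
#' (`p13_sample`, anchored at the light end) and IS-channel templates
#' (`p13_is`, anchored at the heavy end). For metabolites with few carbons
#' the two channel envelopes overlap on the shared isotopologue grid and
#' merge into a single chained cluster; such clusters are recognized by a
#' nonnegative two-template mixture fit spanning the full cluster and called
#' `"joint"`, recording each channel's area fraction. Clusters whose best
#' score falls below `min_score` stay `"unclassified"`.
#'
#' @param clusters Cluster table from [cluster_isotopologues()].
#' @param scheme A [labeling_scheme()].
#' @param min_score Minimum cosine score to accept a channel call. Default 0.9.
#' @param n_range Candidate carbon-count range, default `c(2, 60)`.
#' @return The cluster table with columns `channel`
#'   (`sample`/`is`/`joint`/`unclassified`), `channel_score`, `n_best`,
#'   `frac_sample`, `frac_is` added.
#' @export
classify_cluster_channel <- function(clusters, scheme = labeling_scheme(),
                                     min_score = 0.9, n_range = c(2L, 60L)) {
  stopifnot(inherits(scheme, "labeling_scheme"))
  if (nrow(clusters) == 0L) {
    return(dplyr::mutate(clusters, channel = character(), channel_score = numeric(),
                         n_best = integer(), frac_sample = numeric(), frac_is = numeric()))
  }
  n_min <- max(1L, as.integer(n_range[1])); n_max <- as.integer(n_range[2])
  tmpl_s <- lapply(seq_len(n_max), function(n) stats::dbinom(0:n, n, scheme$p13_sample))
  tmpl_i <- lapply(seq_len(n_max), function(n) stats::dbinom(0:n, n, scheme$p13_is))
  norm_s <- vapply(tmpl_s, function(t) sqrt(sum(t^2)), numeric(1))
  norm_i <- vapply(tmpl_i, function(t) sqrt(sum(t^2)), numeric(1))
  res <- purrr::map(clusters$envelope, function(e) {
    m <- length(e)
    ns <- seq.int(max(n_min, m - 1L), n_max)
    norm_e <- sqrt(sum(e^2))
    # truncated-envelope cosines: sample anchored at the light end, IS at the
    # heavy end, so the zero padding drops out of the dot product; candidate
    # n is only scored when the observed window covers >= 90% of the
    # template's mass (a short window of a long template mimics any shape)
    s_scores <- vapply(ns, function(n) {
      w <- tmpl_s[[n]][seq_len(m)]
      if (sum(w) < 0.9) return(NA_real_)
      sum(e * w) / (norm_e * norm_s[n])
    }, numeric(1))
    i_scores <- vapply(ns, function(n) {
      w <- tmpl_i[[n]][seq.int(n + 2L - m, n + 1L)]
      if (sum(w) < 0.9) return(NA_real_)
      sum(e * w) / (norm_e * norm_i[n])
    }, numeric(1))
    j <- joint_mixture_fit(e, scheme, n_min, n_max)
    max_or_na <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
    idx_or_first <- function(x) if (all(is.na(x))) 1L else which.max(x)
    cand <- tibble::tibble(
      channel = c("sample", "is", "joint"),
      score = c(max_or_na(s_scores), max_or_na(i_scores), j$score),
      n_best = c(ns[idx_or_first(s_scores)], ns[idx_or_first(i_scores)], j$n),
      frac_sample = c(1, 0, j$frac_sample),
      frac_is = c(0, 1, j$frac_is)
    )
    # prefer the joint explanation on exact ties, then sample over IS
    cand <- cand[order(-cand$score, match(cand$channel, c("joint", "sample", "is"))), ]
    best <- cand[1, ]
    if (is.na(best$score) || best$score < min_score) {
      best$channel <- "unclassified"
    }
    best
  })
  res <- purrr::list_rbind(res)
  dplyr::mutate(clusters,
                channel = res$channel,
                channel_score = res$score,
                n_best = as.integer(res$n_best),
                frac_sample = res$frac_sample,
                frac_is = res$frac_is)
}

# Nonnegative least-squares fit of an observed envelope as a mixture of the
# n-carbon sample and IS templates, n fixed by the cluster span (a merged
# cluster covers the full k = 0..n grid). Returns the cosine of the observed
# envelope with the fitted mixture and the two channels' area fractions.
joint_mixture_fit <- function(envelope, scheme, n_min, n_max) {
  none <- list(score = NA_real_, n = NA_integer_,
               frac_sample = NA_real_, frac_is = NA_real_)
  m <- length(envelope)
  n <- m - 1L
  if (m < 3L || n < max(2L, n_min) || n > n_max) return(none)
  ts <- stats::dbinom(0:n, n, scheme$p13_sample)
  ti <- stats::dbinom(0:n, n, scheme$p13_is)
  # 2x2 normal equations, clamped to the nonnegative quadrant
  g11 <- sum(ts * ts); g12 <- sum(ts * ti); g22 <- sum(ti * ti)
  b1 <- sum(ts * envelope); b2 <- sum(ti * envelope)
  det <- g11 * g22 - g12^2
  a <- (b1 * g22 - b2 * g12) / det
  b <- (b2 * g11 - b1 * g12) / det
  if (a < 0) { a <- 0; b <- max(0, b2 / g22) }
  if (b < 0) { b <- 0; a <- max(0, b1 / g11) }
  if (a + b <= 0) return(none)
  fit <- a * ts + b * ti
  frac_s <- a / (a + b); frac_i <- b / (a + b)
  # both channels must contribute or the cluster is really single-channel
  if (min(frac_s, frac_i) < 0.02) return(none)
  list(score = envelope_similarity(envelope, fit), n = n,
       frac_sample = frac_s, frac_is = frac_i)
}

#' Match sample-channel and IS-channel clusters into IROA peak pairs
#'
#' A pair joins a sample-channel cluster with an IS-channel cluster that
#' co-elutes (`|rt difference| <= rt_tol`) and whose monoisotopic gap (IS
#' all-13C top m/z minus sample all-12C base m/z) equals `n * delta_c13 / z`
#' for some carbon count `n` in `n_range`, within `ppm_tol` of the m/z.
#' Both clusters must fit the gap-implied carbon count's channel template
#' with cosine `>= consistency_min`, and cross-channel pairs require at least
#' `min_members` member peaks per cluster. Candidates are ranked by pair
#' score, then smallest gap residual, closest retention time, larger IS area,
#' and matched one-to-one greedily. Clusters classified `"joint"` (merged
#' low-carbon-count pairs) yield a pair directly, with channel areas from the
#' mixture fit. Every cluster without a partner is excluded: a signal with no
#' isotopic twin is not a biosynthesized metabolite.
#'
#' @param clusters Channel-classified cluster table from
#'   [classify_cluster_channel()].
#' @param scheme A [labeling_scheme()].
#' @param ppm_tol m/z tolerance in ppm. Default 10.
#' @param rt_tol Retention-time tolerance in seconds. Default 6.
#' @param n_range Allowed carbon counts, default `c(2, 36)`.
#' @param min_members Minimum member peaks per cluster for cross-channel
#'   pairs. Default 2.
#' @param consistency_min Minimum envelope score at the gap-implied carbon
#'   count. Default 0.95: intact channel envelopes fit their template almost
#'   perfectly, while truncated cluster fragments (mass noise occasionally
#'   breaks a chain link) top out near 0.93 against any wrong-n template, so
#'   this threshold blocks fragment mispairs without costing true pairs.
#' @return A tibble of pairs: `sample_id`, `polarity`, `carbon_count`,
#'   `mz12`, `mz13`, `rt`, `area_sample`, `area_is`, `pair_score`,
#'   `gap_residual_ppm` (ppm of the gap), `cluster_sample`, `cluster_is`, and
#'   list-column `peak_ids`.
#' @export
find_peak_pairs <- function(clusters, scheme = labeling_scheme(),
                            ppm_tol = 10, rt_tol = 6, n_range = c(2L, 36L),
                            min_members = 2L, consistency_min = 0.95) {
  stopifnot("channel" %in% names(clusters))
  n_min <- as.integer(n_range[1]); n_max <- as.integer(n_range[2])

  joint <- dplyr::filter(clusters, .data$channel == "joint",
                         .data$n_best >= n_min, .data$n_best <= n_max)
  joint_pairs <- if (nrow(joint) > 0) {
    tibble::tibble(
      sample_id = joint$sample_id, polarity = joint$polarity,
      carbon_count = joint$n_best,
      mz12 = joint$base_mz, mz13 = joint$top_mz, rt = joint$rt_apex,
      area_sample = joint$frac_sample * joint$total_area,
      area_is = joint$frac_is * joint$total_area,
      pair_score = joint$channel_score,
      gap_residual_ppm = purrr::map2_dbl(joint$top_mz - joint$base_mz,
                                         joint$charge, function(g, z) {
        z <- if (is.na(z)) 1L else z
        estimate_carbon_count(g, z, max_carbons = n_max)$residual_ppm
      }),
      cluster_sample = joint$cluster_id, cluster_is = joint$cluster_id,
      peak_ids = joint$peak_ids
    )
  } else empty_pair_table()

  s_cl <- dplyr::filter(clusters, .data$channel == "sample",
                        .data$n_members >= min_members)
  i_cl <- dplyr::filter(clusters, .data$channel == "is",
                        .data$n_members >= min_members)
  cand <- list()
  for (si in seq_len(nrow(s_cl))) {
    s <- s_cl[si, ]
    for (ii in seq_len(nrow(i_cl))) {
      i <- i_cl[ii, ]
      if (abs(s$rt_apex - i$rt_apex) > rt_tol) next
      z <- dplyr::coalesce(s$charge, i$charge, 1L)
      if (!is.na(s$charge) && !is.na(i$charge) && s$charge != i$charge) next
      gap <- i$top_mz - s$base_mz
      if (gap <= 0) next
      est <- estimate_carbon_count(gap, z, max_carbons = n_max)
      n <- est$n
      if (is.na(n) || n < n_min) next
      # the gap is a difference of two measured m/z values: sqrt(2) widening
      if (abs(gap - n * delta_c13 / z) > sqrt(2) * ppm_tol * 1e-6 * i$top_mz) next
      sc_s <- channel_template_score(s$envelope[[1]], n, scheme$p13_sample, "left")
      sc_i <- channel_template_score(i$envelope[[1]], n, scheme$p13_is, "right")
      if (is.na(sc_s) || is.na(sc_i) ||
          sc_s < consistency_min || sc_i < consistency_min) next
      cand[[length(cand) + 1L]] <- tibble::tibble(
        sample_id = s$sample_id, polarity = s$polarity, carbon_count = n,
        mz12 = s$base_mz, mz13 = i$top_mz, rt = s$rt_apex,
        area_sample = s$total_area, area_is = i$total_area,
        pair_score = (sc_s + sc_i) / 2,
        gap_residual_ppm = est$residual_ppm,
        cluster_sample = s$cluster_id, cluster_is = i$cluster_id,
        peak_ids = list(c(s$peak_ids[[1]], i$peak_ids[[1]])),
        rt_diff = abs(s$rt_apex - i$rt_apex)
      )
    }
  }
  cross <- if (length(cand) > 0) {
    cand <- purrr::list_rbind(cand)
    cand <- dplyr::arrange(cand, dplyr::desc(.data$pair_score),
                           abs(.data$gap_residual_ppm), .data$rt_diff,
                           dplyr::desc(.data$area_is))
    used_s <- integer(0); used_i <- integer(0); keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      if (cand$cluster_sample[r] %in% used_s || cand$cluster_is[r] %in% used_i) next
      keep[r] <- TRUE
      used_s <- c(used_s, cand$cluster_sample[r])
      used_i <- c(used_i, cand$cluster_is[r])
    }
    dplyr::select(cand[keep, ], -"rt_diff")
  } else empty_pair_table()

  out <- dplyr::bind_rows(joint_pairs, cross)
  dplyr::arrange(out, .data$mz12)
}

empty_pair_table <- function() {
  tibble::tibble(
    sample_id = character(), polarity = character(), carbon_count = integer(),
    mz12 = numeric(), mz13 = numeric(), rt = numeric(),
    area_sample = numeric(), area_is = numeric(), pair_score = numeric(),
    gap_residual_ppm = numeric(), cluster_sample = integer(),
    cluster_is = integer(), peak_ids = list()
  )
}

#' Align peak pairs across runs into a metabolite-by-sample table
#'
#' Greedy centroid alignment per polarity: rows are seeded from the run with
#' the most pairs; a pair from another run joins a row when the carbon count
#' matches exactly, `mz12` is within `ppm_tol` of the row's running-mean
#' centroid, and retention time is within `rt_tol`. Unmatched pairs open new
#' rows. When two pairs from one run claim one row, the higher pair score is
#' kept and the collision is reported as a message.
#'
#' @param pairs Pair table from [find_peak_pairs()], any number of runs
#'   (rows from multiple calls bound together). A pre-existing `row_id`
#'   column is ignored, so aligning an aligned table is a no-op.
#' @param ppm_tol m/z tolerance in ppm. Default 10.
#' @param rt_tol Retention-time tolerance in seconds. Default 12: between-run
#'   retention drift exceeds within-run co-elution spread, so the alignment
#'   window is wider than the pairing window.
#' @return A long tibble, one row per (metabolite row, run) with columns
#'   `row_id`, `polarity`, `carbon_count`, `mz12`, `mz13`, `rt` (consensus
#'   centroids), `sample_id`, `area_sample`, `area_is`, `pair_score`, plus
#'   the per-run `peak_ids`.
#' @export
align_pairs_across_samples <- function(pairs, ppm_tol = 10, rt_tol = 12) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) == 0L) {
    return(dplyr::mutate(empty_pair_table(), row_id = character()))
  }
  pairs$row_id <- NULL
  out <- lapply(split(pairs, pairs$polarity), align_one_polarity,
                ppm_tol = ppm_tol, rt_tol = rt_tol)
  out <- purrr::list_rbind(out)
  dplyr::arrange(out, .data$row_id, .data$sample_id)
}

align_one_polarity <- function(pairs, ppm_tol, rt_tol) {
  prefix <- if (pairs$polarity[1] == "negative") "N" else "P"
  run_order <- names(sort(table(pairs$sample_id), decreasing = TRUE))
  # centroid state per row
  mz_c <- numeric(0); rt_c <- numeric(0); carbon <- integer(0); n_in <- integer(0)
  assign_row <- integer(nrow(pairs))
  pairs <- dplyr::arrange(pairs, match(.data$sample_id, run_order), .data$mz12)
  for (r in seq_len(nrow(pairs))) {
    p <- pairs[r, ]
    hit <- which(carbon == p$carbon_count &
                   abs(mz_c - p$mz12) <= ppm_tol * 1e-6 * mz_c &
                   abs(rt_c - p$rt) <= rt_tol)
    if (length(hit) > 0L) {
      hit <- hit[which.min(abs(mz_c[hit] - p$mz12))]
      prev <- seq_len(r - 1L)
      dup <- prev[!is.na(assign_row[prev]) & assign_row[prev] == hit &
                    pairs$sample_id[prev] == p$sample_id]
      if (length(dup) > 0L) {
        rlang::inform(sprintf(
          "alignment collision in run %s near m/z %.4f: keeping higher-scoring pair",
          p$sample_id, p$mz12))
        if (p$pair_score > max(pairs$pair_score[dup])) {
          assign_row[dup] <- NA_integer_
        } else {
          assign_row[r] <- NA_integer_
          next
        }
      }
      assign_row[r] <- hit
      mz_c[hit] <- (mz_c[hit] * n_in[hit] + p$mz12) / (n_in[hit] + 1L)
      rt_c[hit] <- (rt_c[hit] * n_in[hit] + p$rt) / (n_in[hit] + 1L)
      n_in[hit] <- n_in[hit] + 1L
    } else {
      mz_c <- c(mz_c, p$mz12); rt_c <- c(rt_c, p$rt)
      carbon <- c(carbon, p$carbon_count); n_in <- c(n_in, 1L)
      assign_row[r] <- length(mz_c)
    }
  }
  keep <- !is.na(assign_row)
  pairs <- pairs[keep, ]; assign_row <- assign_row[keep]
  # consolidation: running-mean centroids can drift a noisy run out of reach
  # and split one metabolite over two rows; merge co-located rows with equal
  # carbon counts (run collisions resolved by pair score)
  repeat {
    merged <- FALSE
    support <- tabulate(assign_row, nbins = length(mz_c))
    ord <- order(-support, mz_c)
    for (ri in ord) {
      if (support[ri] == 0L) next
      # slightly wider than the cell-level window: the centroids of a split
      # row sit on opposite sides of the outlier run that caused the split
      rivals <- which(abs(mz_c - mz_c[ri]) <= 1.5 * ppm_tol * 1e-6 * mz_c[ri] &
                        abs(rt_c - rt_c[ri]) <= rt_tol &
                        carbon == carbon[ri] & seq_along(mz_c) != ri &
                        support > 0L)
      for (rj in rivals) {
        cells_j <- which(assign_row == rj)
        for (cj in cells_j) {
          dup <- which(assign_row == ri &
                         pairs$sample_id == pairs$sample_id[cj])
          if (length(dup) > 0L &&
              max(pairs$pair_score[dup]) >= pairs$pair_score[cj]) {
            assign_row[cj] <- NA_integer_
          } else {
            if (length(dup) > 0L) assign_row[dup] <- NA_integer_
            assign_row[cj] <- ri
          }
        }
        keep <- !is.na(assign_row)
        pairs <- pairs[keep, ]; assign_row <- assign_row[keep]
        cells_i <- which(assign_row == ri)
        mz_c[ri] <- mean(pairs$mz12[cells_i])
        rt_c[ri] <- mean(pairs$rt[cells_i])
        support <- tabulate(assign_row, nbins = length(mz_c))
        merged <- TRUE
      }
      if (merged) break
    }
    if (!merged) break
  }
  # consensus carbon count: when two rows co-locate (same feature) but read
  # different carbon counts, the better-supported row wins and the shadow row
  # (typically a noise-truncated or artifact-extended chain) is dropped
  support <- tabulate(assign_row, nbins = length(mz_c))
  score_sum <- vapply(seq_along(mz_c), function(ri) {
    sum(pairs$pair_score[assign_row == ri])
  }, numeric(1))
  drop_row <- rep(FALSE, length(mz_c))
  for (ri in seq_along(mz_c)) {
    rivals <- which(abs(mz_c - mz_c[ri]) <= ppm_tol * 1e-6 * mz_c[ri] &
                      abs(rt_c - rt_c[ri]) <= rt_tol & carbon != carbon[ri])
    for (rj in rivals) {
      weaker <- if (support[ri] != support[rj]) {
        if (support[ri] < support[rj]) ri else rj
      } else if (score_sum[ri] != score_sum[rj]) {
        if (score_sum[ri] < score_sum[rj]) ri else rj
      } else max(ri, rj)
      drop_row[weaker] <- TRUE
    }
  }
  if (any(drop_row[assign_row])) {
    rlang::inform(sprintf(
      "dropping %d shadow row(s) with conflicting carbon counts",
      sum(drop_row)))
    keep <- !drop_row[assign_row]
    pairs <- pairs[keep, ]; assign_row <- assign_row[keep]
  }
  # stable row ids ordered by consensus m/z
  rank <- rank(mz_c, ties.method = "first")
  row_ids <- sprintf("%s%04d", prefix, rank)
  tibble::tibble(
    row_id = row_ids[assign_row],
    polarity = pairs$polarity,
    carbon_count = pairs$carbon_count,
    mz12 = mz_c[assign_row],
    mz13 = mz_c[assign_row] + pairs$carbon_count * delta_c13,
    rt = rt_c[assign_row],
    sample_id = pairs$sample_id,
    area_sample = pairs$area_sample,
    area_is = pairs$area_is,
    pair_score = pairs$pair_score,
    peak_ids = pairs$peak_ids
  )
}

#' Row-level features of an aligned pair table
#'
#' @param pair_table Output of [align_pairs_across_samples()].
#' @return One row per metabolite: `row_id`, `polarity`, `carbon_count`,
#'   `mz12`, `mz13`, `rt`, `n_runs`.
#' @export
pair_features <- function(pair_table) {
  dplyr::summarise(
    dplyr::group_by(pair_table, .data$row_id, .data$polarity,
                    .data$carbon_count),
    mz12 = .data$mz12[1], mz13 = .data$mz13[1], rt = .data$rt[1],
    n_runs = dplyr::n(), .groups = "drop"
  )
}
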