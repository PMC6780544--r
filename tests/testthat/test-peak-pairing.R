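leucine_mz <- 132.1019051

test_that("clustering chains co-eluting peaks spaced by the 13C gap", {
  peaks <- tibble::tibble(
    sample_id = "r1", polarity = "positive",
    mz = c(132.1019, 133.1053), rt = c(100, 100), intensity = c(1000, 300)
  )
  cl <- cluster_isotopologues(peaks)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$n_members, 2L)
  expect_identical(cl$charge, 1L)
  # an isolated peak forms a singleton
  single <- cluster_isotopologues(peaks[1, ])
  expect_identical(single$n_members, 1L)
  expect_true(is.na(single$charge))
  # a 0.5 Th gap does not chain at charge 1
  apart <- dplyr::mutate(peaks, mz = c(132.1019, 132.6019))
  expect_identical(nrow(cluster_isotopologues(apart)), 2L)
  # co-elution is required
  late <- dplyr::mutate(peaks, rt = c(100, 150))
  expect_identical(nrow(cluster_isotopologues(late)), 2L)
  expect_identical(nrow(cluster_isotopologues(peaks[0, ])), 0L)
})

test_that("every peak lands in exactly one cluster", {
  st <- simulate_iroa_study(n_metabolites = 40, seed = 5)
  run <- dplyr::filter(st$peaks, sample_id == "S01")
  cl <- cluster_isotopologues(run)
  ids <- unlist(cl$peak_ids)
  expect_identical(sort(ids), sort(run$peak_id))
})

test_that("channel classification recognizes pure and mirrored envelopes", {
  env6 <- carbon_isotopologue_envelope(6, 0.05)
  base_cluster <- function(envelope, base = 100) {
    k <- seq_along(envelope) - 1L
    tibble::tibble(
      cluster_id = 1L, sample_id = "r1", polarity = "positive", charge = 1L,
      n_members = length(envelope), base_mz = base,
      top_mz = base + max(k) * delta_c13, rt_apex = 50, total_area = 1,
      envelope = list(envelope), member_mz = list(base + k * delta_c13),
      peak_ids = list(sprintf("p%d", k))
    )
  }
  out <- classify_cluster_channel(base_cluster(env6))
  expect_identical(out$channel, "sample")
  expect_identical(out$n_best, 6L)
  expect_equal(out$channel_score, 1, tolerance = 1e-9)
  mirrored <- classify_cluster_channel(base_cluster(rev(env6)))
  expect_identical(mirrored$channel, "is")
  expect_identical(mirrored$n_best, 6L)
  # a flat two-member envelope fits no binomial template at min_score 0.95
  flat <- classify_cluster_channel(base_cluster(c(0.5, 0.5)),
                                   min_score = 0.95)
  expect_identical(flat$channel, "unclassified")
})

test_that("merged low-carbon clusters are recognized as joint and split by the mixture fit", {
  scheme <- labeling_scheme()
  a <- 3000; b <- 7000
  env <- a * carbon_isotopologue_envelope(3, 0.05) +
    b * carbon_isotopologue_envelope(3, 0.95)
  cl <- tibble::tibble(
    cluster_id = 1L, sample_id = "r1", polarity = "positive", charge = 1L,
    n_members = 4L, base_mz = 90, top_mz = 90 + 3 * delta_c13,
    rt_apex = 70, total_area = sum(env), envelope = list(env / sum(env)),
    member_mz = list(90 + 0:3 * delta_c13), peak_ids = list(sprintf("p%d", 0:3))
  )
  out <- classify_cluster_channel(cl, scheme)
  expect_identical(out$channel, "joint")
  expect_identical(out$n_best, 3L)
  expect_equal(out$frac_sample, a / (a + b), tolerance = 1e-6)
  pairs <- find_peak_pairs(out, scheme)
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$carbon_count, 3L)
  expect_equal(pairs$area_sample, a, tolerance = 1e-6 * a)
  expect_equal(pairs$area_is, b, tolerance = 1e-6 * b)
})

test_that("pairing joins co-eluting twin clusters and excludes lone signals", {
  scheme <- labeling_scheme()
  peaks <- dplyr::bind_rows(
    make_pair_peaks(leucine_mz, 6, rt = 100, area_sample = 2e5, area_is = 1e5),
    make_pair_peaks(304.2999, 20, rt = 400, area_sample = 5e4, area_is = 8e4)
  )
  cl <- classify_cluster_channel(cluster_isotopologues(peaks), scheme)
  pairs <- find_peak_pairs(cl, scheme)
  expect_identical(nrow(pairs), 2L)
  leu <- pairs[which.min(pairs$mz12), ]
  expect_identical(leu$carbon_count, 6L)
  expect_equal(leu$mz12, leucine_mz)
  expect_equal(leu$mz13, leucine_mz + 6 * delta_c13)
  env6 <- carbon_isotopologue_envelope(6, 0.05)
  coverage <- sum(env6[env6 >= 0.005 * max(env6)])
  expect_equal(leu$area_sample, 2e5 * coverage)
  # a lone sample-channel cluster is excluded as an artifact
  lone <- dplyr::filter(peaks, mz < 140)[1:3, ]
  cl_lone <- classify_cluster_channel(cluster_isotopologues(lone), scheme)
  expect_identical(nrow(find_peak_pairs(cl_lone, scheme)), 0L)
  # twin clusters that do not co-elute are not paired
  apart <- dplyr::bind_rows(
    make_pair_peaks(leucine_mz, 6, rt = 100, area_sample = 2e5, area_is = 0),
    make_pair_peaks(leucine_mz, 6, rt = 130, area_sample = 0, area_is = 1e5)
  )
  cl_apart <- classify_cluster_channel(cluster_isotopologues(apart), scheme)
  expect_identical(nrow(find_peak_pairs(cl_apart, scheme)), 0L)
})

test_that("alignment merges the same pair across runs and separates distinct features", {
  one_run <- function(id, mz_shift = 0, rt_shift = 0, score = 1) {
    tibble::tibble(
      sample_id = id, polarity = "positive", carbon_count = 6L,
      mz12 = leucine_mz * (1 + mz_shift * 1e-6), mz13 = leucine_mz + 6 * delta_c13,
      rt = 100 + rt_shift, area_sample = 1000, area_is = 500,
      pair_score = score, gap_residual_ppm = 0,
      cluster_sample = 1L, cluster_is = 2L, peak_ids = list("p1")
    )
  }
  pairs <- dplyr::bind_rows(lapply(sprintf("S%02d", 1:8), one_run))
  tbl <- align_pairs_across_samples(pairs)
  expect_identical(dplyr::n_distinct(tbl$row_id), 1L)
  expect_identical(nrow(tbl), 8L)
  # a pair absent from one run leaves that cell missing
  tbl7 <- align_pairs_across_samples(pairs[-3, ])
  expect_identical(nrow(tbl7), 7L)
  # two co-eluting metabolites 50 ppm apart stay separate at 10 ppm
  two <- dplyr::bind_rows(one_run("S01"), one_run("S01", mz_shift = 50))
  expect_identical(dplyr::n_distinct(align_pairs_across_samples(two)$row_id), 2L)
  # idempotence: aligning an aligned table changes nothing
  realigned <- align_pairs_across_samples(tbl)
  expect_equal(dplyr::select(realigned, -"row_id"),
               dplyr::select(tbl, -"row_id"))
  expect_identical(realigned$row_id, tbl$row_id)
})

test_that("no artifact peak ever enters a pair on stressed synthetic data", {
  st <- stress_study()
  pt <- stress_pairs()
  art_ids <- st$peaks$peak_id[st$peaks$channel == "artifact"]
  expect_identical(sum(unlist(pt$peak_ids) %in% art_ids), 0L)
})

test_that("detectable metabolites are recovered with correct carbon counts", {
  ev <- evaluate_detection(stress_study(), stress_pairs())
  expect_gte(ev$summary$recovery_rate, 0.95)
  expect_identical(ev$summary$carbon_accuracy, 1)
})
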