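test_that("category counts follow the configured fractions exactly", {
  st <- simulate_iroa_study(n_metabolites = 100, frac_up = 0.10,
                            frac_down = 0.10, frac_on = 0.05,
                            frac_off = 0.05, seed = 1)
  counts <- table(st$truth$category)
  expect_identical(as.integer(counts[c("up", "down", "on", "off")]),
                   c(10L, 10L, 5L, 5L))
  expect_identical(as.integer(counts["unchanged"]), 70L)
  expect_error(simulate_iroa_study(frac_up = 0.8, frac_down = 0.4, seed = 1),
               "sum to <= 1")
})

test_that("identical seeds reproduce the study; different seeds differ", {
  a <- simulate_iroa_study(n_metabolites = 30, seed = 9)
  b <- simulate_iroa_study(n_metabolites = 30, seed = 9)
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$truth, b$truth)
  c <- simulate_iroa_study(n_metabolites = 30, seed = 10)
  expect_false(identical(a$peaks, c$peaks))
})

test_that("with no artifacts every peak belongs to a true metabolite", {
  st <- simulate_iroa_study(n_metabolites = 30, artifact_rate = 0, seed = 2)
  expect_false(any(is.na(st$peaks$metabolite_id)))
  expect_true(all(st$peaks$channel %in% c("sample", "is", "both")))
})

test_that("the IS channel is one pooled mixture: identical across runs up to noise", {
  st <- simulate_iroa_study(n_metabolites = 40, replicate_cv = 0.05, seed = 3)
  spread <- dplyr::summarise(
    dplyr::group_by(st$channel_areas, metabolite_id),
    cv = sd(area_is) / mean(area_is), .groups = "drop")
  expect_true(all(spread$cv < 0.15))
  # and matches the pooled mean of the two group means
  joined <- dplyr::left_join(
    dplyr::summarise(dplyr::group_by(st$channel_areas, metabolite_id),
                     mean_is = mean(area_is), .groups = "drop"),
    st$truth, by = "metabolite_id")
  expect_equal(joined$mean_is,
               (joined$treatment_mean + joined$control_mean) / 2,
               tolerance = 0.1)
})

test_that("on metabolites lack the control sample channel but keep an IS channel", {
  st <- simulate_iroa_study(n_metabolites = 60, frac_on = 0.1, frac_off = 0.1,
                            seed = 4)
  on_ids <- st$truth$metabolite_id[st$truth$category == "on"]
  ctrl <- st$design$sample_id[st$design$group == "control"]
  on_ctrl <- dplyr::filter(st$peaks, metabolite_id %in% on_ids,
                           sample_id %in% ctrl)
  expect_true(all(on_ctrl$channel == "is"))
  expect_gt(nrow(on_ctrl), 0)
  # off metabolites mirror this in the treatment runs
  off_ids <- st$truth$metabolite_id[st$truth$category == "off"]
  trt <- st$design$sample_id[st$design$group == "treatment"]
  off_trt <- dplyr::filter(st$peaks, metabolite_id %in% off_ids,
                           sample_id %in% trt)
  expect_true(all(off_trt$channel == "is"))
})

test_that("emitted peaks sit on the isotopologue grid within the mass noise", {
  st <- simulate_iroa_study(n_metabolites = 20, mass_noise_ppm = 1, seed = 5)
  joined <- dplyr::inner_join(st$peaks,
                              dplyr::select(st$truth, metabolite_id, mono12_mz),
                              by = "metabolite_id")
  k <- round((joined$mz - joined$mono12_mz) / delta_c13)
  resid_ppm <- (joined$mz - (joined$mono12_mz + k * delta_c13)) /
    joined$mz * 1e6
  expect_true(all(abs(resid_ppm) < 6))  # within ~5 sigma of 1 ppm noise
  expect_true(all(joined$intensity >= st$config$loq))
})

test_that("a written study round-trips through the TSV dialect", {
  st <- simulate_iroa_study(n_metabolites = 15, seed = 6)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  files <- list.files(dir)
  expect_length(grep("^peaks_.*\\.tsv$", files), 8L)
  expect_true(all(c("ground_truth.csv", "design.csv", "config.yaml") %in% files))
  back <- read_peaks(file.path(dir, "peaks_S01.tsv"))
  orig <- dplyr::filter(st$peaks, sample_id == "S01")
  expect_equal(back$mz, orig$mz)
  expect_equal(back$rt, orig$rt)
  expect_equal(back$intensity, orig$intensity)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_identical(cfg$seed, 6L)
  expect_identical(cfg$n_metabolites, 15L)
})
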