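# Small hand-built pair tables exercise the ratio, imputation and
# regulation rules cell by cell.

design8 <- tibble::tibble(
  sample_id = sprintf("S%02d", 1:8),
  group = rep(c("control", "treatment"), each = 4)
)

make_table <- function(area_sample, area_is, row_id = "P0001") {
  tibble::tibble(
    row_id = row_id, polarity = "positive", carbon_count = 6L,
    mz12 = 132.1019, mz13 = 138.122, rt = 100,
    sample_id = design8$sample_id[seq_along(area_sample)],
    area_sample = area_sample, area_is = area_is, pair_score = 1,
    peak_ids = replicate(length(area_sample), "p", simplify = FALSE)
  )[!is.na(area_sample) | !is.na(area_is), ]
}

test_that("ratios divide channel areas and censor at the LOQ", {
  tbl <- make_table(c(200, 100, 50, 100, 400, 400, 400, 400),
                    rep(100, 8))
  r <- compute_ratios(tbl, design8, loq = 80)
  expect_equal(r$ratio[r$sample_id == "S01"], 2)
  expect_equal(r$ratio[r$sample_id == "S02"], 1)
  # sample area below LOQ gives a missing, flagged cell
  expect_true(is.na(r$ratio[r$sample_id == "S03"]))
  expect_false(r$observed[r$sample_id == "S03"])
  expect_true(all(r$quantifiable))
})

test_that("rows whose IS is below LOQ in half the detected runs are unquantifiable", {
  tbl <- make_table(rep(400, 8), c(10, 10, 10, 10, 100, 100, 100, 100))
  r <- compute_ratios(tbl, design8, loq = 80)
  expect_true(all(!r$quantifiable))
  expect_message(imp <- impute_missing(r), "unquantifiable")
  expect_identical(nrow(imp), 0L)
})

test_that("a zero IS area never divides; the cell goes missing", {
  tbl <- make_table(c(400, 400, 400, 400, 400, 400, 400, 400),
                    c(0, rep(100, 7)))
  r <- compute_ratios(tbl, design8, loq = 0)
  expect_true(is.na(r$ratio[r$sample_id == "S01"]))
  expect_true(all(!is.na(r$ratio[r$sample_id != "S01"])))
})

test_that("imputation fills missing cells with half the row minimum", {
  tbl <- make_table(c(200, NA, 100, 150, 200, 200, 200, 200), rep(100, 8))
  r <- compute_ratios(tbl, design8, loq = 0)
  imp <- impute_missing(r)
  expect_equal(imp$ratio[imp$sample_id == "S02"], 0.5)  # half of min 1.0
  expect_true(imp$imputed[imp$sample_id == "S02"])
  expect_false(any(imp$imputed[imp$sample_id != "S02"]))
  # no missing cells: imputation is the identity on ratios
  full <- compute_ratios(make_table(rep(200, 8), rep(100, 8)), design8, loq = 0)
  expect_identical(impute_missing(full)$ratio, full$ratio)
  # imputed values never exceed the observed row minimum
  expect_true(all(imp$ratio[imp$imputed] <= min(imp$ratio[!imp$imputed])))
})

test_that("log2 fold change compares arithmetic group means", {
  tbl <- make_table(c(100, 100, 100, 100, 200, 200, 200, 200), rep(100, 8))
  imp <- impute_missing(compute_ratios(tbl, design8, loq = 0))
  fc <- log2_fold_change(imp)
  expect_equal(fc$log2fc, 1)
  expect_equal(log2_fold_change(imp, method = "geometric")$log2fc, 1)
  even <- make_table(rep(100, 8), rep(100, 8))
  expect_equal(
    log2_fold_change(impute_missing(compute_ratios(even, design8, 0)))$log2fc, 0)
})

test_that("the internal standard cancels: rescaling IS areas leaves the fold change unchanged", {
  tbl <- make_table(c(100, 110, 90, 100, 420, 380, 400, 400),
                    c(100, 105, 95, 100, 101, 99, 100, 100))
  fc1 <- log2_fold_change(impute_missing(compute_ratios(tbl, design8, 0)))
  tbl2 <- dplyr::mutate(tbl, area_is = area_is * 7.3)
  fc2 <- log2_fold_change(impute_missing(compute_ratios(tbl2, design8, 0)))
  expect_equal(fc1$log2fc, fc2$log2fc)
})

test_that("regulation classes follow the on/off and threshold rules", {
  # observed in all treatment runs, absent from every control run: initiated
  on_tbl <- make_table(c(NA, NA, NA, NA, 400, 420, 380, 400),
                       c(NA, NA, NA, NA, 100, 100, 100, 100))
  imp <- impute_missing(compute_ratios(on_tbl, design8, loq = 0))
  reg <- classify_regulation(imp)
  expect_identical(as.character(reg$category), "initiated")
  # the mirror image is terminated
  off_tbl <- make_table(c(400, 420, 380, 400, NA, NA, NA, NA),
                        c(100, 100, 100, 100, NA, NA, NA, NA))
  imp_off <- impute_missing(compute_ratios(off_tbl, design8, loq = 0))
  expect_identical(as.character(classify_regulation(imp_off)$category),
                   "terminated")
  # strong shift with tiny p: upregulated
  up_tbl <- make_table(c(100, 101, 99, 100, 570, 560, 580, 570), rep(100, 8))
  imp_up <- impute_missing(compute_ratios(up_tbl, design8, loq = 0))
  reg_up <- classify_regulation(imp_up, fc_threshold = 1, alpha = 0.001)
  expect_identical(as.character(reg_up$category), "upregulated")
  expect_gt(reg_up$log2fc, 2)
  # small shift, large p: unchanged
  flat_tbl <- make_table(c(100, 140, 80, 100, 120, 90, 130, 100), rep(100, 8))
  imp_flat <- impute_missing(compute_ratios(flat_tbl, design8, loq = 0))
  expect_identical(as.character(classify_regulation(imp_flat)$category),
                   "unchanged")
})

test_that("targeted extraction matches panel entries by carbon count and adduct m/z", {
  leu_mz <- adduct_mz(monoisotopic_mass("C6H13NO2"))
  tbl <- dplyr::mutate(
    make_table(c(100, 100, 100, 100, 200, 200, 200, 200), rep(100, 8)),
    mz12 = leu_mz
  )
  imp <- impute_missing(compute_ratios(tbl, design8, loq = 0))
  panel <- tibble::tibble(
    name = c("leucine", "missing DKP"),
    formula = c("C6H13NO2", "C15H18N2O2"),
    adducts = "[M+H]+", pathway_position = c("precursor", "product")
  )
  out <- targeted_extract(tbl, panel, imp)
  expect_identical(out$found, c(TRUE, FALSE))
  expect_equal(out$log2fc[1], 1)
  expect_true(is.na(out$log2fc[2]))
  # a formula with the right mass but wrong carbon count does not match:
  # C6H13NO2 vs a hypothetical 7-carbon isobar is impossible, so emulate by
  # shifting the row's carbon count
  tbl7 <- dplyr::mutate(tbl, carbon_count = 7L)
  out7 <- targeted_extract(tbl7, panel[1, ], imp)
  expect_false(out7$found)
})

test_that("estimated fold changes track the simulated truth", {
  st <- stress_study()
  imp <- stress_ratios()
  reg <- classify_regulation(imp)
  fc <- log2_fold_change(imp)
  eq <- evaluate_quantification(st, stress_pairs(), reg, fc)
  expect_lte(eq$rmse_log2fc, 0.25)
  expect_gte(eq$onoff_sensitivity, 0.95)
})
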