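test_that("formula parsing and printing round-trip over CHNOSP", {
  counts <- parse_formula("C6H13NO2")
  expect_equal(counts$C, 6L)
  expect_equal(counts$H, 13L)
  expect_equal(counts$N, 1L)
  expect_equal(counts$O, 2L)
  expect_equal(formula_string(counts), "C6H13NO2")
  expect_equal(formula_string(parse_formula("H2O")), "H2O")
  expect_error(parse_formula("C2FeO4"), "unsupported element")
})

test_that("monoisotopic masses match elementwise sums", {
  expect_equal(monoisotopic_mass("H2O"), 18.0105647, tolerance = 1e-7)
  expect_equal(monoisotopic_mass("C6H13NO2"), 131.0946287, tolerance = 1e-7)
  expect_equal(monoisotopic_mass(c(C = 0, H = 0)), 0)  # empty formula
  expect_error(monoisotopic_mass(c(C = -1, H = 2)), "non-negative")
})

test_that("adduct arithmetic is consistent and invertible", {
  leu <- monoisotopic_mass("C6H13NO2")
  expect_equal(adduct_mz(leu, "[M+H]+"), 132.1019051, tolerance = 1e-7)
  m <- 250.1234
  expect_equal(adduct_mz(m, "[M-H]-"), m - 1.0072765)
  for (a in iroa_adducts()$adduct) {
    expect_equal(neutral_from_mz(adduct_mz(m, a), a), m)
  }
  expect_error(adduct_mz(m, "[M+K]+"), "unknown adduct")
})

test_that("carbon-constrained enumeration finds the 16-carbon worked example", {
  # carbon count 16 from the peak pair + printed [M+H]+ m/z 385.1761; the
  # printed ion sits ~11 ppm from the theoretical mass, so 15 ppm is needed
  hits <- enumerate_formulas(neutral_from_mz(385.1761), 16, tol_ppm = 15,
                             element_bounds = list(H = 40, N = 8, O = 12))
  expect_true("C16H24N4O7" %in% hits$formula)
  # shrinking the tolerance below the ~11 ppm deviation removes it
  tight <- enumerate_formulas(neutral_from_mz(385.1761), 16, tol_ppm = 5,
                              element_bounds = list(H = 40, N = 8, O = 12))
  expect_false("C16H24N4O7" %in% tight$formula)
})

test_that("enumeration respects the carbon constraint, bounds and monotonicity", {
  hits <- enumerate_formulas(131.09463, 6, tol_ppm = 5)
  expect_true("C6H13NO2" %in% hits$formula)
  expect_true(all(hits$C == 6L))
  expect_identical(nrow(enumerate_formulas(50.0, 2, tol_ppm = 5)), 0L)
  # shrinking tolerance never adds formulas
  wide <- enumerate_formulas(300.1, 12, tol_ppm = 20)
  narrow <- enumerate_formulas(300.1, 12, tol_ppm = 5)
  expect_true(all(narrow$formula %in% wide$formula))
})

test_that("enumeration agrees with brute-force search on random cases", {
  set.seed(4)
  for (i in 1:20) {
    n_c <- sample(2:24, 1)
    mass <- runif(1, 12 * n_c, min(500, 12 * n_c + 200))
    mine <- enumerate_formulas(mass, n_c, tol_ppm = 10,
                               element_bounds = list(H = 50, N = 10, O = 15))
    ref <- brute_force_formulas(mass, n_c, tol_ppm = 10,
                                h_max = 50, n_max = 10, o_max = 15)
    expect_identical(formula_key(mine), brute_key(ref))
  }
})

test_that("enumeration round-trips its own masses", {
  pool <- metabolite_formula_pool()
  set.seed(7)
  for (f in pool$formula[sample.int(nrow(pool), 15)]) {
    counts <- parse_formula(f)
    hits <- enumerate_formulas(monoisotopic_mass(f), counts$C, tol_ppm = 1,
                               element_bounds = list(H = 80, N = 12, O = 20))
    expect_true(formula_string(counts) %in% hits$formula)
  }
})

test_that("library matching gates on carbon count, mass, retention time and polarity", {
  lib <- tibble::tibble(
    name = c("leucine", "phenylalanine"),
    formula = c("C6H13NO2", "C9H11NO2"),
    rt_sec = c(120, 300), polarity = "positive"
  )
  features <- tibble::tibble(
    row_id = "P0001", carbon_count = 6L,
    mz12 = 132.1019, rt = 121, polarity = "positive"
  )
  hit <- library_match(features, lib)
  expect_identical(hit$name, "leucine")
  expect_lt(abs(hit$mass_error_ppm), 1)
  # retention time too far off
  expect_identical(nrow(library_match(
    dplyr::mutate(features, rt = 500), lib)), 0L)
  # correct mass but wrong carbon count is rejected
  expect_identical(nrow(library_match(
    dplyr::mutate(features, carbon_count = 7L), lib)), 0L)
  # opposite polarity is rejected
  expect_identical(nrow(library_match(
    dplyr::mutate(features, polarity = "negative"), lib)), 0L)
})
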