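test_that("per-test cost reproduces the published batch table to the cent", {
  tab <- batch_cost_table(1:6)
  published <- data.frame(
    manpower = c(38.98, 19.49, 12.99, 9.74, 7.80, 6.50) +
      c(23.12, 11.56, 7.71, 5.78, 4.62, 3.85) +
      c(3.30, 1.65, 1.10, 0.83, 0.66, 0.55),
    dna_reagent = rep(1.46, 6),
    pcr_reagent = c(8.56, 5.13, 3.99, 3.42, 3.08, 2.85),
    pcr_material = c(1.07, 0.64, 0.50, 0.43, 0.39, 0.36),
    total = c(76.50, 39.94, 27.76, 21.67, 18.01, 15.57)
  )
  for (col in names(published)) {
    expect_true(all(abs(tab[[col]] - published[[col]]) <= 0.011),
                label = sprintf("column %s within one cent", col))
  }
})

test_that("per-test components scale exactly as 1/n and (n+4)/n", {
  one <- per_test_cost(1)
  for (n in 2:6) {
    b <- per_test_cost(n)
    expect_equal(b$manpower, one$manpower / n)
    expect_equal(b$pcr_reagent, one$pcr_reagent / 5 * (n + 4) / n)
    expect_equal(b$dna_reagent, one$dna_reagent)
  }
  totals <- batch_cost_table(1:6)$total_unrounded
  expect_true(all(diff(totals) < 0))
  # large batches approach the pure per-sample reagent floor
  big <- suppressWarnings(per_test_cost(1000))
  expect_lt(abs(big$total_unrounded - (1.46 + 8.56 / 5 + 1.07 / 5)), 0.2)
  expect_error(per_test_cost(0), "positive")
  expect_warning(per_test_cost(7), "extrapolate")
})

test_that("annual amortization is machine cost times the rate", {
  expect_equal(round(annual_amortization(), 2), 7272.97)
  expect_equal(annual_amortization(unit_costs(amortization_rate = 1)),
               36364.86)
  expect_equal(round(annual_amortization(unit_costs(amortization_rate = 0.10)), 2),
               3636.49)
})

test_that("scenario totals match the published annual figures", {
  pv <- printed_means()
  two <- scenario_costs(pv, 300, 2, convention = "dropout_adjusted")
  expect_lt(abs(two$standard_total - 64569.75) / 64569.75, 0.002)
  expect_lt(abs(two$genotyping_total - 60314.65) / 60314.65, 0.002)
  expect_lt(abs(two$savings - 4255.10) / 4255.10, 0.005)
  six <- scenario_costs(pv, 300, 6, convention = "dropout_adjusted")
  expect_lt(abs(six$genotyping_total - 53003.72) / 53003.72, 0.002)
  expect_lt(abs(six$savings - 11566.02) / 11566.02, 0.005)
  # the fixed amortization floor remains with zero patients
  none <- scenario_costs(pv, 0, 2)
  expect_equal(none$standard_total, 0)
  expect_equal(none$genotyping_total, annual_amortization())
})

test_that("savings identity holds for arbitrary inputs", {
  for (pv in random_pvs(10, seed = 55)) {
    n <- sample(0:500, 1)
    b <- sample(1:6, 1)
    conv <- sample(dose_conventions(), 1)
    sc <- scenario_costs(pv, n, b, convention = conv)
    expect_equal(sc$savings, sc$standard_total - sc$genotyping_total)
    expect_gte(sc$genotyping_total,
               n * per_test_cost(b)$total_unrounded - 1e-9)
  }
})

test_that("drug cost reduction percentage behaves at the published point and limits", {
  expect_lt(abs(drug_cost_reduction(printed_means()) - 35.83), 0.3)
  all_high <- probability_vector(1 - 1e-12, 0.139, 0.947, 0.748)
  expect_equal(drug_cost_reduction(all_high), 0, tolerance = 1e-6)
  none <- probability_vector(1e-12, 1e-12, 0.947, 0.748)
  expect_equal(drug_cost_reduction(none), 100, tolerance = 1e-6)
})

test_that("break-even thresholds match the published 155 and 102", {
  pv <- printed_means()
  expect_equal(breakeven_threshold(pv, 2), 155)
  expect_equal(breakeven_threshold(pv, 6), 102)
})

test_that("threshold edge cases: no fixed cost, no margin", {
  pv <- printed_means()
  free_machine <- unit_costs(machine_cost = 0)
  expect_equal(breakeven_threshold(pv, 2, free_machine), 1)
  # high-risk fraction near 1 leaves no margin to recover amortization
  hopeless <- probability_vector(0.999, 0.999, 0.9, 0.9)
  expect_error(breakeven_threshold(hopeless, 2), "never breaks even")
  expect_identical(breakeven_threshold(hopeless, 2, inf_on_no_margin = TRUE),
                   Inf)
})

test_that("threshold is consistent with the scenario totals and monotone", {
  pv <- printed_means()
  for (b in c(2, 6)) {
    n_star <- breakeven_threshold(pv, b)
    at <- scenario_costs(pv, n_star, b, convention = "intent_to_treat")
    below <- scenario_costs(pv, n_star - 1, b, convention = "intent_to_treat")
    expect_lte(at$genotyping_total, at$standard_total + 1e-9)
    expect_gt(below$genotyping_total, below$standard_total)
  }
  # nondecreasing in amortization; larger batches (cheaper tests) never raise it
  dear <- unit_costs(machine_cost = 36364.86 * 2)
  expect_gte(breakeven_threshold(pv, 2, dear), breakeven_threshold(pv, 2))
  expect_lte(breakeven_threshold(pv, 6), breakeven_threshold(pv, 2))
})

test_that("per-patient overall difference matches the published percentages", {
  pv <- printed_means()
  expect_lt(abs(per_patient_difference_percent(pv, 300, 2) - 9.45), 0.2)
  expect_lt(abs(per_patient_difference_percent(pv, 300, 6) - 19.46), 0.2)
  # with free testing and no amortization it reduces to the drug-only percent
  free <- unit_costs(dna_reagent_per_sample = 0, pcr_reagent_per_reaction = 0,
                     pcr_material_per_reaction = 0, manpower_rate_per_hour = 0,
                     machine_cost = 0)
  expect_equal(per_patient_difference_percent(pv, 300, 2, free),
               drug_cost_reduction(pv, free))
})
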