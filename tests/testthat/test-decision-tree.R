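test_that("probability vectors must be strictly interior", {
  expect_error(probability_vector(0, 0.5, 0.5, 0.5), "strictly")
  expect_error(probability_vector(0.5, 1, 0.5, 0.5), "strictly")
  pv <- probability_vector(0.587, 0.139, 0.947, 0.748)
  expect_s3_class(pv, "probability_vector")
})

test_that("standard branch doses: 3 under intent-to-treat, dropout-weighted otherwise", {
  pv <- printed_means()
  expect_equal(expected_doses_standard(pv, "intent_to_treat"), 3)
  expect_equal(expected_doses_standard(pv, "dropout_adjusted"),
               1 + 0.947 + 0.947 * 0.748)
  # no dropout collapses the two conventions
  nearly1 <- probability_vector(0.5, 0.2, 1 - 1e-12, 1 - 1e-12)
  expect_equal(expected_doses_standard(nearly1, "dropout_adjusted"), 3,
               tolerance = 1e-9)
})

test_that("published per-patient and annual figures are reproduced", {
  pv <- printed_means()
  price <- 81.08
  # intent-to-treat genotyping branch: ~1.925 doses, ~$156.08/patient
  d_itt <- expected_doses_genotyping(pv, "intent_to_treat")
  expect_lt(abs(d_itt - 1.925), 0.001)
  expect_lt(abs(d_itt * price - 156.08), 0.10)
  # dropout-adjusted standard branch: annual total for 300 patients
  d_std <- expected_doses_standard(pv, "dropout_adjusted")
  expect_lt(abs(d_std * price * 300 - 64569.75) / 64569.75, 0.001)
})

test_that("limiting cases of the genotyping branch", {
  # everyone high risk: identical to the standard branch
  all_high <- probability_vector(1 - 1e-12, 0.139, 0.947, 0.748)
  for (conv in dose_conventions()) {
    expect_equal(expected_doses_genotyping(all_high, conv),
                 expected_doses_standard(all_high, conv), tolerance = 1e-9)
  }
  # zero toxicity: low-risk patients never escalate
  no_tox <- probability_vector(0.6, 1e-12, 0.9, 0.8)
  expect_equal(expected_doses_genotyping(no_tox, "intent_to_treat"),
               0.6 * 3, tolerance = 1e-9)
})

test_that("closed forms equal the exhaustive path-enumeration oracle", {
  for (pv in c(list(printed_means()), random_pvs(20))) {
    for (conv in dose_conventions()) {
      expect_equal(expected_doses_standard(pv, conv),
                   enumerate_doses(pv, "standard", conv), tolerance = 1e-12)
      expect_equal(expected_doses_genotyping(pv, conv),
                   enumerate_doses(pv, "genotyping", conv), tolerance = 1e-12)
    }
  }
})

test_that("dominance, monotonicity, and convention ordering hold", {
  pvs <- random_pvs(40, seed = 71)
  for (pv in pvs) {
    for (conv in dose_conventions()) {
      g <- expected_doses_genotyping(pv, conv)
      s <- expected_doses_standard(pv, conv)
      expect_lte(g, s + 1e-12)
      expect_gte(g, 0)
      expect_lte(s, 3)
    }
    # dropout adjustment can only lower the expectation
    expect_lte(expected_doses_genotyping(pv, "dropout_adjusted"),
               expected_doses_genotyping(pv, "intent_to_treat") + 1e-12)
    expect_lte(expected_doses_standard(pv, "dropout_adjusted"),
               expected_doses_standard(pv, "intent_to_treat") + 1e-12)
  }
  # nondecreasing in P1 and in P2
  base <- probability_vector(0.4, 0.2, 0.9, 0.7)
  up_p1 <- probability_vector(0.6, 0.2, 0.9, 0.7)
  up_p2 <- probability_vector(0.4, 0.5, 0.9, 0.7)
  for (conv in dose_conventions()) {
    expect_gte(expected_doses_genotyping(up_p1, conv),
               expected_doses_genotyping(base, conv))
    expect_gte(expected_doses_genotyping(up_p2, conv),
               expected_doses_genotyping(base, conv))
  }
})
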