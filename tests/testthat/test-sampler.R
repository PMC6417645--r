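test_that("a fixed seed reproduces the chain exactly; seeds differ otherwise", {
  s <- sampler_settings(iterations = 3000, burn_in = 500, seed = 99)
  a <- mh_sample(binom_obs(45, 88), beta_prior(178, 114), s)
  b <- mh_sample(binom_obs(45, 88), beta_prior(178, 114), s)
  expect_identical(a$draws, b$draws)
  expect_identical(a$acceptance_rate, b$acceptance_rate)
  s2 <- s; s2$seed <- 100L
  c <- mh_sample(binom_obs(45, 88), beta_prior(178, 114), s2)
  expect_false(identical(a$draws, c$draws))
})

test_that("chain matches the conjugate closed form within Monte-Carlo error", {
  obs <- default_observations()
  pri <- default_priors()
  cases <- c(
    mapply(function(o, p) list(list(obs = o, prior = p)), obs, pri),
    random_obs_prior(6)
  )
  for (i in seq_along(cases)) {
    case <- cases[[i]]
    ch <- mh_sample(case$obs, case$prior,
                    sampler_settings(seed = 1000 + i))
    target <- prior_mean(conjugate_posterior(case$obs, case$prior))
    ess <- diagnose_chain(ch)$effective_sample_size
    mc_err <- stats::sd(ch$draws) / sqrt(ess)
    expect_lt(abs(mean(ch$draws) - target), 3 * mc_err)
    expect_true(all(ch$draws > 0 & ch$draws < 1))
  }
})

test_that("adaptation lands near the 44% acceptance target and is recorded", {
  ch <- mh_sample(binom_obs(86, 88), beta_prior(160, 12),
                  sampler_settings(seed = 7))
  expect_gt(ch$acceptance_rate, 0.25)
  expect_lt(ch$acceptance_rate, 0.65)
  expect_equal(length(ch$draws),
               ch$settings$iterations - ch$settings$burn_in)
})

test_that("extreme observations stay strictly inside the unit interval", {
  ch <- mh_sample(binom_obs(0, 10), beta_prior(1, 1),
                  sampler_settings(seed = 5))
  expect_true(all(ch$draws > 0 & ch$draws < 1))
  # conjugate mean of Beta(1, 11)
  expect_lt(abs(mean(ch$draws) - 1 / 12), 0.02)
})

test_that("settings constructor rejects impossible configurations", {
  expect_error(sampler_settings(iterations = 0), "positive")
  expect_error(sampler_settings(iterations = 100, burn_in = 100), "burn_in")
  expect_error(sampler_settings(proposal_scale = -1), "proposal_scale")
})

test_that("summaries give mean/median and equal-tailed interval", {
  ch <- mh_sample(binom_obs(64, 86), beta_prior(120, 40),
                  sampler_settings(seed = 31))
  sm <- summarize_chain(ch, 0.95)
  expect_lt(abs(sm$mean - 0.748), 0.01)
  expect_lt(abs(sm$ci_low - 0.692), 0.015)
  expect_lt(abs(sm$ci_high - 0.800), 0.015)
  expect_true(sm$ci_low <= sm$median && sm$median <= sm$ci_high)

  # degenerate chain collapses every summary to the single value
  const <- summarize_chain(rep(0.3, 100), 0.95)
  expect_equal(const$mean, 0.3)
  expect_equal(const$median, 0.3)
  expect_equal(const$ci_low, 0.3)
  expect_equal(const$ci_high, 0.3)

  expect_error(summarize_chain(ch, 1.2), "level")
  expect_error(summarize_chain(numeric(0)), "empty")
})

test_that("diagnostics: iid draws are efficient, constant chains are not", {
  iid <- withr::with_seed(8, rbeta(5000, 223, 157))
  d <- diagnose_chain(iid)
  expect_gt(d$efficiency, 0.8)
  expect_equal(d$autocorrelations[1], 1)

  const <- diagnose_chain(rep(0.4, 500), max_lag = 10)
  expect_true(all(const$autocorrelations == 1))

  mh <- diagnose_chain(mh_sample(binom_obs(45, 88), beta_prior(178, 114),
                                 sampler_settings(seed = 2)))
  expect_gt(mh$efficiency, 0)
  expect_lte(mh$efficiency, 1)
  expect_error(diagnose_chain(rep(0.5, 10), max_lag = 20), "max_lag")
})

test_that("fit_posteriors derives independent but reproducible sub-seeds", {
  s <- sampler_settings(iterations = 2000, burn_in = 500, seed = 77)
  a <- fit_posteriors(settings = s)
  b <- fit_posteriors(settings = s)
  expect_identical(lapply(a, `[[`, "draws"), lapply(b, `[[`, "draws"))
  seeds <- vapply(a, function(ch) ch$settings$seed, integer(1))
  expect_equal(length(unique(seeds)), 4L)
})
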