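#' Sampler settings
#'
#' Settings for the Metropolis-Hastings sampler. Defaults match the study
#' conditions: 12,500 iterations with a 2,500-iteration burn-in, leaving
#' 10,000 retained draws per chain.
#'
#' @param iterations Total MCMC iterations.
#' @param burn_in Iterations discarded before summarization; `burn_in < iterations`.
#' @param seed Integer RNG seed; fixed seed reproduces the chain exactly.
#' @param proposal_scale Initial standard deviation of the Gaussian random-walk
#'   proposal on the logit scale.
#' @param adapt If `TRUE`, the proposal scale is tuned during burn-in towards
#'   ~44% acceptance (the scalar random-walk optimum) and then frozen.
#' @return An object of class `sampler_settings`.
#' @export
sampler_settings <- function(iterations = 12500L, burn_in = 2500L, seed = 1L,
                             proposal_scale = 0.5, adapt = TRUE) {
  iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  if (is.na(iterations) || iterations < 1) {
    stop("iterations must be a positive integer", call. = FALSE)
  }
  if (is.na(burn_in) || burn_in < 0 || burn_in >= iterations) {
    stop("burn_in must satisfy 0 <= burn_in < iterations", call. = FALSE)
  }
  if (!is.finite(proposal_scale) || proposal_scale <= 0) {
    stop("proposal_scale must be positive", call. = FALSE)
  }
  structure(list(iterations = iterations, burn_in = burn_in,
                 seed = as.integer(seed), proposal_scale = proposal_scale,
                 adapt = isTRUE(adapt)),
            class = "sampler_settings")
}

#' Metropolis-Hastings sampler for the beta-binomial posterior
#'
#' Samples the posterior of a binomial proportion under a beta prior with a
#' Gaussian random walk on logit(p). On the logit scale the target density is
#' proportional to `p^a (1-p)^b` with `a = alpha + events`,
#' `b = beta + total - events` (the beta-distribution kernel times the
#' logit Jacobian), so every draw stays strictly inside (0, 1). The proposal
#' scale is adapted during burn-in (batches of 50, diminishing gain) towards
#' 44% acceptance, then frozen so the retained chain is a valid Markov chain.
#'
#' The exact posterior is available in closed form via
#' [conjugate_posterior()]; the sampler exists so that uncertainty can be
#' propagated draw-by-draw through the economic model, and the closed form
#' acts as its oracle in the tests.
#'
#' @param obs A [binom_obs()].
#' @param prior A [beta_prior()].
#' @param settings A [sampler_settings()].
#' @return An object of class `posterior_chain`: `draws` (the retained
#'   draws, length `iterations - burn_in`), `acceptance_rate` (post burn-in),
#'   `settings`, and the conjugate posterior shape in `posterior`.
#' @examples
#' ch <- mh_sample(binom_obs(45, 88), beta_prior(178, 114),
#'                 sampler_settings(seed = 42))
#' mean(ch$draws)  # ~ 223/380
#' @export
mh_sample <- function(obs, prior, settings = sampler_settings()) {
  stopifnot(inherits(obs, "binom_obs"), inherits(prior, "beta_prior"),
            inherits(settings, "sampler_settings"))
  post <- conjugate_posterior(obs, prior)
  a <- post$alpha
  b <- post$beta

  n_iter <- settings$iterations
  burn <- settings$burn_in
  scale <- settings$proposal_scale

  # log target on the logit scale: a*log(p) + b*log(1-p)
  lp <- function(theta) {
    a * stats::plogis(theta, log.p = TRUE) +
      b * stats::plogis(-theta, log.p = TRUE)
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(settings$seed)
  z <- stats::rnorm(n_iter)
  logu <- log(stats::runif(n_iter))

  theta <- stats::qlogis(a / (a + b))  # start at the posterior mean
  lcur <- lp(theta)
  draws <- numeric(n_iter - burn)
  accepted <- 0L
  batch_acc <- 0L
  batch_n <- 0L
  n_batch <- 0L

  for (i in seq_len(n_iter)) {
    prop <- theta + scale * z[i]
    lprop <- lp(prop)
    acc <- logu[i] < (lprop - lcur)
    if (acc) {
      theta <- prop
      lcur <- lprop
    }
    if (i <= burn) {
      if (settings$adapt) {
        batch_acc <- batch_acc + acc
        batch_n <- batch_n + 1L
        if (batch_n == 50L) {
          n_batch <- n_batch + 1L
          gain <- 1 / sqrt(n_batch)
          scale <- scale * exp(gain * (batch_acc / 50 - 0.44))
          batch_acc <- 0L
          batch_n <- 0L
        }
      }
    } else {
      draws[i - burn] <- theta
      accepted <- accepted + acc
    }
  }

  rate <- accepted / (n_iter - burn)
  if (rate <= 0 || rate >= 1) {
    stop(sprintf(
      "degenerate chain: post burn-in acceptance rate %.3f (proposal scale %.3g)",
      rate, scale), call. = FALSE)
  }

  structure(list(draws = stats::plogis(draws),
                 acceptance_rate = rate,
                 proposal_scale = scale,
                 settings = settings,
                 posterior = post),
            class = "posterior_chain")
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat(sprintf(
    "<posterior_chain> %d retained draws, mean %.4f, acceptance %.1f%% (seed %d)\n",
    length(x$draws), mean(x$draws), 100 * x$acceptance_rate, x$settings$seed))
  invisible(x)
}

#' Posterior summary of a chain
#'
#' Mean, median and equal-tailed percentile credible interval of the retained
#' draws.
#'
#' @param chain A [mh_sample()] result (or any object with numeric `draws`).
#' @param level Credible level in (0, 1); default 0.95.
#' @return An object of class `posterior_summary` with `mean`, `median`,
#'   `ci_low`, `ci_high`, `level`.
#' @export
summarize_chain <- function(chain, level = 0.95) {
  draws <- if (is.numeric(chain)) chain else chain$draws
  if (length(draws) == 0) stop("empty chain", call. = FALSE)
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("level must be a single number in (0, 1)", call. = FALSE)
  }
  q <- stats::quantile(draws, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  structure(list(mean = mean(draws), median = stats::median(draws),
                 ci_low = q[1], ci_high = q[2], level = level),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("<posterior_summary> mean %.3f, median %.3f, %g%% CI [%.3f, %.3f]\n",
              x$mean, x$median, 100 * x$level, x$ci_low, x$ci_high))
  invisible(x)
}

#' Chain diagnostics: autocorrelation, effective sample size, efficiency
#'
#' Sample autocorrelation up to `max_lag`, effective sample size via the
#' truncated autocorrelation-sum estimator (lags summed until the first
#' non-positive autocorrelation), and efficiency = ESS / retained draws.
#' A zero-variance chain is reported as perfectly autocorrelated.
#'
#' @param chain A [mh_sample()] result or numeric vector of draws.
#' @param max_lag Largest lag for the autocorrelation function.
#' @return An object of class `chain_diagnostics` with
#'   `effective_sample_size`, `efficiency`, and `autocorrelations`
#'   (lags 0..`max_lag`).
#' @export
diagnose_chain <- function(chain, max_lag = 40L) {
  draws <- if (is.numeric(chain)) chain else chain$draws
  n <- length(draws)
  max_lag <- as.integer(max_lag)
  if (n <= max_lag) stop("chain shorter than max_lag", call. = FALSE)
  if (stats::var(draws) == 0) {
    rho <- rep(1, max_lag + 1)
  } else {
    rho <- as.numeric(stats::acf(draws, lag.max = max_lag,
                                 plot = FALSE, demean = TRUE)$acf)
  }
  pos <- rho[-1]
  cut <- which(pos <= 0)
  if (length(cut)) pos <- pos[seq_len(cut[1] - 1)]
  ess <- n / (1 + 2 * sum(pos))
  ess <- min(max(ess, 1), n)
  structure(list(effective_sample_size = ess,
                 efficiency = ess / n,
                 autocorrelations = rho),
            class = "chain_diagnostics")
}

#' @export
print.chain_diagnostics <- function(x, ...) {
  cat(sprintf("<chain_diagnostics> ESS %.0f, efficiency %.2f, lag-1 acf %.3f\n",
              x$effective_sample_size, x$efficiency, x$autocorrelations[2]))
  invisible(x)
}

#' Deterministic per-node sub-seeds from one master seed
#'
#' The four probability chains must be mutually independent but jointly
#' reproducible from a single configured seed; sub-seeds are drawn once from
#' the master seed.
#'
#' @param seed Master integer seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of `n` seeds.
#' @export
derive_seeds <- function(seed, n = 4L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Fit the four decision-tree posteriors
#'
#' Runs one Metropolis-Hastings chain per decision-tree probability
#' (P1..P4) with deterministic sub-seeds derived from `seed`.
#'
#' @param observations Named list of four [binom_obs()] (`p1`..`p4`).
#' @param priors Named list of four [beta_prior()].
#' @param settings A [sampler_settings()]; its `seed` is the master seed.
#' @return Named list of four `posterior_chain` objects.
#' @examples
#' chains <- fit_posteriors(settings = sampler_settings(seed = 7))
#' sapply(chains, function(ch) mean(ch$draws))
#' @export
fit_posteriors <- function(observations = default_observations(),
                           priors = default_priors(),
                           settings = sampler_settings()) {
  stopifnot(length(observations) == length(priors))
  seeds <- derive_seeds(settings$seed, length(observations))
  chains <- vector("list", length(observations))
  names(chains) <- names(observations)
  for (i in seq_along(observations)) {
    s <- settings
    s$seed <- seeds[i]
    chains[[i]] <- mh_sample(observations[[i]], priors[[i]], s)
  }
  chains
}
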