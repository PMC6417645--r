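#' Binomial observation
#'
#' A count of events out of a total, the observed data for one node of the
#' decision tree (e.g. 45 high-risk genotypes among 88 patients).
#'
#' @param events Non-negative integer count of events.
#' @param total Non-negative integer count of trials; `events <= total`.
#' @return An object of class `binom_obs` with elements `events` and `total`.
#' @examples
#' binom_obs(45, 88)
#' @export
binom_obs <- function(events, total) {
  stopifnot(
    length(events) == 1, length(total) == 1,
    is.finite(events), is.finite(total)
  )
  if (events < 0 || total < 0 || events > total) {
    stop("invalid binomial observation: need 0 <= events <= total", call. = FALSE)
  }
  if (events != round(events) || total != round(total)) {
    stop("events and total must be whole numbers", call. = FALSE)
  }
  structure(list(events = as.integer(events), total = as.integer(total)),
            class = "binom_obs")
}

#' Beta prior
#'
#' A Beta(alpha, beta) prior expressed as pseudo-event counts taken from
#' published studies (alpha prior events, beta prior non-events).
#'
#' @param alpha Positive pseudo-event count.
#' @param beta Positive pseudo-non-event count.
#' @return An object of class `beta_prior` with elements `alpha` and `beta`.
#' @examples
#' beta_prior(178, 114)
#' @export
beta_prior <- function(alpha, beta) {
  stopifnot(length(alpha) == 1, length(beta) == 1,
            is.finite(alpha), is.finite(beta))
  if (alpha <= 0 || beta <= 0) {
    stop("beta prior requires alpha > 0 and beta > 0", call. = FALSE)
  }
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "beta_prior")
}

#' Conjugate beta-binomial posterior
#'
#' Closed-form posterior for a binomial likelihood under a beta prior:
#' Beta(alpha + events, beta + total - events). Serves as the exact oracle
#' against which the Metropolis-Hastings sampler is validated.
#'
#' @param obs A [binom_obs()].
#' @param prior A [beta_prior()].
#' @return A `beta_prior` object holding the posterior shape parameters.
#' @examples
#' post <- conjugate_posterior(binom_obs(45, 88), beta_prior(178, 114))
#' prior_mean(post)  # 223/380
#' @export
conjugate_posterior <- function(obs, prior) {
  stopifnot(inherits(obs, "binom_obs"), inherits(prior, "beta_prior"))
  beta_prior(prior$alpha + obs$events,
             prior$beta + (obs$total - obs$events))
}

#' Mean of a beta distribution given as a `beta_prior`
#'
#' @param prior A [beta_prior()] (prior or posterior shape parameters).
#' @return `alpha / (alpha + beta)`.
#' @export
prior_mean <- function(prior) {
  stopifnot(inherits(prior, "beta_prior"))
  prior$alpha / (prior$alpha + prior$beta)
}

#' @export
print.binom_obs <- function(x, ...) {
  cat(sprintf("<binom_obs> %d / %d events\n", x$events, x$total))
  invisible(x)
}

#' @export
print.beta_prior <- function(x, ...) {
  cat(sprintf("<beta_prior> Beta(%g, %g), mean %.4f\n",
              x$alpha, x$beta, prior_mean(x)))
  invisible(x)
}

#' Decision-tree inputs: observed data and priors
#'
#' The packaged defaults: observed events/totals from the prospective cohort
#' treated without fosaprepitant, and beta priors from the published studies
#' feeding each node. Order: P1 (high-risk genotype), P2 (grade >= 3 CINV),
#' P3 (cycle-2 receipt), P4 (cycle-3 receipt given cycle 2).
#'
#' @return A named list of four [binom_obs()] (`default_observations`) or
#'   four [beta_prior()] (`default_priors`), names `p1`..`p4`.
#' @export
default_observations <- function() {
  list(
    p1 = binom_obs(45, 88),
    p2 = binom_obs(4, 43),
    p3 = binom_obs(86, 88),
    p4 = binom_obs(64, 86)
  )
}

#' @rdname default_observations
#' @export
default_priors <- function() {
  list(
    p1 = beta_prior(178, 114),
    p2 = beta_prior(33, 191),
    p3 = beta_prior(160, 12),
    p4 = beta_prior(120, 40)
  )
}
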