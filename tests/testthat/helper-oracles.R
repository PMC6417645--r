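# Published point estimates (posterior means rounded to 3 decimals) used
# throughout as reference inputs.
printed_means <- function() probability_vector(0.587, 0.139, 0.947, 0.748)

# Table of published posterior summaries per probability.
printed_posteriors <- function() {
  data.frame(
    probability = c("p1", "p2", "p3", "p4"),
    mean = c(0.587, 0.139, 0.947, 0.748),
    ci_low = c(0.538, 0.100, 0.917, 0.692),
    ci_high = c(0.634, 0.181, 0.970, 0.800)
  )
}

# Independent brute-force oracle for the dose expectations: enumerate all
# 2^5 patient paths (risk status, CINV in each of two evaluation phases,
# cycle-2 receipt, cycle-3 continuation draw) with their joint probability
# and sum dose counts path by path.
enumerate_doses <- function(pv, branch = c("standard", "genotyping"),
                            convention = c("intent_to_treat", "dropout_adjusted")) {
  branch <- match.arg(branch)
  convention <- match.arg(convention)
  p1 <- pv[["p_high_risk"]]; p2 <- pv[["p_cinv"]]
  p3 <- pv[["p_cycle2"]]; p4 <- pv[["p_cycle3"]]
  total <- 0
  for (high in 0:1) for (c1 in 0:1) for (c2 in 0:1)
    for (r2 in 0:1) for (r3d in 0:1) {
      prob <- (if (high) p1 else 1 - p1) *
        (if (c1) p2 else 1 - p2) * (if (c2) p2 else 1 - p2) *
        (if (r2) p3 else 1 - p3) * (if (r3d) p4 else 1 - p4)
      r3 <- r2 && r3d
      itt <- convention == "intent_to_treat"
      dose <- if (branch == "standard") {
        if (itt) 3 else 1 + r2 + r3
      } else if (high) {
        if (itt) 3 else 1 + r2 + r3
      } else {
        esc2 <- c1 == 1          # escalated after phase-1 event
        esc3 <- c1 == 1 || c2 == 1  # escalated after any event in phases 1-2
        if (itt) esc2 + esc3 else (esc2 && r2) + (esc3 && r3)
      }
      total <- total + prob * dose
    }
  total
}

# Random strictly-interior probability vectors under a fixed seed.
random_pvs <- function(n, seed = 404) {
  withr::with_seed(seed, replicate(n, simplify = FALSE, {
    p <- runif(4, 0.02, 0.98)
    probability_vector(p[1], p[2], p[3], p[4])
  }))
}

# Random observation/prior pairs for oracle checks.
random_obs_prior <- function(n, seed = 905) {
  withr::with_seed(seed, replicate(n, simplify = FALSE, {
    total <- sample(5:200, 1)
    list(obs = binom_obs(sample(0:total, 1), total),
         prior = beta_prior(runif(1, 0.5, 200), runif(1, 0.5, 200)))
  }))
}
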