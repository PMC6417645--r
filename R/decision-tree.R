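#' Joint probability vector for the decision tree
#'
#' The four probabilities driving the decision tree: P1 the frequency of the
#' high-risk (AG/GG) genotype, P2 the per-evaluation-phase probability of
#' grade >= 3 CINV without fosaprepitant, P3 the probability of receiving
#' chemotherapy cycle 2 (day 22), and P4 the probability of receiving cycle 3
#' (day 43) conditional on cycle 2. Components are treated as independent.
#'
#' @param p_high_risk,p_cinv,p_cycle2,p_cycle3 Probabilities strictly in (0, 1).
#' @return A named numeric vector of class `probability_vector`.
#' @examples
#' posterior_mean_pv()          # conjugate posterior means of the defaults
#' probability_vector(0.587, 0.139, 0.947, 0.748)
#' @export
probability_vector <- function(p_high_risk, p_cinv, p_cycle2, p_cycle3) {
  pv <- c(p_high_risk = unname(p_high_risk), p_cinv = unname(p_cinv),
          p_cycle2 = unname(p_cycle2), p_cycle3 = unname(p_cycle3))
  if (!all(is.finite(pv)) || any(pv <= 0) || any(pv >= 1)) {
    stop("all probabilities must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(pv, class = "probability_vector")
}

#' @rdname probability_vector
#' @param observations,priors Inputs passed to [conjugate_posterior()]; the
#'   defaults are the packaged observed data and priors.
#' @export
posterior_mean_pv <- function(observations = default_observations(),
                              priors = default_priors()) {
  m <- mapply(function(o, p) prior_mean(conjugate_posterior(o, p)),
              observations, priors)
  probability_vector(m[[1]], m[[2]], m[[3]], m[[4]])
}

#' @export
print.probability_vector <- function(x, ...) {
  cat(sprintf(
    "<probability_vector> P1 %.3f  P2 %.3f  P3 %.3f  P4 %.3f\n",
    x[["p_high_risk"]], x[["p_cinv"]], x[["p_cycle2"]], x[["p_cycle3"]]))
  invisible(x)
}

#' Dose-accounting conventions
#'
#' `"intent_to_treat"` costs every patient for all three planned cycles
#' regardless of dropout (the per-patient figures and break-even thresholds
#' use this). `"dropout_adjusted"` weights cycle-2 and cycle-3 doses by the
#' continuation probabilities P3 and P3*P4 (the annual branch totals use
#' this).
#'
#' @return Character vector of the two valid convention tags.
#' @export
dose_conventions <- function() c("intent_to_treat", "dropout_adjusted")

check_convention <- function(convention) {
  match.arg(convention, dose_conventions())
}

as_pv <- function(pv) {
  if (!inherits(pv, "probability_vector")) {
    stopifnot(is.numeric(pv), length(pv) == 4)
    pv <- probability_vector(pv[[1]], pv[[2]], pv[[3]], pv[[4]])
  }
  pv
}

#' Expected fosaprepitant doses per patient, standard (treat-all) branch
#'
#' Every patient is planned for three doses (days 1, 22, 43). Under
#' intent-to-treat the expectation is exactly 3; under the dropout-adjusted
#' convention cycle receipt is weighted by continuation, giving
#' `1 + P3 + P3*P4`.
#'
#' @param pv A [probability_vector()].
#' @param convention One of [dose_conventions()].
#' @return Expected doses per patient (numeric scalar in \[0, 3\]).
#' @export
expected_doses_standard <- function(pv, convention = "intent_to_treat") {
  pv <- as_pv(pv)
  convention <- check_convention(convention)
  if (convention == "intent_to_treat") {
    3
  } else {
    p3 <- pv[["p_cycle2"]]
    p4 <- pv[["p_cycle3"]]
    1 + p3 + p3 * p4
  }
}

#' Expected fosaprepitant doses per patient, genotyping branch
#'
#' High-risk (AG/GG) patients receive fosaprepitant in every cycle, like the
#' standard branch. Low-risk (AA) patients start without it and escalate for
#' all subsequent cycles after a grade >= 3 CINV event: the cycle-2 dose
#' requires an event in evaluation phase 1 (probability P2) and the cycle-3
#' dose requires at least one event in phases 1-2 (probability
#' `1 - (1 - P2)^2`, since the per-phase event rate is constant).
#'
#' Intent-to-treat:
#' `P1*3 + (1-P1) * (P2 + 1 - (1-P2)^2)`.
#' Dropout-adjusted, with cycle receipt weighted by P3 and P3*P4:
#' `P1*(1 + P3 + P3*P4) + (1-P1) * (P2*P3 + (1 - (1-P2)^2)*P3*P4)`.
#'
#' @inheritParams expected_doses_standard
#' @return Expected doses per patient; never exceeds the standard branch.
#' @export
expected_doses_genotyping <- function(pv, convention = "intent_to_treat") {
  pv <- as_pv(pv)
  convention <- check_convention(convention)
  p1 <- pv[["p_high_risk"]]
  p2 <- pv[["p_cinv"]]
  esc2 <- p2                 # escalated by cycle 2
  esc3 <- 1 - (1 - p2)^2     # escalated by cycle 3
  if (convention == "intent_to_treat") {
    p1 * 3 + (1 - p1) * (esc2 + esc3)
  } else {
    p3 <- pv[["p_cycle2"]]
    p4 <- pv[["p_cycle3"]]
    p1 * (1 + p3 + p3 * p4) +
      (1 - p1) * (esc2 * p3 + esc3 * p3 * p4)
  }
}
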