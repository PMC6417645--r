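#' Unit costs and laboratory time parameters
#'
#' Every monetary and time parameter of the cost model, in US dollars.
#' Defaults are the published unit prices: fosaprepitant $81.08 per 150 mg
#' dose; DNA-extraction reagents $1.46 per sample; real-time PCR reagents
#' and materials expressed per reaction ($8.56 and $1.07 for a single-sample
#' run of 5 reactions, i.e. $1.712 and $0.214 per reaction, each run adding
#' 4 controls); manpower at a monthly rate of $1,585.65 over 160 working
#' hours ($9.91/h) across three stages (DNA extraction 3 h 56 min, PCR
#' 2 h 20 min, data reporting 20 min); and a real-time PCR machine at
#' $36,364.86 amortized at 20% per year. The quoted reagent prices already
#' include the 10% loss allowance.
#'
#' @param fosaprepitant_per_dose USD per fosaprepitant dose.
#' @param dna_reagent_per_sample USD per sample, DNA extraction reagents.
#' @param pcr_reagent_per_reaction,pcr_material_per_reaction USD per PCR
#'   reaction (samples + controls).
#' @param controls_per_run Control reactions added to every PCR run.
#' @param manpower_rate_per_hour USD per technician hour.
#' @param stage_hours_extraction,stage_hours_pcr,stage_hours_reporting Hours
#'   per run for each laboratory stage.
#' @param machine_cost USD, real-time PCR equipment.
#' @param amortization_rate Fraction of `machine_cost` charged per year.
#' @param initial_investment USD, total published investment plan (reported
#'   as-is; amortization is computed from `machine_cost` only).
#' @return An object of class `unit_costs`.
#' @export
unit_costs <- function(fosaprepitant_per_dose = 81.08,
                       dna_reagent_per_sample = 1.46,
                       pcr_reagent_per_reaction = 8.56 / 5,
                       pcr_material_per_reaction = 1.07 / 5,
                       controls_per_run = 4L,
                       manpower_rate_per_hour = 1585.65 / 160,
                       stage_hours_extraction = 3 + 56 / 60,
                       stage_hours_pcr = 2 + 20 / 60,
                       stage_hours_reporting = 20 / 60,
                       machine_cost = 36364.86,
                       amortization_rate = 0.20,
                       initial_investment = 39379.97) {
  x <- list(fosaprepitant_per_dose = fosaprepitant_per_dose,
            dna_reagent_per_sample = dna_reagent_per_sample,
            pcr_reagent_per_reaction = pcr_reagent_per_reaction,
            pcr_material_per_reaction = pcr_material_per_reaction,
            controls_per_run = as.integer(controls_per_run),
            manpower_rate_per_hour = manpower_rate_per_hour,
            stage_hours_extraction = stage_hours_extraction,
            stage_hours_pcr = stage_hours_pcr,
            stage_hours_reporting = stage_hours_reporting,
            machine_cost = machine_cost,
            amortization_rate = amortization_rate,
            initial_investment = initial_investment)
  money <- unlist(x[setdiff(names(x), c("controls_per_run", "amortization_rate"))])
  if (any(!is.finite(money)) || any(money < 0)) {
    stop("all cost and time parameters must be non-negative", call. = FALSE)
  }
  if (x$amortization_rate <= 0 || x$amortization_rate > 1) {
    stop("amortization_rate must lie in (0, 1]", call. = FALSE)
  }
  if (x$controls_per_run < 0) stop("controls_per_run must be >= 0", call. = FALSE)
  structure(x, class = "unit_costs")
}

#' @export
print.unit_costs <- function(x, ...) {
  cat(sprintf(
    "<unit_costs> drug $%.2f/dose, manpower $%.2f/h, machine $%.2f @ %.0f%%/yr\n",
    x$fosaprepitant_per_dose, x$manpower_rate_per_hour,
    x$machine_cost, 100 * x$amortization_rate))
  invisible(x)
}

#' Genotyping cost per test as a function of batch size
#'
#' One PCR run processes `n_samples` patient samples plus
#' `controls_per_run` control reactions; manpower for the three laboratory
#' stages is divided over the samples in the run, reagents for DNA
#' extraction are per sample, and PCR reagents/materials scale as
#' `(n_samples + controls) / n_samples`. Components are kept at full
#' precision; only the total is rounded to cents.
#'
#' @param n_samples Samples per run (>= 1). The published scenarios cover
#'   1..6 (six samples a week serve ~300 patients/year); larger batches are
#'   allowed with a warning.
#' @param costs A [unit_costs()].
#' @return An object of class `batch_cost` (also a one-row data.frame) with
#'   per-sample components `manpower`, `dna_reagent`, `pcr_reagent`,
#'   `pcr_material`, the unrounded component sum `total_unrounded`, and
#'   `total` rounded to cents.
#' @examples
#' per_test_cost(6)$total  # 15.57
#' @export
per_test_cost <- function(n_samples, costs = unit_costs()) {
  stopifnot(inherits(costs, "unit_costs"))
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1) {
    stop("n_samples must be a positive integer", call. = FALSE)
  }
  if (n_samples > 6) {
    warning("batch sizes above 6 extrapolate beyond the modelled scenarios")
  }
  hours <- costs$stage_hours_extraction + costs$stage_hours_pcr +
    costs$stage_hours_reporting
  manpower <- hours * costs$manpower_rate_per_hour / n_samples
  reactions_per_sample <- (n_samples + costs$controls_per_run) / n_samples
  out <- data.frame(
    n_samples = n_samples,
    manpower = manpower,
    dna_reagent = costs$dna_reagent_per_sample,
    pcr_reagent = costs$pcr_reagent_per_reaction * reactions_per_sample,
    pcr_material = costs$pcr_material_per_reaction * reactions_per_sample
  )
  out$total_unrounded <- out$manpower + out$dna_reagent +
    out$pcr_reagent + out$pcr_material
  out$total <- round(out$total_unrounded, 2)
  class(out) <- c("batch_cost", "data.frame")
  out
}

#' Batch-cost table across sample quantities
#'
#' @param n_samples Integer vector of batch sizes.
#' @param costs A [unit_costs()].
#' @return A data.frame with one row per batch size (see [per_test_cost()]).
#' @export
batch_cost_table <- function(n_samples = 1:6, costs = unit_costs()) {
  out <- do.call(rbind, lapply(n_samples, per_test_cost, costs = costs))
  rownames(out) <- NULL
  out
}

#' Annual equipment amortization
#'
#' @param costs A [unit_costs()].
#' @return `machine_cost * amortization_rate`, USD per year.
#' @examples
#' round(annual_amortization(), 2)  # 7272.97
#' @export
annual_amortization <- function(costs = unit_costs()) {
  stopifnot(inherits(costs, "unit_costs"))
  costs$machine_cost * costs$amortization_rate
}

per_patient_drug_costs <- function(pv, costs, convention) {
  d_std <- expected_doses_standard(pv, convention)
  d_gen <- expected_doses_genotyping(pv, convention)
  list(standard = d_std * costs$fosaprepitant_per_dose,
       genotyping = d_gen * costs$fosaprepitant_per_dose,
       doses_standard = d_std, doses_genotyping = d_gen)
}

#' Annual branch totals and savings for a patient-volume scenario
#'
#' Standard branch: patients times expected doses times drug price.
#' Genotyping branch: drug cost at the genotyping branch's expected doses,
#' plus one genotyping test per patient (at the batch-size-dependent
#' per-test cost), plus annual equipment amortization.
#'
#' @param pv A [probability_vector()].
#' @param n_patients Patients treated per year (>= 0).
#' @param batch_size Samples per PCR run.
#' @param costs A [unit_costs()].
#' @param convention One of [dose_conventions()]; the published annual totals
#'   use `"dropout_adjusted"`.
#' @return An object of class `scenario_cost` (one-row data.frame) with
#'   branch totals, savings, and per-patient figures.
#' @examples
#' scenario_costs(posterior_mean_pv(), 300, 2, convention = "dropout_adjusted")
#' @export
scenario_costs <- function(pv, n_patients, batch_size, costs = unit_costs(),
                           convention = "dropout_adjusted") {
  pv <- as_pv(pv)
  convention <- check_convention(convention)
  stopifnot(n_patients >= 0)
  drug <- per_patient_drug_costs(pv, costs, convention)
  test <- per_test_cost(batch_size, costs)$total_unrounded
  amort <- annual_amortization(costs)
  standard_total <- n_patients * drug$standard
  genotyping_total <- n_patients * (drug$genotyping + test) + amort
  out <- data.frame(
    n_patients = n_patients, batch_size = as.integer(batch_size),
    convention = convention,
    standard_total = standard_total,
    genotyping_total = genotyping_total,
    savings = standard_total - genotyping_total,
    standard_per_patient = drug$standard,
    genotyping_per_patient = if (n_patients > 0)
      drug$genotyping + test + amort / n_patients else NA_real_
  )
  class(out) <- c("scenario_cost", "data.frame")
  out
}

#' Percentage reduction in fosaprepitant expenditure
#'
#' Drug-only comparison per patient under intent-to-treat:
#' `100 * (1 - genotyping drug cost / standard drug cost)`.
#'
#' @param pv A [probability_vector()].
#' @param costs A [unit_costs()].
#' @return Percent reduction (numeric scalar).
#' @export
drug_cost_reduction <- function(pv, costs = unit_costs()) {
  drug <- per_patient_drug_costs(as_pv(pv), costs, "intent_to_treat")
  100 * (1 - drug$genotyping / drug$standard)
}

#' Break-even annual patient volume
#'
#' Smallest integer number of patients per year for which the genotyping
#' branch is no more expensive than the standard branch, i.e. the smallest N
#' with `N * margin >= annual amortization`, where the per-patient margin is
#' the standard drug cost minus the genotyping drug cost minus the per-test
#' cost, all under intent-to-treat (per-patient accounting).
#'
#' @param pv A [probability_vector()].
#' @param batch_size Samples per PCR run.
#' @param costs A [unit_costs()].
#' @return Integer threshold (patients per year), or `Inf` with
#'   `never_break_even = TRUE` attribute suppressed — a non-positive margin
#'   signals an error unless `inf_on_no_margin = TRUE`.
#' @param inf_on_no_margin If `TRUE`, return `Inf` instead of signalling an
#'   error when the margin is non-positive (used when propagating posterior
#'   draws, where such draws count in the upper tail).
#' @examples
#' breakeven_threshold(probability_vector(0.587, 0.139, 0.947, 0.748), 2) # 155
#' @export
breakeven_threshold <- function(pv, batch_size, costs = unit_costs(),
                                inf_on_no_margin = FALSE) {
  drug <- per_patient_drug_costs(as_pv(pv), costs, "intent_to_treat")
  test <- per_test_cost(batch_size, costs)$total_unrounded
  margin <- drug$standard - drug$genotyping - test
  if (margin <= 0) {
    if (inf_on_no_margin) return(Inf)
    stop("genotyping never breaks even: per-patient margin <= 0", call. = FALSE)
  }
  amort <- annual_amortization(costs)
  as.numeric(max(1, ceiling(amort / margin)))
}

#' Per-patient overall cost difference, percent
#'
#' Difference between the standard and genotyping branches in overall cost
#' per patient (drug + genotyping test + amortization share), intent-to-treat:
#' `100 * (1 - (genotyping drug + per-test + amortization/N) / standard drug)`.
#'
#' @param pv A [probability_vector()].
#' @param n_patients Patients per year (> 0), over whom amortization spreads.
#' @param batch_size Samples per PCR run.
#' @param costs A [unit_costs()].
#' @return Percent difference (positive favours genotyping).
#' @export
per_patient_difference_percent <- function(pv, n_patients, batch_size,
                                           costs = unit_costs()) {
  stopifnot(n_patients > 0)
  drug <- per_patient_drug_costs(as_pv(pv), costs, "intent_to_treat")
  test <- per_test_cost(batch_size, costs)$total_unrounded
  amort <- annual_amortization(costs)
  100 * (1 - (drug$genotyping + test + amort / n_patients) / drug$standard)
}

#' Propagate posterior uncertainty into the economic outputs
#'
#' Pairs the four posterior chains draw-by-draw into probability vectors and
#' evaluates, for every draw: the per-patient genotyping drug cost, the
#' percent reduction in drug expenditure, the break-even threshold, and the
#' per-patient overall cost difference (all intent-to-treat). Each quantity
#' is summarized by its value at the posterior-mean probabilities (point
#' estimate), the mean over draws, and the equal-tailed credible interval.
#' Draws with a non-positive break-even margin yield an infinite threshold
#' and are counted in the upper tail.
#'
#' @param chains Named list of four `posterior_chain` objects (`p1`..`p4`)
#'   of equal retained length, as from [fit_posteriors()].
#' @param n_patients Patients per year for the per-patient difference.
#' @param batch_size Samples per PCR run.
#' @param costs A [unit_costs()].
#' @param level Credible level.
#' @return A data.frame of class `economic_summary` with one row per
#'   quantity: `quantity`, `point_estimate`, `draw_mean`, `ci_low`,
#'   `ci_high`, `level`.
#' @export
propagate_uncertainty <- function(chains, n_patients = 300, batch_size = 2,
                                  costs = unit_costs(), level = 0.95) {
  stopifnot(length(chains) == 4)
  len <- lengths(lapply(chains, `[[`, "draws"))
  if (length(unique(len)) != 1) {
    stop("all chains must have the same retained length", call. = FALSE)
  }
  p1 <- chains[[1]]$draws; p2 <- chains[[2]]$draws
  p3 <- chains[[3]]$draws; p4 <- chains[[4]]$draws

  price <- costs$fosaprepitant_per_dose
  test <- per_test_cost(batch_size, costs)$total_unrounded
  amort <- annual_amortization(costs)

  esc <- p2 + 1 - (1 - p2)^2
  doses_gen <- p1 * 3 + (1 - p1) * esc
  drug_gen <- doses_gen * price
  drug_std <- 3 * price
  reduction <- 100 * (1 - drug_gen / drug_std)
  margin <- drug_std - drug_gen - test
  threshold <- ifelse(margin > 0, pmax(1, ceiling(amort / margin)), Inf)
  pp_diff <- 100 * (1 - (drug_gen + test + amort / n_patients) / drug_std)

  pv_mean <- probability_vector(mean(p1), mean(p2), mean(p3), mean(p4))
  points <- c(
    drug_cost_per_patient =
      per_patient_drug_costs(pv_mean, costs, "intent_to_treat")$genotyping,
    reduction_percent = drug_cost_reduction(pv_mean, costs),
    breakeven_threshold =
      breakeven_threshold(pv_mean, batch_size, costs, inf_on_no_margin = TRUE),
    per_patient_difference_percent =
      per_patient_difference_percent(pv_mean, n_patients, batch_size, costs)
  )

  draws <- list(drug_cost_per_patient = drug_gen,
                reduction_percent = reduction,
                breakeven_threshold = threshold,
                per_patient_difference_percent = pp_diff)
  lo <- (1 - level) / 2
  out <- data.frame(
    quantity = names(draws),
    point_estimate = unname(points),
    draw_mean = vapply(draws, mean, numeric(1)),
    ci_low = vapply(draws, function(d)
      stats::quantile(d, lo, names = FALSE, type = 1), numeric(1)),
    ci_high = vapply(draws, function(d)
      stats::quantile(d, 1 - lo, names = FALSE, type = 1), numeric(1)),
    level = level,
    row.names = NULL
  )
  class(out) <- c("economic_summary", "data.frame")
  out
}
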