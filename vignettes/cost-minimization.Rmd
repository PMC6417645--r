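---
title: "Genotype-guided antiemetic prophylaxis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-guided antiemetic prophylaxis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinvcost)
```

## The decision problem

Patients with head and neck cancer under chemoradiation receive high-dose
cisplatin on days 1, 22, and 43. The regimen is highly emetogenic, so
guidelines add an NK1-receptor antagonist (fosaprepitant, $81.08 per dose)
to every cycle. Carriers of the *GSTP1* c.313A>G AG/GG genotype are at high
risk of grade ≥ 3 chemotherapy-induced nausea and vomiting (CINV); AA
carriers are at low risk. The genotype-guided strategy gives fosaprepitant
up front only to high-risk patients; low-risk patients start without it and
escalate — for all remaining cycles — after a grade ≥ 3 event. Both
strategies are assumed equally effective (high-risk patients are protected
either way, low-risk patients rarely need protection), so the comparison
is a pure cost-minimization: which strategy is cheaper, and above what
annual patient volume does the fixed cost of a real-time PCR platform pay
for itself?

Four probabilities drive the tree:

* **P1** — frequency of the high-risk (AG/GG) genotype,
* **P2** — per-evaluation-phase probability of grade ≥ 3 CINV without
  fosaprepitant,
* **P3** — probability of receiving cycle 2 (day 22),
* **P4** — probability of receiving cycle 3 (day 43) given cycle 2.

They are treated as mutually independent; toxicity is assumed not to alter
continuation, which is what the published arithmetic implies.

## Posterior inference

Each probability has a binomial observation (events/total from a
prospective cohort treated without fosaprepitant) and a Beta prior whose
pseudo-counts encode the published external studies. The posterior is
conjugate — `Beta(alpha + events, beta + total − events)` — and
`conjugate_posterior()` returns it in closed form. Nevertheless the
package samples the posterior by Metropolis–Hastings
(`mh_sample()`, 12,500 iterations, 2,500 burn-in, 10,000 retained draws by
default), because the economic quantities are nonlinear in the
probabilities and their credible intervals are obtained by pushing draws
through the cost model. The closed form then serves as an exact oracle: the
test suite requires every chain mean to sit within Monte-Carlo error of the
conjugate mean.

Sampler design choices, where the method description left them open:

* **Proposal.** Gaussian random walk on logit(p). On that scale the target
  kernel is `p^a (1−p)^b` (beta kernel times the Jacobian), every draw stays
  strictly inside (0, 1), and no boundary rejection logic is needed.
* **Adaptation.** The proposal scale is tuned during burn-in in batches of
  50 with diminishing gain toward 44% acceptance — the classical optimum
  for a scalar random walk — and frozen afterwards, so the retained chain
  is a proper Markov chain. A post-burn-in acceptance rate of exactly 0
  or 1 raises an error rather than returning a degenerate chain.
* **Initialization.** Chains start at the conjugate posterior mean; with a
  2,500-iteration burn-in the starting point is immaterial.
* **Intervals.** Equal-tailed percentile intervals of the retained draws
  (not HPD), matching the symmetric intervals the analysis reports. The
  median is the sample median of the retained draws.
* **Seeding.** One master seed; the four chains receive sub-seeds drawn
  once from it (`derive_seeds()`), so they are mutually independent but
  jointly reproducible bit-for-bit.
* **Diagnostics.** `diagnose_chain()` reports the autocorrelation function,
  an effective sample size from the truncated positive-autocorrelation sum,
  and efficiency = ESS/draws. Typical efficiency for these targets is
  0.2–0.25.

## Dose expectations

`expected_doses_standard()` and `expected_doses_genotyping()` convert a
probability vector into expected fosaprepitant doses per patient. Two
accounting conventions are first-class because the published figures mix
them:

* **Intent-to-treat** — every patient is costed for all three planned
  cycles. Standard branch: exactly 3 doses ($243.24/patient). Genotyping
  branch: `P1·3 + (1−P1)·(P2 + 1 − (1−P2)²)`. The per-patient figures and
  break-even thresholds use this convention.
* **Dropout-adjusted** — cycle-2 and cycle-3 doses are weighted by P3 and
  P3·P4. The annual 300-patient branch totals use this convention.

The low-risk escalation term deserves a note: the cycle-2 dose requires a
grade ≥ 3 event in the first evaluation phase (probability P2), and the
cycle-3 dose requires at least one event across the first two phases
(`1 − (1−P2)²`, the per-phase rate being constant), because escalation is
permanent. This cumulative-complement rule reproduces the published
per-patient genotyping drug cost to within $0.10; the additive alternative
(`2·P2`) does not. Once escalated, both conventions treat low- and
high-risk patients identically with respect to continuation (same P3, P4).
An exhaustive enumeration of all 2⁵ patient paths is kept in the test suite
as an independent oracle for both branches and both conventions.

## The cost engine

`unit_costs()` carries every monetary and time parameter. Non-obvious
reconstructions, each validated against the published per-test table:

* **Per-reaction prices.** Only single-test PCR reagent ($8.56) and
  material ($1.07) costs are published. A single-test run is 5 reactions
  (1 sample + 4 controls), so the per-reaction prices are $1.712 and
  $0.214; an *n*-sample run then costs `unit × (n+4)/n` per sample. This
  reproduces the published batch columns for n = 2…6 to within $0.01.
* **Stage times.** Manpower stage durations are taken as 3 h 56 min,
  2 h 20 min, and 20 min (printed rounded as 3.93/2.33/0.33 h): only the
  unrounded values reproduce the published single-sample manpower cells at
  the hourly rate $1,585.65/160 ≈ $9.91.
* **Rounding.** All arithmetic is unrounded; only displayed totals are
  rounded to cents. Individual published cells show inconsistent rounding
  (one total differs by exactly $0.01 from the unrounded component sum),
  so cell comparisons carry a ±$0.01 tolerance.
* **Loss allowance.** The quoted reagent prices are treated as already
  including the 10% loss uplift.
* **Amortization.** Annual amortization is `machine_cost × 20%` = $7,272.97
  from the PCR platform price alone. The published initial-investment
  figure ($39,379.97) exceeds the platform price with no printed breakdown;
  it is carried as an opaque reporting constant and takes no part in any
  computation.

`scenario_costs()` prices a (patients, batch size, convention) cell;
`breakeven_threshold()` returns the smallest N with
`N × margin ≥ amortization`, where the margin is the intent-to-treat
standard drug cost minus genotyping drug cost minus per-test cost. A
non-positive margin signals "never breaks even" (or yields an infinite
threshold when propagating draws).

## Uncertainty propagation

`propagate_uncertainty()` pairs the four chains draw-by-draw and evaluates
the per-patient genotyping drug cost, the percent reduction, the break-even
threshold, and the per-patient overall difference for every draw, then
summarizes each with the value at the posterior-mean probabilities (the
point estimate) plus an equal-tailed interval over draws. Draws whose
margin is non-positive contribute infinite thresholds in the upper tail.
Per-draw propagation is the package's design choice; plugging the marginal
credible-interval endpoints of P1 and P2 into the cost formulas (an
alternative that treats the band edges as scenarios) gives slightly wider
intervals. Both answer slightly different questions; per-draw is the
statistically coherent one for a joint posterior.

Two small reconciliations worth knowing when comparing against published
figures: the standard per-patient cost is 3 × $81.08 = $243.24 (one quoted
passage says $243.40, an unexplained $0.16 drift), and the break-even
threshold is razor-close to a ceiling boundary — at the conjugate posterior
means it is 154, at the means rounded to three decimals it is exactly 155.
Chain realizations land on either side; this is Monte-Carlo noise at a
discontinuity, not a model difference.

## Synthetic cohorts

`generate_cohort()` draws per-patient Bernoulli outcomes — genotype ~ P1,
one grade ≥ 3 CINV indicator per evaluation phase ~ P2, cycle-2 receipt ~
P3, cycle-3 receipt ~ P4 conditional on cycle 2 — and
`aggregate_cohort()` collapses them into the four binomial observations
with the same denominator conventions as the observed data (the CINV
denominator can be restricted to an evaluable subset, mirroring the
observed data's partial evaluability; the mechanism behind that subset is
not modelled). Phase-1 events alone enter the aggregated CINV numerator so
the proportion is unbiased for the per-phase rate; the phase-2 draw feeds
dose accounting only. The generator captures exactly the independence
structure the analysis assumes — it does not emulate per-cycle toxicity
heterogeneity, genotype-dependent dropout, or covariates, so passing
recovery tests validate the inferential machinery under the model's own
assumptions, not those assumptions themselves.

`parameter_recovery()` closes the loop: generate, aggregate, infer,
summarize, and report posterior-mean bias and empirical interval coverage.
With flat priors and cohorts of 500, 95% intervals cover the truth within
±4 percentage points of nominal over 200 replicates (the calibration test
runs 5,000-iteration chains — 4,000 retained draws — per replicate, which
estimates a 95% percentile interval to well under the width of the
coverage band).

## Reporting

`run_full_analysis()` executes the whole pipeline from one
`default_config()` (whose values are the packaged study conditions) and
writes the posterior table, batch-cost table, scenario grid, thresholds,
economic summaries (JSON), and a run manifest with the seed and a config
hash. Identical config and seed give byte-identical tables. `figure_data()`
emits the series behind the three headline figures: savings versus batch
size, cumulative branch costs versus patient volume, and per-patient cost
with its credible band.

```{r example, eval = FALSE}
cfg <- default_config(seed = 1)
res <- run_full_analysis(cfg, out_dir = "report")
res$posterior_table
res$thresholds
```

## Limitations

* The model prices exactly one SNP test on one platform; drug prices,
  toxicity rates, and genotype frequency all shift the break-even point,
  and none is discounted over time (single-year horizon).
* Cost-minimization presumes equal effectiveness of the two strategies;
  establishing that claim needs an interventional study, not this model.
* Independence of P1–P4 is assumed throughout; correlated dropout and
  toxicity would require a richer cohort model than the generator provides.
* The MH sampler reproduces the published inference only up to its
  conjugate target: the original proposal, adaptation, and thinning
  settings are unknown, so chain-level artifacts (e.g. the last rounded
  digit of a posterior mean) are not expected to match realization for
  realization.
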