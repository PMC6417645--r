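Package: cinvcost
Title: Bayesian Cost-Minimization of Genotype-Guided Antiemetic Prophylaxis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-minimization of GSTP1 c.313A>G
    genotype-guided fosaprepitant prophylaxis against universal prophylaxis
    for chemotherapy-induced nausea and vomiting (CINV) under high-dose
    cisplatin. Estimates the four probabilities of the decision tree
    (high-risk genotype frequency, grade >= 3 CINV rate, cycle-2 and
    cycle-3 continuation) by beta-binomial Metropolis-Hastings MCMC
    validated against the conjugate closed form, converts posterior draws
    into expected fosaprepitant doses per branch, prices genotyping as a
    function of PCR batch size with equipment amortization, solves
    break-even patient thresholds, and propagates posterior uncertainty
    into credible intervals for every economic output. Includes a
    synthetic-cohort generator so the whole pipeline is testable
    end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
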