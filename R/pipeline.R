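#' Default analysis configuration
#'
#' One plain list holding every input of the analysis: the four binomial
#' observations and beta priors, the unit costs, the sampler settings, the
#' scenario grid, and the credible level. The defaults reproduce the
#' published analysis exactly; any field can be overridden before
#' [run_full_analysis()]. Configurations round-trip through YAML via
#' [write_config()] / [read_config()].
#'
#' @param seed Master seed used for the four posterior chains.
#' @return A list of class `analysis_config`.
#' @export
default_config <- function(seed = 20190314) {
  structure(list(
    observations = default_observations(),
    priors = default_priors(),
    costs = unit_costs(),
    sampler = sampler_settings(seed = seed),
    level = 0.95,
    scenario = list(n_patients = 300L, batch_sizes = 1:6,
                    conventions = dose_conventions())
  ), class = "analysis_config")
}

#' Validate an analysis configuration
#'
#' Checks structure and every type invariant, naming the offending field.
#'
#' @param config An `analysis_config` list.
#' @return The validated config, invisibly; errors otherwise.
#' @export
validate_config <- function(config) {
  need <- c("observations", "priors", "costs", "sampler", "level", "scenario")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    stop("config is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ids <- c("p1", "p2", "p3", "p4")
  for (fld in c("observations", "priors")) {
    if (!all(ids %in% names(config[[fld]]))) {
      stop(sprintf("config field '%s' must have entries p1..p4", fld),
           call. = FALSE)
    }
  }
  for (id in ids) {
    o <- config$observations[[id]]
    p <- config$priors[[id]]
    tryCatch({
      binom_obs(o$events, o$total)
      beta_prior(p$alpha, p$beta)
    }, error = function(e) stop(sprintf("config field '%s/%s': %s",
                                        "observations|priors", id,
                                        conditionMessage(e)), call. = FALSE))
  }
  s <- config$sampler
  tryCatch(
    sampler_settings(s$iterations, s$burn_in, s$seed, s$proposal_scale,
                     s$adapt),
    error = function(e) stop("config field 'sampler': ", conditionMessage(e),
                             call. = FALSE))
  tryCatch(do.call(unit_costs,
                   config$costs[setdiff(names(config$costs), NULL)]),
           error = function(e) stop("config field 'costs': ",
                                    conditionMessage(e), call. = FALSE))
  if (!is.numeric(config$level) || config$level <= 0 || config$level >= 1) {
    stop("config field 'level' must lie in (0, 1)", call. = FALSE)
  }
  sc <- config$scenario
  if (any(sc$n_patients < 0) || any(sc$batch_sizes < 1) ||
      !all(sc$conventions %in% dose_conventions())) {
    stop("config field 'scenario' is invalid", call. = FALSE)
  }
  invisible(config)
}

config_to_plain <- function(config) {
  rapply(unclass(config), function(x) if (is.list(x)) x else unclass(x),
         how = "replace")
}

#' Write / read a configuration as YAML
#'
#' @param config An `analysis_config`.
#' @param path File path.
#' @return `read_config` returns a validated `analysis_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config_to_plain(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  for (id in c("p1", "p2", "p3", "p4")) {
    o <- raw$observations[[id]]
    p <- raw$priors[[id]]
    cfg$observations[[id]] <- binom_obs(o$events, o$total)
    cfg$priors[[id]] <- beta_prior(p$alpha, p$beta)
  }
  s <- raw$sampler
  cfg$sampler <- sampler_settings(s$iterations, s$burn_in, s$seed,
                                  s$proposal_scale, s$adapt)
  cfg$costs <- do.call(unit_costs,
                       raw$costs[names(raw$costs) %in% names(formals(unit_costs))])
  cfg$level <- raw$level
  cfg$scenario <- raw$scenario
  validate_config(cfg)
  cfg
}

# 31-bit polynomial rolling hash over the serialized config, for the manifest
config_hash <- function(config) {
  txt <- yaml::as.yaml(config_to_plain(config))
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the complete analysis
#'
#' Fits the four posteriors, summarizes and diagnoses the chains, builds the
#' batch-cost table, evaluates the scenario grid, solves break-even
#' thresholds, propagates posterior uncertainty, and (optionally) writes the
#' report bundle: `posterior_table.csv`, `batch_costs.csv`, `scenarios.csv`,
#' `summaries.json`, and `manifest.json` (seed, config hash, package
#' version, diagnostics warnings). Identical config and seed give
#' byte-identical tables.
#'
#' @param config An `analysis_config`; see [default_config()].
#' @param out_dir Output directory; `NULL` skips writing files.
#' @param quiet Suppress per-stage log lines.
#' @return A list with elements `posterior_table`, `chains`, `batch_costs`,
#'   `scenarios`, `thresholds`, `summaries` (one `economic_summary` per
#'   batch size), `diagnostics`, and `manifest`, invisibly when writing.
#' @examples
#' \donttest{
#' res <- run_full_analysis(default_config(seed = 1), out_dir = NULL)
#' res$posterior_table
#' }
#' @export
run_full_analysis <- function(config = default_config(), out_dir = NULL,
                              quiet = FALSE) {
  validate_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]

  say("[infer] 4 MH chains, %d iterations, seed %d",
      config$sampler$iterations, config$sampler$seed)
  chains <- fit_posteriors(config$observations, config$priors, config$sampler)
  ids <- names(chains)
  posterior_table <- do.call(rbind, lapply(ids, function(id) {
    ch <- chains[[id]]
    sm <- summarize_chain(ch, config$level)
    dg <- diagnose_chain(ch)
    o <- config$observations[[id]]
    p <- config$priors[[id]]
    data.frame(probability = id, events = o$events, total = o$total,
               prior_alpha = p$alpha, prior_beta = p$beta,
               mean = sm$mean, median = sm$median,
               ci_low = sm$ci_low, ci_high = sm$ci_high,
               acceptance_rate = ch$acceptance_rate,
               ess = dg$effective_sample_size,
               efficiency = dg$efficiency)
  }))

  warnings <- character()
  low_eff <- posterior_table$probability[posterior_table$efficiency < 0.01]
  if (length(low_eff)) {
    warnings <- c(warnings, paste("low sampler efficiency for:",
                                  paste(low_eff, collapse = ", ")))
  }

  say("[costs] batch-cost table, batch sizes %s",
      paste(range(config$scenario$batch_sizes), collapse = "-"))
  batch_costs <- batch_cost_table(config$scenario$batch_sizes, config$costs)

  pv_mean <- probability_vector(posterior_table$mean[1], posterior_table$mean[2],
                                posterior_table$mean[3], posterior_table$mean[4])
  grid <- expand.grid(n_patients = config$scenario$n_patients,
                      batch_size = config$scenario$batch_sizes,
                      convention = config$scenario$conventions,
                      stringsAsFactors = FALSE)
  say("[compare] %d scenario cells", nrow(grid))
  scenarios <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    scenario_costs(pv_mean, grid$n_patients[i], grid$batch_size[i],
                   config$costs, grid$convention[i])
  }))

  say("[threshold + propagate] batch sizes %s",
      paste(config$scenario$batch_sizes, collapse = ","))
  thresholds <- data.frame(batch_size = integer(), n_star = numeric(),
                           ci_low = numeric(), ci_high = numeric())
  summaries <- list()
  for (b in config$scenario$batch_sizes) {
    es <- propagate_uncertainty(chains, max(config$scenario$n_patients), b,
                                config$costs, config$level)
    summaries[[as.character(b)]] <- es
    th <- es[es$quantity == "breakeven_threshold", ]
    thresholds <- rbind(thresholds,
                        data.frame(batch_size = b, n_star = th$point_estimate,
                                   ci_low = th$ci_low, ci_high = th$ci_high))
  }

  manifest <- list(
    package = "cinvcost",
    version = as.character(utils::packageVersion("cinvcost")),
    seed = config$sampler$seed,
    config_hash = config_hash(config),
    level = config$level,
    elapsed_seconds = round(proc.time()[["elapsed"]] - t0, 3),
    warnings = warnings
  )

  res <- list(posterior_table = posterior_table, chains = chains,
              batch_costs = batch_costs, scenarios = scenarios,
              thresholds = thresholds, summaries = summaries,
              diagnostics = posterior_table[, c("probability",
                                                "acceptance_rate",
                                                "ess", "efficiency")],
              manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                           row.names = FALSE)
    wr(posterior_table, "posterior_table.csv")
    wr(as.data.frame(batch_costs), "batch_costs.csv")
    wr(as.data.frame(scenarios), "scenarios.csv")
    wr(thresholds, "thresholds.csv")
    jsonlite::write_json(
      list(economic_summaries = lapply(summaries, function(es) {
        es$ci_high[!is.finite(es$ci_high)] <- NA
        es$draw_mean[!is.finite(es$draw_mean)] <- NA
        es
      })),
      file.path(out_dir, "summaries.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("[report] wrote %s (elapsed %.1fs)", out_dir,
        manifest$elapsed_seconds)
    return(invisible(res))
  }
  res
}

#' Series behind the cost figures
#'
#' Tabular data for the three headline figures: annual savings against batch
#' size; cumulative branch costs against patient volume; and per-patient
#' overall cost against patient volume with the credible band from the
#' posterior drug-cost interval (the test and amortization terms carry no
#' sampling uncertainty).
#'
#' @param config An `analysis_config`.
#' @param max_patients Upper end of the patient-volume axis.
#' @return A list of three data.frames: `batch_savings`, `cumulative`,
#'   `per_patient`.
#' @export
figure_data <- function(config = default_config(), max_patients = 300) {
  validate_config(config)
  chains <- fit_posteriors(config$observations, config$priors, config$sampler)
  pm <- vapply(chains, function(ch) mean(ch$draws), numeric(1))
  pv <- probability_vector(pm[1], pm[2], pm[3], pm[4])
  costs <- config$costs
  n_ref <- max(config$scenario$n_patients)

  batch_savings <- do.call(rbind, lapply(config$scenario$batch_sizes,
    function(b) {
      sc <- scenario_costs(pv, n_ref, b, costs, "dropout_adjusted")
      data.frame(batch_size = b, annual_savings = sc$savings)
    }))

  npts <- seq_len(max_patients)
  cumulative <- do.call(rbind, lapply(config$scenario$batch_sizes,
    function(b) {
      sc <- lapply(npts, function(n)
        scenario_costs(pv, n, b, costs, "dropout_adjusted"))
      data.frame(batch_size = b, n_patients = npts,
                 standard_total = vapply(sc, `[[`, numeric(1), "standard_total"),
                 genotyping_total = vapply(sc, `[[`, numeric(1),
                                           "genotyping_total"))
    }))

  es <- propagate_uncertainty(chains, n_ref, min(config$scenario$batch_sizes),
                              costs, config$level)
  per_patient <- do.call(rbind, lapply(config$scenario$batch_sizes,
    function(b) {
      test <- per_test_cost(b, costs)$total_unrounded
      amort <- annual_amortization(costs)
      drug <- es[es$quantity == "drug_cost_per_patient", ]
      data.frame(batch_size = b, n_patients = npts,
                 standard_per_patient = 3 * costs$fosaprepitant_per_dose,
                 genotyping_per_patient =
                   drug$point_estimate + test + amort / npts,
                 ci_low = drug$ci_low + test + amort / npts,
                 ci_high = drug$ci_high + test + amort / npts)
    }))

  list(batch_savings = batch_savings, cumulative = cumulative,
       per_patient = per_patient)
}
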