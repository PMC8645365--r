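# shared serialization conventions: CSVs carry 6 significant digits,
# decision summaries go to JSON, every run writes a manifest
fmt6 <- function(df) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 6)))
}

write_manifest <- function(command, out_dir, outputs, seed = NULL, config = NULL) {
  missing <- outputs[!file.exists(file.path(out_dir, outputs))]
  if (length(missing)) {
    abort(sprintf("manifest lists missing output file(s): %s",
                  paste(missing, collapse = ", ")))
  }
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    version = as.character(utils::packageVersion("markovcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs)
  )
  path <- file.path(out_dir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

log_run <- function(params, ..., verbose = TRUE) {
  if (!verbose) return(invisible(NULL))
  cfg <- params$config
  extras <- list(...)
  message(sprintf(
    "run: cycle %.2g yr, discount %.3g/%.3g (costs/outcomes), start = %s",
    cfg$cycle_length_years, cfg$discount_rate_costs, cfg$discount_rate_outcomes,
    paste(sprintf("%s %.2g", names(cfg$initial_distribution)[cfg$initial_distribution > 0],
                  cfg$initial_distribution[cfg$initial_distribution > 0]), collapse = ", ")
  ))
  if (length(extras)) {
    message(paste(sprintf("  %s = %s", names(extras), unlist(extras)), collapse = "; "))
  }
  invisible(NULL)
}

#' Run the deterministic evaluation and write its outputs
#'
#' Evaluates every strategy, ranks them with dominance analysis, and writes:
#' one cohort-trace CSV per strategy (cycle, elapsed years, occupancies,
#' both discount factors), the cost-effectiveness table CSV, a decision JSON
#' (ICERs, dominance statuses, threshold verdicts), and a run manifest.
#'
#' @param params A [cea_params()] object.
#' @param out_dir Output directory (created if needed).
#' @param config_path Optional path recorded in the manifest.
#' @param verbose Log the run's key settings, default `TRUE`.
#' @return The `cea_table`, invisibly; files on disk as side effect.
#' @export
write_evaluation <- function(params, out_dir, config_path = NULL, verbose = TRUE) {
  stopifnot(inherits(params, "cea_params"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_run(params, verbose = verbose)

  ev <- evaluate_strategies(params)
  trace <- attr(ev, "trace")
  cfg <- params$config
  trace_out <- dplyr::mutate(
    as_tibble(trace),
    cost_discount = discount_factor(.data$cycle, cfg$discount_rate_costs,
                                    cfg$cycle_length_years),
    outcome_discount = discount_factor(.data$cycle, cfg$discount_rate_outcomes,
                                       cfg$cycle_length_years)
  )
  outputs <- character(0)
  for (s in ev$strategy) {
    f <- sprintf("trace_%s.csv", gsub("[^A-Za-z0-9]+", "_", s))
    readr::write_csv(fmt6(trace_out), file.path(out_dir, f))
    outputs <- c(outputs, f)
  }

  ce <- rank_strategies(ev, gdp = cfg$gdp_per_capita,
                        wtp_multipliers = cfg$wtp_multipliers)
  readr::write_csv(fmt6(as_tibble(ce)), file.path(out_dir, "ce_table.csv"))
  outputs <- c(outputs, "ce_table.csv")

  decision <- list(
    strategies = purrr::transpose(as.list(fmt6(as_tibble(ce)))),
    gdp_per_capita = cfg$gdp_per_capita,
    wtp_thresholds = cfg$wtp_multipliers * cfg$gdp_per_capita
  )
  jsonlite::write_json(decision, file.path(out_dir, "decision.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  outputs <- c(outputs, "decision.json")

  write_manifest("evaluate", out_dir, outputs, config = config_path)
  invisible(ce)
}

#' Run the tornado analysis and write its outputs
#'
#' @inheritParams write_evaluation
#' @inheritParams run_owsa
#' @return The `cea_owsa` tibble, invisibly; `tornado.csv` and a manifest on
#'   disk.
#' @export
write_owsa <- function(params, strategy, comparator, out_dir,
                       rel_change = 0.2, config_path = NULL, verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_run(params, comparison = paste(strategy, "vs", comparator), verbose = verbose)
  tor <- run_owsa(params, strategy, comparator, rel_change = rel_change)
  readr::write_csv(fmt6(as_tibble(tor)), file.path(out_dir, "tornado.csv"))
  write_manifest("owsa", out_dir, "tornado.csv", config = config_path)
  invisible(tor)
}

#' Run the probabilistic sensitivity analysis and write its outputs
#'
#' Writes the per-draw cost/QALY table, the CEAC (one probability column per
#' strategy per WTP row), and one incremental scatter CSV per ordered pair of
#' the first-listed strategy against each other strategy at 1x GDP, plus a
#' manifest.
#'
#' @inheritParams write_evaluation
#' @inheritParams run_psa
#' @param scatter_reference Strategy whose pairwise scatters are written;
#'   defaults to the first strategy name.
#' @return The `cea_psa` object, invisibly.
#' @export
write_psa <- function(params, out_dir, n_draws = 5000, seed, cost_cv = 0.2,
                      scatter_reference = NULL, config_path = NULL, verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_run(params, n_draws = n_draws, seed = seed, verbose = verbose)
  psa <- run_psa(params, n_draws = n_draws, seed = seed, cost_cv = cost_cv)

  draws_wide <- tidyr::pivot_wider(psa, id_cols = "draw", names_from = "strategy",
                                   values_from = c("cost", "qaly"))
  readr::write_csv(fmt6(draws_wide), file.path(out_dir, "psa_draws.csv"))
  outputs <- "psa_draws.csv"

  cc <- ceac(psa)
  ceac_wide <- tidyr::pivot_wider(as_tibble(cc), names_from = "strategy",
                                  values_from = "prob_optimal")
  readr::write_csv(fmt6(ceac_wide), file.path(out_dir, "ceac.csv"))
  outputs <- c(outputs, "ceac.csv")

  strategies <- sort(unique(psa$strategy))
  ref <- scatter_reference %||% strategies[1]
  gdp <- params$config$gdp_per_capita
  for (other in setdiff(strategies, ref)) {
    sc <- psa_scatter_data(psa, ref, other, wtp = gdp)
    f <- sprintf("scatter_%s_vs_%s.csv",
                 gsub("[^A-Za-z0-9]+", "_", ref), gsub("[^A-Za-z0-9]+", "_", other))
    readr::write_csv(fmt6(sc), file.path(out_dir, f))
    outputs <- c(outputs, f)
  }

  write_manifest("psa", out_dir, outputs, seed = seed, config = config_path)
  invisible(psa)
}

#' Generate a synthetic cohort and write it with a recovery report
#'
#' Writes the patient-level CSV (arm, DAS-28 band, utility, one column per
#' cost component) and a JSON report of the parameters recovered from the
#' generated records, plus a manifest.
#'
#' @inheritParams write_evaluation
#' @inheritParams generate_cohort
#' @return The patient tibble, invisibly.
#' @export
write_cohort <- function(params, out_dir, n_per_arm = NULL, seed,
                         cost_cv = 0.2, config_path = NULL, verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_run(params, n_per_arm = n_per_arm %||% "study sizes", seed = seed,
          verbose = verbose)
  cohort <- generate_cohort(params, n_per_arm = n_per_arm, seed = seed,
                            cost_cv = cost_cv)
  readr::write_csv(fmt6(cohort), file.path(out_dir, "patients.csv"))

  rec <- recover_parameters(cohort)
  jsonlite::write_json(
    list(
      responses = purrr::transpose(as.list(fmt6(rec$responses))),
      utilities = purrr::transpose(as.list(fmt6(rec$utilities))),
      costs = purrr::transpose(as.list(fmt6(rec$costs)))
    ),
    file.path(out_dir, "recovered_parameters.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null"
  )
  write_manifest("synth", out_dir, c("patients.csv", "recovered_parameters.json"),
                 seed = seed, config = config_path)
  invisible(cohort)
}
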