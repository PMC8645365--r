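# compact constructors for toy parameter sets used across tests

toy_config <- function(...) {
  cfg <- list(
    cycle_length_years = 0.25,
    discount_rate_costs = 0.058,
    discount_rate_outcomes = 0.03,
    max_cycles = 40L,
    initial_distribution = c(Remission = 0, Low = 0, Moderate = 0,
                             Severe = 1, Death = 0),
    half_cycle_correction = FALSE,
    gdp_per_capita = 12547,
    wtp_multipliers = c(1, 3)
  )
  utils::modifyList(cfg, list(...))
}

toy_strategy <- function(name, medication = 1000, utility = 0.8, sd = 0,
                         state_cycle_costs = NULL) {
  u <- if (length(utility) == 1) {
    setNames(rep(utility, 4), c("Remission", "Low", "Moderate", "Severe"))
  } else utility
  s <- if (length(sd) == 1) setNames(rep(sd, 4), names(u)) else sd
  list(
    name = name,
    annual_costs = list(medication = medication),
    utilities = purrr::map2(u, s, ~ list(mean = .x, sd = .y)),
    response = list(Remission = 1),
    state_cycle_costs = state_cycle_costs
  )
}

toy_params <- function(strategies, tm = NULL, ...) {
  if (is.null(tm)) tm <- unclass(ra_biologics_params()$transitions)
  cea_params(toy_config(...), tm, strategies)
}
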