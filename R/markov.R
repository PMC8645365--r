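#' Discount factor at a given cycle
#'
#' Elapsed time is continuous in cycles: cycle `t` of length `delta` years
#' has elapsed `t * delta` years, and the factor is
#' `1 / (1 + annual_rate)^(t * delta)`. This is exact at year boundaries and
#' smooth between them, rather than stepping once per model year.
#'
#' @param cycle_index Nonnegative integer cycle index (vectorised).
#' @param annual_rate Annual discount rate as a fraction in `[0, 1)`.
#' @param cycle_length_years Cycle length in years (e.g. `0.25`).
#' @return Discount factor(s) in `(0, 1]`.
#' @examples
#' discount_factor(4, 0.03, 0.25) # one elapsed year -> 1/1.03
#' @export
discount_factor <- function(cycle_index, annual_rate, cycle_length_years) {
  if (any(cycle_index < 0)) abort("`cycle_index` must be nonnegative.")
  (1 + annual_rate)^(-(cycle_index * cycle_length_years))
}

#' Run the cohort through the transition matrix
#'
#' Propagates the initial state distribution through the per-cycle transition
#' matrix: occupancy row `t + 1` equals row `t` times the matrix. The trace
#' stops at `max_cycles` or as soon as the living mass falls below `1e-9`
#' (a lifetime-horizon proxy; with an absorbing Death state the remaining
#' contribution is negligible).
#'
#' @param transitions A `cea_transition_matrix` (see [validate_matrix()]).
#' @param config Model configuration list as held in [cea_params()]`$config`.
#' @return A `cea_trace` tibble with columns `cycle`, `elapsed_years`, and one
#'   occupancy column per state; row `cycle = 0` is the initial distribution.
#' @examples
#' p <- ra_biologics_params()
#' run_cohort(p$transitions, p$config)
#' @export
run_cohort <- function(transitions, config) {
  tm <- unclass(as_transition_matrix(transitions))
  config <- validate_config(config)
  living <- cea_living_states()

  rows <- matrix(NA_real_, nrow = config$max_cycles + 1L, ncol = 5,
                 dimnames = list(NULL, cea_states()))
  rows[1, ] <- config$initial_distribution
  n_rows <- 1L
  for (t in seq_len(config$max_cycles)) {
    rows[t + 1L, ] <- rows[t, ] %*% tm
    n_rows <- t + 1L
    if (sum(rows[t + 1L, living]) < 1e-9) break
  }
  rows <- rows[seq_len(n_rows), , drop = FALSE]

  out <- as_tibble(rows)
  out <- dplyr::bind_cols(
    tibble(
      cycle = seq_len(n_rows) - 1L,
      elapsed_years = (seq_len(n_rows) - 1L) * config$cycle_length_years
    ),
    out
  )
  structure(out, class = c("cea_trace", class(out)), config = config)
}

# occupancy matrix (rows x 5) from a cea_trace
trace_matrix <- function(trace) {
  as.matrix(trace[, cea_states()])
}

# Discounted occupancy weights per state, the linear kernel of all totals:
#   total_cost = sum_s cycle_cost_s * w_cost[s]
#   total_qaly = sum_s utility_s * cycle_length * w_outcome[s]
# Reward attribution is start-of-cycle (row t pays cycle t); the half-cycle
# correction replaces row t by the mean of rows t and t+1.
outcome_weights <- function(trace, config) {
  occ <- trace_matrix(trace)
  if (isTRUE(config$half_cycle_correction) && nrow(occ) > 1) {
    occ <- (occ[-nrow(occ), , drop = FALSE] + occ[-1, , drop = FALSE]) / 2
  }
  cycles <- seq_len(nrow(occ)) - 1L
  list(
    cost = colSums(occ * discount_factor(cycles, config$discount_rate_costs,
                                         config$cycle_length_years)),
    outcome = colSums(occ * discount_factor(cycles, config$discount_rate_outcomes,
                                            config$cycle_length_years)),
    life_years = colSums(occ) * config$cycle_length_years
  )
}

# per-cycle cost per living state for one strategy:
# uniform allocation of the annual total unless state_cycle_costs overrides
strategy_cycle_costs <- function(params, strategy_name) {
  living <- cea_living_states()
  sc <- params$state_costs
  if (nrow(sc)) sc <- dplyr::filter(sc, .data$strategy == strategy_name)
  if (nrow(sc)) {
    return(setNames(sc$cycle_cost[match(living, sc$state)], living))
  }
  annual <- dplyr::filter(params$costs, .data$strategy == strategy_name)
  setNames(rep(sum(annual$annual_cost) * params$config$cycle_length_years, 4), living)
}

#' Accumulate discounted costs and QALYs over a trace
#'
#' Sums, over cycles and states, occupancy times per-cycle state cost (under
#' the cost discount rate) and occupancy times state utility times cycle
#' length (under the outcome discount rate). Death contributes neither cost
#' nor utility.
#'
#' @param trace A `cea_trace` from [run_cohort()].
#' @param strategy Strategy name present in `params`.
#' @param params A [cea_params()] object supplying costs and utilities.
#' @return One-row tibble: `strategy`, `cost` (discounted PPP $), `qaly`
#'   (discounted quality-adjusted life years).
#' @export
accumulate_outcomes <- function(trace, strategy, params) {
  stopifnot(inherits(params, "cea_params"))
  ut <- dplyr::filter(params$utilities, .data$strategy == !!strategy)
  if (!nrow(ut)) abort(sprintf("unknown strategy: '%s'", strategy))
  living <- cea_living_states()
  missing <- setdiff(living, ut$state)
  if (length(missing)) {
    abort(sprintf("strategy '%s' lacks a utility for state(s): %s",
                  strategy, paste(missing, collapse = ", ")))
  }
  w <- outcome_weights(trace, params$config)
  cyc_costs <- strategy_cycle_costs(params, strategy)
  u <- setNames(ut$mean[match(living, ut$state)], living)
  tibble(
    strategy = strategy,
    cost = sum(cyc_costs * w$cost[living]),
    qaly = sum(u * params$config$cycle_length_years * w$outcome[living])
  )
}

#' Evaluate every strategy's discounted cost and QALY total
#'
#' Runs the cohort once (the transition matrix and starting distribution are
#' shared across strategies) and accumulates each strategy's discounted cost
#' and QALY totals.
#'
#' @param params A [cea_params()] object.
#' @return A `cea_eval` tibble with columns `strategy`, `cost`, `qaly`, one
#'   row per strategy; the cohort trace is attached as attribute `trace`.
#' @examples
#' evaluate_strategies(ra_biologics_params())
#' @export
evaluate_strategies <- function(params) {
  stopifnot(inherits(params, "cea_params"))
  trace <- run_cohort(params$transitions, params$config)
  out <- purrr::map_dfr(unique(params$costs$strategy),
                        ~ accumulate_outcomes(trace, .x, params))
  structure(out, class = c("cea_eval", class(out)),
            trace = trace, params = params)
}
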