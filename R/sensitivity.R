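# (cost, qaly) of one strategy from precomputed occupancy weights,
# optionally with one parameter scaled; the workhorse behind the tornado
strat_outcome_weighted <- function(params, w, strategy) {
  living <- cea_living_states()
  cyc <- strategy_cycle_costs(params, strategy)
  ut <- dplyr::filter(params$utilities, .data$strategy == !!strategy)
  u <- setNames(ut$mean[match(living, ut$state)], living)
  c(
    cost = sum(cyc * w$cost[living]),
    qaly = sum(u * params$config$cycle_length_years * w$outcome[living])
  )
}

#' One-way (tornado) sensitivity analysis of a pairwise ICER
#'
#' Perturbs every cost component and every living-state utility mean of the
#' two compared strategies, one at a time, to `1 - rel_change` and
#' `1 + rel_change` of its base value (default +/-20%), re-evaluates the
#' model, and records the ICER of `strategy` against `comparator` at each
#' endpoint. Entries are sorted by descending tornado width
#' `|high_icer - low_icer|`; parameters with no influence keep zero-width
#' bars at the tail.
#'
#' Utility perturbations are applied as-is even when `1.2 * mean` exceeds 1:
#' the tornado is a deterministic what-if on the mean, not a draw from the
#' utility distribution.
#'
#' @param params A [cea_params()] object.
#' @param strategy,comparator Names of the two strategies whose ICER is
#'   studied (`strategy` minus `comparator` in both numerator and
#'   denominator).
#' @param rel_change Relative perturbation, default `0.2`.
#' @return A `cea_owsa` tibble: `parameter`, `strategy`, `kind`
#'   (`"cost"`/`"utility"`), `item`, `base_value`, `low_icer`, `high_icer`,
#'   `base_icer`, `width`.
#' @examples
#' run_owsa(ra_biologics_params(), "Adalimumab", "Infliximab")
#' @export
run_owsa <- function(params, strategy, comparator, rel_change = 0.2) {
  stopifnot(inherits(params, "cea_params"))
  pair <- c(strategy, comparator)
  known <- unique(params$costs$strategy)
  if (!all(pair %in% known)) {
    abort(sprintf("unknown strategy name(s): %s",
                  paste(setdiff(pair, known), collapse = ", ")))
  }
  trace <- run_cohort(params$transitions, params$config)
  w <- outcome_weights(trace, params$config)

  pair_icer <- function(p) {
    a <- strat_outcome_weighted(p, w, strategy)
    b <- strat_outcome_weighted(p, w, comparator)
    icer(a["cost"], b["cost"], a["qaly"], b["qaly"])
  }
  base_icer <- pair_icer(params)

  grid <- dplyr::bind_rows(
    dplyr::filter(params$costs, .data$strategy %in% pair) |>
      dplyr::transmute(.data$strategy, kind = "cost", item = .data$component,
                       base_value = .data$annual_cost),
    dplyr::filter(params$utilities, .data$strategy %in% pair) |>
      dplyr::transmute(.data$strategy, kind = "utility", item = .data$state,
                       base_value = .data$mean)
  )

  perturbed <- function(strat, kind, item, value) {
    p <- params
    if (kind == "cost") {
      i <- which(p$costs$strategy == strat & p$costs$component == item)
      p$costs$annual_cost[i] <- value
    } else {
      i <- which(p$utilities$strategy == strat & p$utilities$state == item)
      p$utilities$mean[i] <- value
    }
    p
  }

  out <- purrr::pmap_dfr(grid, function(strategy, kind, item, base_value) {
    lo <- pair_icer(perturbed(strategy, kind, item, base_value * (1 - rel_change)))
    hi <- pair_icer(perturbed(strategy, kind, item, base_value * (1 + rel_change)))
    tibble(
      parameter = sprintf("%s %s %s", strategy, kind, item),
      strategy = strategy, kind = kind, item = item, base_value = base_value,
      low_icer = unname(lo), high_icer = unname(hi),
      base_icer = unname(base_icer)
    )
  })
  out <- dplyr::mutate(out, width = abs(.data$high_icer - .data$low_icer)) |>
    dplyr::arrange(dplyr::desc(.data$width))
  structure(out, class = c("cea_owsa", class(out)),
            strategy = strategy, comparator = comparator,
            rel_change = rel_change)
}

# feasibility sweep before any sampling: every (strategy, state) utility with
# sd > 0 must admit a beta fit
check_psa_feasible <- function(params) {
  ut <- dplyr::filter(params$utilities, .data$sd > 0)
  if (nrow(ut)) {
    bad <- ut$sd^2 >= ut$mean * (1 - ut$mean) | ut$mean <= 0 | ut$mean >= 1
    if (any(bad)) {
      b <- ut[which(bad)[1], ]
      abort(sprintf(
        "infeasible beta utility for %s/%s (mean %.4g, sd %.4g): shrink the SD below %.4g.",
        b$strategy, b$state, b$mean, b$sd, beta_feasible_sd(b$mean)
      ))
    }
  }
  invisible(TRUE)
}

#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' Draws every utility parameter from a moment-matched beta distribution and
#' every annual cost component from a moment-matched gamma distribution, once
#' per trial, and evaluates each strategy's discounted totals on the shared
#' draw. Cost SDs are not part of the base parameter set, so the gamma fit
#' uses a coefficient of variation (`cost_cv`, default 0.2) on each component
#' mean; a parameter with zero SD (or a zero-mean cost) is a degenerate point
#' mass. The transition matrix is not sampled, so the occupancy trace is
#' shared across draws and totals are evaluated through precomputed
#' discounted occupancy weights.
#'
#' Sampling order is fixed (strategies alphabetically; within a strategy,
#' utility states then cost components alphabetically), so a given seed
#' yields bit-identical results.
#'
#' @param params A [cea_params()] object.
#' @param n_draws Number of Monte Carlo trials (default 5000).
#' @param seed Integer RNG seed; required for reproducibility.
#' @param cost_cv Coefficient of variation applied to each cost component
#'   mean for the gamma fit. `0` makes all costs degenerate.
#' @return A `cea_psa` tibble: `draw`, `strategy`, `cost`, `qaly`, with
#'   attributes `seed`, `n_draws`, `cost_cv`, `params`, and `base` (the
#'   deterministic [evaluate_strategies()] table).
#' @examples
#' psa <- run_psa(ra_biologics_params(), n_draws = 200, seed = 1)
#' @export
run_psa <- function(params, n_draws = 5000, seed, cost_cv = 0.2) {
  stopifnot(inherits(params, "cea_params"))
  if (missing(seed)) abort("`seed` is required for a reproducible PSA.")
  if (n_draws < 1) abort("`n_draws` must be a positive integer.")
  check_psa_feasible(params)

  trace <- run_cohort(params$transitions, params$config)
  w <- outcome_weights(trace, params$config)
  living <- cea_living_states()
  delta <- params$config$cycle_length_years
  strategies <- sort(unique(params$costs$strategy))

  draws <- withr::with_seed(seed, {
    purrr::map_dfr(strategies, function(s) {
      ut <- dplyr::filter(params$utilities, .data$strategy == s) |>
        dplyr::arrange(.data$state)
      u_draws <- purrr::map(seq_len(nrow(ut)), function(i) {
        m <- ut$mean[i]; sdev <- ut$sd[i]
        if (sdev == 0) return(rep(m, n_draws))
        sh <- beta_params_from_moments(m, sdev)
        rbeta(n_draws, sh$alpha, sh$beta)
      })
      names(u_draws) <- ut$state

      co <- dplyr::filter(params$costs, .data$strategy == s) |>
        dplyr::arrange(.data$component)
      c_draws <- purrr::map(co$annual_cost, function(m) {
        sdev <- cost_cv * m
        if (m == 0 || sdev == 0) return(rep(m, n_draws))
        sh <- gamma_params_from_moments(m, sdev)
        rgamma(n_draws, shape = sh$shape, rate = sh$rate)
      })
      annual_total <- Reduce(`+`, c_draws)

      qaly <- Reduce(`+`, purrr::map(living, function(st) {
        u_draws[[st]] * delta * w$outcome[st]
      }))

      sc <- params$state_costs
      if (nrow(sc)) sc <- dplyr::filter(sc, .data$strategy == s)
      if (nrow(sc)) {
        # state-cost override: scale base state costs by the sampled annual
        # total relative to the base annual total
        base_total <- sum(co$annual_cost)
        scale <- if (base_total > 0) annual_total / base_total else 1
        base_state_cost <- sum(strategy_cycle_costs(params, s) * w$cost[living])
        cost <- base_state_cost * scale
      } else {
        cost <- annual_total * delta * sum(w$cost[living])
      }

      tibble(draw = seq_len(n_draws), strategy = s, cost = cost, qaly = qaly)
    })
  })

  structure(draws, class = c("cea_psa", class(draws)),
            seed = seed, n_draws = n_draws, cost_cv = cost_cv,
            params = params, base = evaluate_strategies(params))
}

# default willingness-to-pay grid: 0 to 3x GDP in 100 steps, with 1x GDP
# always included as a grid point
default_wtp_grid <- function(gdp, multipliers = c(1, 3)) {
  sort(unique(c(seq(0, multipliers[2] * gdp, length.out = 100),
                multipliers[1] * gdp)))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that each strategy is
#' optimal: the fraction of PSA draws in which it attains the maximal net
#' monetary benefit, ties split equally among the tied strategies.
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Ascending WTP values; defaults to 0 to 3x GDP per capita
#'   in 100 steps with 1x GDP included.
#' @return A `cea_ceac` tibble: `wtp`, `strategy`, `prob_optimal`.
#' @export
ceac <- function(psa, wtp_grid = NULL) {
  stopifnot(inherits(psa, "cea_psa"))
  if (is.null(wtp_grid)) {
    cfg <- attr(psa, "params")$config
    wtp_grid <- default_wtp_grid(cfg$gdp_per_capita, cfg$wtp_multipliers)
  }
  if (!length(wtp_grid) || is.unsorted(wtp_grid)) {
    abort("`wtp_grid` must be a nonempty ascending vector.")
  }
  wide_c <- tidyr::pivot_wider(psa, id_cols = "draw", names_from = "strategy",
                               values_from = "cost")
  wide_q <- tidyr::pivot_wider(psa, id_cols = "draw", names_from = "strategy",
                               values_from = "qaly")
  strategies <- setdiff(names(wide_c), "draw")
  cm <- as.matrix(wide_c[, strategies])
  qm <- as.matrix(wide_q[, strategies])
  n <- nrow(cm)

  out <- purrr::map_dfr(wtp_grid, function(wtp) {
    nmb <- qm * wtp - cm
    mx <- do.call(pmax, as.data.frame(nmb))
    ties <- rowSums(nmb == mx)
    tibble(
      wtp = wtp,
      strategy = strategies,
      prob_optimal = unname(colSums((nmb == mx) / ties)) / n
    )
  })
  structure(out, class = c("cea_ceac", class(out)), n_draws = n)
}

#' Pairwise acceptance fraction below a willingness-to-pay threshold
#'
#' The fraction of PSA draws in which strategy A is acceptable against
#' strategy B at the given WTP: draws where the incremental net monetary
#' benefit `(qaly_a - qaly_b) * wtp - (cost_a - cost_b)` is strictly
#' positive (the scatter-plot points falling in the acceptance region below
#' the threshold line).
#'
#' @param psa A [run_psa()] result.
#' @param strategy_a,strategy_b Strategy names present in the PSA.
#' @param wtp Willingness-to-pay value(s), PPP $ per QALY.
#' @return Fraction(s) in `[0, 1]`, one per `wtp` value.
#' @export
acceptance_fraction <- function(psa, strategy_a, strategy_b, wtp) {
  stopifnot(inherits(psa, "cea_psa"))
  sc <- psa_scatter_data(psa, strategy_a, strategy_b)
  vapply(wtp, function(l) mean(sc$incr_qaly * l - sc$incr_cost > 0), numeric(1))
}

#' Incremental scatter data for a strategy pair
#'
#' Per-draw incremental cost and QALY of strategy A over strategy B, with an
#' acceptance flag at the supplied WTP (strict inequality, matching
#' [acceptance_fraction()]). This is the plot-ready table behind the
#' incremental cost-effectiveness scatter.
#'
#' @inheritParams acceptance_fraction
#' @param wtp Single WTP used for the `accepted` flag (optional).
#' @return Tibble: `draw`, `incr_cost`, `incr_qaly` (and `accepted` when
#'   `wtp` is given).
#' @export
psa_scatter_data <- function(psa, strategy_a, strategy_b, wtp = NULL) {
  stopifnot(inherits(psa, "cea_psa"))
  known <- unique(psa$strategy)
  missing <- setdiff(c(strategy_a, strategy_b), known)
  if (length(missing)) {
    abort(sprintf("unknown strategy name(s): %s", paste(missing, collapse = ", ")))
  }
  a <- dplyr::filter(psa, .data$strategy == strategy_a) |> dplyr::arrange(.data$draw)
  b <- dplyr::filter(psa, .data$strategy == strategy_b) |> dplyr::arrange(.data$draw)
  out <- tibble(
    draw = a$draw,
    incr_cost = a$cost - b$cost,
    incr_qaly = a$qaly - b$qaly
  )
  if (!is.null(wtp)) {
    out$accepted <- out$incr_qaly * wtp - out$incr_cost > 0
  }
  out
}
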