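test_that("discount_factor matches its closed form", {
  expect_equal(discount_factor(0, 0.058, 0.25), 1.0)
  expect_equal(discount_factor(4, 0.03, 0.25), 1 / 1.03)
  expect_equal(discount_factor(8, 0.058, 0.25), 1 / 1.058^2)
  expect_equal(discount_factor(0:4, 0, 0.25), rep(1, 5))
  expect_error(discount_factor(-1, 0.03, 0.25), "nonnegative")
})

test_that("identity matrix leaves the cohort in its starting state", {
  cfg <- toy_config(max_cycles = 10L,
                    initial_distribution = c(Remission = 0.3, Low = 0.7,
                                             Moderate = 0, Severe = 0, Death = 0))
  trace <- run_cohort(validate_matrix(diag(5)), cfg)
  occ <- as.matrix(trace[, states5])
  expect_equal(nrow(occ), 11)
  for (t in seq_len(nrow(occ))) {
    expect_equal(unname(occ[t, ]), c(0.3, 0.7, 0, 0, 0))
  }
})

test_that("first cycles from a severe start reproduce hand-computed products", {
  p <- ra_biologics_params()
  trace <- run_cohort(p$transitions, p$config)
  occ <- as.matrix(trace[, states5])
  # one step from 100% Severe is the Severe transition row
  expect_equal(unname(occ[2, ]), c(0.020, 0.040, 0.307, 0.621, 0.012))
  # two steps equal the independent matrix-power product
  tm <- unclass(p$transitions)
  start <- c(0, 0, 0, 1, 0)
  expect_equal(unname(occ[3, ]), unname(drop(start %*% mat_pow(tm, 2))),
               tolerance = 1e-12)
})

test_that("trace equals the matrix-power oracle for t <= 50", {
  p <- ra_biologics_params()
  trace <- run_cohort(p$transitions, toy_config(max_cycles = 50L))
  occ <- as.matrix(trace[, states5])
  tm <- unclass(p$transitions)
  start <- c(0, 0, 0, 1, 0)
  for (t in c(1, 5, 17, 33, 50)) {
    expect_equal(unname(occ[t + 1, ]), unname(drop(start %*% mat_pow(tm, t))),
                 tolerance = 1e-12)
  }
})

test_that("probability is conserved and Death is monotone for random matrices", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      tm <- random_transition_matrix()
      init <- stats::runif(4)
      init <- c(init / sum(init), 0)
      names(init) <- states5
      trace <- run_cohort(validate_matrix(tm),
                          toy_config(max_cycles = 30L, initial_distribution = init))
      occ <- as.matrix(trace[, states5])
      expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
      expect_true(all(diff(occ[, "Death"]) >= -1e-12))
    }
  })
})

test_that("the trace stops early once the living mass is exhausted", {
  # everyone dies in one cycle from every living state
  tm <- rbind(matrix(rep(c(0, 0, 0, 0, 1), 4), 4, 5, byrow = TRUE),
              c(0, 0, 0, 0, 1))
  trace <- run_cohort(validate_matrix(tm), toy_config(max_cycles = 400L))
  expect_lt(nrow(trace), 5)
  occ <- as.matrix(trace[, states5])
  expect_equal(unname(occ[nrow(occ), "Death"]), 1)
})

test_that("accumulate_outcomes reproduces single-term and series closed forms", {
  # zero cost, zero utility annihilates both totals
  null_p <- toy_params(list(toy_strategy("Null", medication = 0, utility = 0),
                            toy_strategy("B")))
  trace <- run_cohort(null_p$transitions, null_p$config)
  out <- accumulate_outcomes(trace, "Null", null_p)
  expect_equal(out$cost, 0)
  expect_equal(out$qaly, 0)

  # one cycle, 100% Remission, utility 0.836, no discounting:
  # QALY = 0.836 * 0.25 paid at cycle 0 (and the trace's final row)
  one <- toy_params(
    list(toy_strategy("A", utility = 0.836), toy_strategy("B")),
    tm = diag(5),
    max_cycles = 1L, discount_rate_outcomes = 0,
    initial_distribution = c(Remission = 1, Low = 0, Moderate = 0,
                             Severe = 0, Death = 0)
  )
  trace1 <- run_cohort(one$transitions, one$config)
  out1 <- accumulate_outcomes(trace1, "A", one)
  # two occupancy rows (cycles 0 and 1), each 0.836 * 0.25
  expect_equal(out1$qaly, 2 * 0.836 * 0.25)
  single_row <- trace1[1, ]
  expect_equal(accumulate_outcomes(single_row, "A", one)$qaly, 0.836 * 0.25)

  # immortal cohort at constant utility: finite geometric series in the
  # per-cycle discount x = (1+r)^(-delta), independently computed
  r <- 0.03; delta <- 0.25; u <- 0.7; n <- 200L
  imm <- toy_params(list(toy_strategy("A", utility = u), toy_strategy("B")),
                    tm = diag(5), max_cycles = n)
  tr <- run_cohort(imm$transitions, imm$config)
  got <- accumulate_outcomes(tr, "A", imm)$qaly
  x <- (1 + r)^(-delta)
  expect_equal(got, u * delta * (1 - x^(n + 1)) / (1 - x), tolerance = 1e-12)
  # and approaches the infinite-series form u*delta/(1-x) within truncation
  expect_equal(got, u * delta / (1 - x), tolerance = x^(n + 1) / (1 - x) + 1e-12)
})

test_that("discounting can only shrink totals; zero rates leave them unchanged", {
  base <- ra_biologics_params()
  ev_disc <- evaluate_strategies(base)
  undisc <- base
  undisc$config$discount_rate_costs <- 0
  undisc$config$discount_rate_outcomes <- 0
  ev_un <- evaluate_strategies(undisc)
  expect_true(all(ev_disc$cost < ev_un$cost))
  expect_true(all(ev_disc$qaly < ev_un$qaly))

  same <- evaluate_strategies(undisc)
  expect_equal(same$cost, ev_un$cost)

  # QALYs never exceed undiscounted life-years
  trace <- attr(ev_un, "trace")
  ly <- sum(as.matrix(trace[, c("Remission", "Low", "Moderate", "Severe")])) * 0.25
  expect_true(all(ev_disc$qaly <= ly))
})

test_that("totals are monotone in utilities and costs", {
  p <- ra_biologics_params()
  base <- evaluate_strategies(p)

  up_u <- p
  i <- which(up_u$utilities$strategy == "Infliximab" & up_u$utilities$state == "Moderate")
  up_u$utilities$mean[i] <- up_u$utilities$mean[i] + 0.1
  ev <- evaluate_strategies(up_u)
  expect_gt(ev$qaly[ev$strategy == "Infliximab"],
            base$qaly[base$strategy == "Infliximab"])
  expect_equal(ev$cost, base$cost)

  up_c <- p
  j <- which(up_c$costs$strategy == "Etanercept" & up_c$costs$component == "medication")
  up_c$costs$annual_cost[j] <- up_c$costs$annual_cost[j] * 1.5
  ev <- evaluate_strategies(up_c)
  expect_gt(ev$cost[ev$strategy == "Etanercept"],
            base$cost[base$strategy == "Etanercept"])
  expect_equal(ev$qaly, base$qaly)
})

test_that("half-cycle correction averages adjacent occupancy rows", {
  p <- ra_biologics_params()
  p$config$max_cycles <- 20L
  hcc <- p
  hcc$config$half_cycle_correction <- TRUE

  ev <- evaluate_strategies(p)
  ev_h <- evaluate_strategies(hcc)

  # independent recomputation of the corrected QALY for one strategy
  trace <- attr(ev, "trace")
  occ <- as.matrix(trace[, states5])
  mid <- (occ[-nrow(occ), ] + occ[-1, ]) / 2
  ut <- dplyr::filter(p$utilities, strategy == "Infliximab")
  u <- setNames(ut$mean, ut$state)[c("Remission", "Low", "Moderate", "Severe")]
  df <- discount_factor(seq_len(nrow(mid)) - 1, 0.03, 0.25)
  expected <- sum((mid[, 1:4] %*% u) * 0.25 * df)
  expect_equal(ev_h$qaly[ev_h$strategy == "Infliximab"], expected, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(ev$qaly, ev_h$qaly)))
})

test_that("state-specific cycle costs override the uniform allocation", {
  uniform <- toy_params(list(toy_strategy("A", medication = 400), toy_strategy("B")))
  # uniform: 400/year * 0.25 = 100 per cycle in every living state;
  # the explicit override with the same 100s must agree exactly
  override <- toy_params(list(
    toy_strategy("A", medication = 400, state_cycle_costs = list(
      Remission = 100, Low = 100, Moderate = 100, Severe = 100
    )),
    toy_strategy("B")
  ))
  ev_u <- evaluate_strategies(uniform)
  ev_o <- evaluate_strategies(override)
  expect_equal(ev_o$cost[ev_o$strategy == "A"], ev_u$cost[ev_u$strategy == "A"])

  # loading cost onto the severe state changes the total under a severe start
  skewed <- toy_params(list(
    toy_strategy("A", medication = 400, state_cycle_costs = list(
      Remission = 0, Low = 0, Moderate = 0, Severe = 400
    )),
    toy_strategy("B")
  ))
  ev_s <- evaluate_strategies(skewed)
  expect_gt(ev_s$cost[ev_s$strategy == "A"], ev_u$cost[ev_u$strategy == "A"])
})
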