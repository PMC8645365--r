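test_that("tornado entries match brute-force re-evaluation at the endpoints", {
  p <- ra_biologics_params()
  p$config$max_cycles <- 60L
  tor <- run_owsa(p, "Adalimumab", "Infliximab")

  expect_equal(nrow(tor), 2 * (10 + 4))     # two strategies x (components + states)
  expect_true(all(diff(tor$width) <= 1e-9)) # sorted by descending width
  expect_equal(length(unique(tor$base_icer)), 1)

  # oracle: rebuild a fresh parameter set with the perturbed value and run the
  # full evaluation path
  reeval_icer <- function(p2) {
    ev <- evaluate_strategies(p2)
    icer(ev$cost[ev$strategy == "Adalimumab"], ev$cost[ev$strategy == "Infliximab"],
         ev$qaly[ev$strategy == "Adalimumab"], ev$qaly[ev$strategy == "Infliximab"])
  }
  row <- tor[tor$parameter == "Adalimumab cost medication", ]
  for (fac in c(0.8, 1.2)) {
    p2 <- p
    i <- which(p2$costs$strategy == "Adalimumab" & p2$costs$component == "medication")
    p2$costs$annual_cost[i] <- row$base_value * fac
    expected <- reeval_icer(p2)
    got <- if (fac < 1) row$low_icer else row$high_icer
    expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("an inert parameter produces a zero-width bar at the tail", {
  p <- ra_biologics_params()
  p$config$max_cycles <- 40L
  # injection cost is 0 for Adalimumab: perturbing it cannot move the ICER
  tor <- run_owsa(p, "Adalimumab", "Infliximab")
  inert <- tor[tor$parameter == "Adalimumab cost injection", ]
  expect_equal(inert$width, 0)
  expect_equal(inert$low_icer, inert$base_icer)
  expect_equal(inert$high_icer, inert$base_icer)
  expect_equal(tor$width[nrow(tor)], 0)
})

test_that("the comparator's remission utility ranks among the top-sensitivity entries", {
  p <- ra_biologics_params()
  tor <- run_owsa(p, "Adalimumab", "Infliximab")
  rank_ada_rem <- which(tor$parameter == "Adalimumab utility Remission")
  expect_lte(rank_ada_rem, nrow(tor) / 2)
  expect_gt(tor$width[rank_ada_rem], 0)
})

test_that("cost perturbations move the ICER collinearly around the base", {
  p <- ra_biologics_params()
  p$config$max_cycles <- 40L
  tor <- run_owsa(p, "Adalimumab", "Infliximab")
  # a cost component enters the numerator linearly with the QALY gap fixed,
  # so ICER(x0.8) and ICER(x1.2) sit symmetrically around the base
  row <- tor[tor$parameter == "Adalimumab cost medication", ]
  expect_equal((row$low_icer + row$high_icer) / 2, row$base_icer, tolerance = 1e-9)
})

test_that("an undefined base ICER propagates from equal-QALY comparators", {
  p <- toy_params(list(toy_strategy("A", medication = 100, utility = 0.5),
                       toy_strategy("B", medication = 900, utility = 0.5)))
  tor <- run_owsa(p, "A", "B")
  expect_true(all(is.na(tor$base_icer)))
})

test_that("a degenerate PSA (all SDs zero) reproduces the deterministic table", {
  p <- ra_biologics_params()
  p$config$max_cycles <- 60L
  p$utilities$sd <- 0
  psa <- run_psa(p, n_draws = 25, seed = 5, cost_cv = 0)
  base <- evaluate_strategies(p)
  for (s in base$strategy) {
    sub <- psa[psa$strategy == s, ]
    expect_equal(sub$cost, rep(base$cost[base$strategy == s], 25))
    expect_equal(sub$qaly, rep(base$qaly[base$strategy == s], 25))
  }
  # and the ranked table from any single draw equals the deterministic one
  d1 <- psa[psa$draw == 1, c("strategy", "cost", "qaly")]
  expect_equal(as.data.frame(rank_strategies(d1)),
               as.data.frame(rank_strategies(base)))
})

test_that("PSA draws are reproducible from the seed and differ across seeds", {
  p <- ra_biologics_params()
  p$config$max_cycles <- 60L
  a <- run_psa(p, n_draws = 50, seed = 33)
  b <- run_psa(p, n_draws = 50, seed = 33)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(ceac(a), ceac(b))
  expect_equal(acceptance_fraction(a, "Infliximab", "Adalimumab", 12547),
               acceptance_fraction(b, "Infliximab", "Adalimumab", 12547))

  c_ <- run_psa(p, n_draws = 50, seed = 34)
  expect_false(identical(as.data.frame(a), as.data.frame(c_)))
})

test_that("PSA draw means agree with the deterministic base within MC error", {
  p <- ra_biologics_params()
  p$config$max_cycles <- 60L
  psa <- run_psa(p, n_draws = 2000, seed = 8)
  base <- evaluate_strategies(p)
  for (s in base$strategy) {
    sub <- psa[psa$strategy == s, ]
    se_cost <- sd(sub$cost) / sqrt(nrow(sub))
    expect_lt(abs(mean(sub$cost) - base$cost[base$strategy == s]), 3 * se_cost)
    # a beta's mean matches the moment target exactly, so QALY means converge
    se_qaly <- sd(sub$qaly) / sqrt(nrow(sub))
    expect_lt(abs(mean(sub$qaly) - base$qaly[base$strategy == s]), 4 * se_qaly)
  }
})

test_that("PSA draws equal a full Markov re-evaluation at the drawn parameters", {
  # draws with zero utility SD isolate cost sampling; feeding the sampled
  # annual totals back through the full evaluation path must reproduce the
  # recorded costs (linearity of the accumulator in the parameters)
  p <- ra_biologics_params()
  p$config$max_cycles <- 30L
  p$utilities$sd <- 0
  psa <- run_psa(p, n_draws = 5, seed = 21, cost_cv = 0.2)
  base <- evaluate_strategies(p)
  for (s in unique(psa$strategy)) {
    sub <- psa[psa$strategy == s, ]
    base_cost <- base$cost[base$strategy == s]
    base_total <- sum(p$costs$annual_cost[p$costs$strategy == s])
    implied_totals <- sub$cost / base_cost * base_total
    for (d in 1:5) {
      p2 <- p
      rows <- which(p2$costs$strategy == s)
      p2$costs$annual_cost[rows] <- p2$costs$annual_cost[rows] *
        implied_totals[d] / base_total
      ev <- evaluate_strategies(p2)
      expect_equal(ev$cost[ev$strategy == s], sub$cost[d], tolerance = 1e-9)
    }
  }
})

test_that("infeasible beta utilities abort the PSA before sampling", {
  p <- ra_biologics_params()
  i <- which(p$utilities$strategy == "Infliximab" & p$utilities$state == "Remission")
  p$utilities$sd[i] <- 0.5   # 0.5^2 > 0.836 * 0.164
  expect_error(run_psa(p, n_draws = 10, seed = 1), "infeasible beta")
  expect_error(generate_cohort(p, seed = 1), "infeasible beta")
})

test_that("CEAC probabilities are probabilities, sum to one, and match a recount", {
  p <- ra_biologics_params()
  p$config$max_cycles <- 60L
  psa <- run_psa(p, n_draws = 400, seed = 13)
  cc <- ceac(psa, wtp_grid = c(0, 5000, 12547, 40000))

  sums <- dplyr::count(cc, wtp, wt = prob_optimal)
  expect_equal(sums$n, rep(1, 4), tolerance = 1e-12)
  expect_true(all(cc$prob_optimal >= 0 & cc$prob_optimal <= 1))

  for (w in c(0, 12547)) {
    oracle <- oracle_ceac_point(as.data.frame(psa), w)
    got <- cc[cc$wtp == w, ]
    expect_equal(setNames(got$prob_optimal, got$strategy), oracle[got$strategy])
  }

  # at WTP 0 the per-draw winner is the cheapest strategy
  zero <- cc[cc$wtp == 0, ]
  cheap_wins <- tapply(psa$cost, psa$draw, function(x) which.min(x))
  expect_equal(
    zero$prob_optimal[zero$strategy == sort(unique(psa$strategy))[1]],
    mean(cheap_wins == 1)
  )

  # the max-QALY strategy can only gain probability from the low to the high
  # end of the WTP grid
  mean_q <- tapply(psa$qaly, psa$strategy, mean)
  best <- names(which.max(mean_q))
  lo <- cc$prob_optimal[cc$wtp == 0 & cc$strategy == best]
  hi <- cc$prob_optimal[cc$wtp == 40000 & cc$strategy == best]
  expect_gte(hi, lo)
})

test_that("ceac defaults to a 0-3x GDP grid containing 1x GDP", {
  p <- ra_biologics_params()
  p$config$max_cycles <- 40L
  psa <- run_psa(p, n_draws = 20, seed = 2)
  cc <- ceac(psa)
  expect_true(12547 %in% cc$wtp)
  expect_equal(max(cc$wtp), 3 * 12547)
  expect_equal(min(cc$wtp), 0)
})

test_that("a single-strategy PSA is always optimal", {
  p <- toy_params(list(toy_strategy("Only", medication = 100, utility = 0.6,
                                    sd = 0.1)))
  psa <- run_psa(p, n_draws = 30, seed = 4)
  cc <- ceac(psa, wtp_grid = c(0, 12547))
  expect_equal(cc$prob_optimal, c(1, 1))
})

test_that("acceptance fractions use strict inequality and match a recount", {
  p <- ra_biologics_params()
  p$config$max_cycles <- 60L
  psa <- run_psa(p, n_draws = 300, seed = 17)

  # identical strategies: never strictly better
  expect_equal(acceptance_fraction(psa, "Infliximab", "Infliximab", 12547), 0)

  got <- acceptance_fraction(psa, "Infliximab", "Etanercept", 12547)
  expect_equal(got, oracle_acceptance(as.data.frame(psa), "Infliximab",
                                      "Etanercept", 12547))
  expect_error(acceptance_fraction(psa, "Infliximab", "Nope", 12547), "Nope")

  sc <- psa_scatter_data(psa, "Infliximab", "Etanercept", wtp = 12547)
  expect_equal(mean(sc$accepted), got)
  expect_equal(nrow(sc), 300)
})

test_that("a strategy dominating in every draw has acceptance fraction 1", {
  p <- toy_params(list(toy_strategy("Cheap", medication = 10, utility = 0.9),
                       toy_strategy("Costly", medication = 5000, utility = 0.2)))
  psa <- run_psa(p, n_draws = 40, seed = 3, cost_cv = 0.1)
  expect_equal(acceptance_fraction(psa, "Cheap", "Costly", 12547), 1)
})
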