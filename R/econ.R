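#' Incremental cost-effectiveness ratio
#'
#' `(cost_a - cost_b) / (outcome_a - outcome_b)`: the extra cost per extra
#' unit of outcome (here PPP $ per QALY) of strategy A over comparator B.
#' When the outcomes are equal the ratio is undefined and `NA` is returned;
#' the caller decides dominance by cost alone.
#'
#' @param cost_a,cost_b Total costs of strategy A and comparator B.
#' @param outcome_a,outcome_b Total outcomes (QALYs) of A and B.
#' @return The ratio (vectorised); `NA` where `outcome_a == outcome_b`.
#' @examples
#' icer(91695.59, 79518.33, 13.25, 12.34)
#' @export
icer <- function(cost_a, cost_b, outcome_a, outcome_b) {
  out <- (cost_a - cost_b) / (outcome_a - outcome_b)
  out[outcome_a == outcome_b] <- NA_real_
  out
}

#' Net monetary benefit
#'
#' `qaly * wtp - cost`: a strategy's value at a given willingness-to-pay,
#' on the money scale. The strategy with the highest NMB at a given WTP is
#' the optimal choice there; across PSA draws this defines the
#' cost-effectiveness acceptability curve.
#'
#' @param cost Total cost (PPP $).
#' @param qaly Total QALYs.
#' @param wtp Willingness to pay (PPP $ per QALY), nonnegative.
#' @return NMB in PPP $ (vectorised).
#' @export
net_monetary_benefit <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) abort("`wtp` must be nonnegative.")
  qaly * wtp - cost
}

#' Rank strategies by cost with dominance analysis
#'
#' Sorts strategies by ascending cost and classifies each row:
#' * **absolutely dominated** — some other strategy costs no more and yields
#'   at least as many QALYs (with at least one strict inequality; identical
#'   pairs are broken by name order);
#' * **extendedly dominated** — among the survivors, a strategy whose
#'   incremental ICER against the previous survivor exceeds the ICER of the
#'   next survivor against itself lies above the efficiency frontier and is
#'   removed (iterated until the ICER sequence is nondecreasing);
#' * the cheapest surviving strategy is the **reference**; the remaining
#'   nondominated strategies carry sequential ICERs.
#'
#' Nondominated rows report increments against the previous nondominated
#' strategy; dominated rows report increments against the reference.
#'
#' @param results Data frame with columns `strategy`, `cost`, `qaly`
#'   (e.g. a [evaluate_strategies()] result).
#' @param gdp Optional GDP per capita; when supplied, a `verdict` column from
#'   [classify_icer()] is added for rows with a finite ICER.
#' @param wtp_multipliers Threshold multipliers used with `gdp`.
#' @return A `cea_table` tibble: `strategy`, `cost`, `qaly`, `incr_cost`,
#'   `incr_qaly`, `icer`, `status` (and `verdict` if `gdp` given).
#' @examples
#' res <- tibble::tibble(
#'   strategy = c("Infliximab", "Etanercept", "Adalimumab"),
#'   cost = c(79518.33, 87440.92, 91695.59),
#'   qaly = c(12.34, 11.79, 13.25)
#' )
#' rank_strategies(res, gdp = 12547)
#' @export
rank_strategies <- function(results, gdp = NULL, wtp_multipliers = c(1, 3)) {
  results <- as.data.frame(results)
  df <- tibble(strategy = results$strategy, cost = results$cost,
               qaly = results$qaly)
  if (anyDuplicated(df$strategy)) abort("strategy names must be distinct.")
  if (nrow(df) < 2) abort("at least two strategies are required for ranking.")
  df <- dplyr::arrange(df, .data$cost, .data$qaly, .data$strategy)

  n <- nrow(df)
  status <- rep("nondominated", n)

  # absolute (incl. weak) dominance; identical pairs broken by name order
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ci <- df$cost[i]; cj <- df$cost[j]
      qi <- df$qaly[i]; qj <- df$qaly[j]
      if (cj < ci && qj >= qi) status[i] <- "absolutely_dominated"
      if (cj <= ci && qj > qi) status[i] <- "absolutely_dominated"
      if (cj == ci && qj == qi && df$strategy[j] < df$strategy[i]) {
        status[i] <- "absolutely_dominated"
      }
    }
  }

  # extended dominance on the survivors, iterated until the sequential ICERs
  # are nondecreasing along the frontier
  repeat {
    surv <- which(status == "nondominated")
    if (length(surv) < 3) break
    icers <- icer(df$cost[surv[-1]], df$cost[surv[-length(surv)]],
                  df$qaly[surv[-1]], df$qaly[surv[-length(surv)]])
    drop <- which(head(icers, -1) > tail(icers, -1))
    if (!length(drop)) break
    status[surv[drop[1] + 1]] <- "extendedly_dominated"
  }

  surv <- which(status == "nondominated")
  status[surv[1]] <- "reference"
  ref <- surv[1]

  incr_cost <- incr_qaly <- icer_col <- rep(NA_real_, n)
  incr_cost[ref] <- 0; incr_qaly[ref] <- 0
  if (length(surv) > 1) {
    prev <- surv[-length(surv)]; cur <- surv[-1]
    incr_cost[cur] <- df$cost[cur] - df$cost[prev]
    incr_qaly[cur] <- df$qaly[cur] - df$qaly[prev]
    icer_col[cur] <- icer(df$cost[cur], df$cost[prev], df$qaly[cur], df$qaly[prev])
  }
  dom <- which(!(seq_len(n) %in% surv))
  incr_cost[dom] <- df$cost[dom] - df$cost[ref]
  incr_qaly[dom] <- df$qaly[dom] - df$qaly[ref]

  out <- dplyr::mutate(df, incr_cost = incr_cost, incr_qaly = incr_qaly,
                       icer = icer_col, status = status)
  if (!is.null(gdp)) {
    out$verdict <- NA_character_
    fin <- which(is.finite(out$icer) & out$status == "nondominated")
    if (length(fin)) out$verdict[fin] <- classify_icer(out$icer[fin], gdp, wtp_multipliers)
  }
  structure(out, class = c("cea_table", class(out)))
}

#' Classify an ICER against a GDP-based willingness-to-pay threshold
#'
#' Applies the WHO rule of thumb for settings without an explicit threshold:
#' an intervention is *highly cost-effective* below 1x GDP per capita per
#' QALY, *cost-effective* from 1x up to (but excluding) 3x, and *not
#' cost-effective* at 3x or above.
#'
#' @param icer Finite ICER(s), PPP $ per QALY.
#' @param gdp GDP per capita (PPP $).
#' @param wtp_multipliers Lower and upper threshold multipliers, default `c(1, 3)`.
#' @return Character vector: `"highly_cost_effective"`, `"cost_effective"`,
#'   or `"not_cost_effective"`.
#' @examples
#' classify_icer(13420.09, gdp = 12547)
#' @export
classify_icer <- function(icer, gdp, wtp_multipliers = c(1, 3)) {
  if (any(!is.finite(icer))) abort("`icer` must be finite.")
  dplyr::case_when(
    icer < wtp_multipliers[1] * gdp ~ "highly_cost_effective",
    icer < wtp_multipliers[2] * gdp ~ "cost_effective",
    TRUE ~ "not_cost_effective"
  )
}
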