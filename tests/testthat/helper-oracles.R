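# Independent brute-force oracles. These deliberately avoid the package's
# own computation paths: matrix powers by repeated multiplication, frontier
# membership by convex-combination enumeration, CEAC/acceptance by plain
# per-draw loops.

states5 <- c("Remission", "Low", "Moderate", "Severe", "Death")

# random row-stochastic 5x5 matrix with absorbing Death
random_transition_matrix <- function() {
  m <- matrix(stats::runif(25), 5, 5)
  m <- m / rowSums(m)
  m[5, ] <- c(0, 0, 0, 0, 1)
  dimnames(m) <- list(states5, states5)
  m
}

mat_pow <- function(m, k) {
  out <- diag(nrow(m))
  for (i in seq_len(k)) out <- out %*% m
  out
}

# Frontier oracle: strategy i is dominated iff some other strategy, or some
# convex combination of two others, costs no more and yields at least as many
# QALYs, strictly better in one. The lambda-feasibility of a pair reduces to
# intersecting two half-lines with [0, 1].
oracle_frontier <- function(cost, qaly) {
  n <- length(cost)
  dominated_by_single <- function(i) {
    any(vapply(seq_len(n), function(j) {
      j != i && cost[j] <= cost[i] && qaly[j] >= qaly[i] &&
        (cost[j] < cost[i] || qaly[j] > qaly[i])
    }, logical(1)))
  }
  dominated_by_pair <- function(i) {
    others <- setdiff(seq_len(n), i)
    if (length(others) < 2) return(FALSE)
    pairs <- utils::combn(others, 2)
    for (p in seq_len(ncol(pairs))) {
      j <- pairs[1, p]; k <- pairs[2, p]
      lo <- 0; hi <- 1
      a <- qaly[j] - qaly[k]; b <- qaly[i] - qaly[k]
      if (a > 0) lo <- max(lo, b / a)
      else if (a < 0) hi <- min(hi, b / a)
      else if (b > 0) next
      cc <- cost[j] - cost[k]; d <- cost[i] - cost[k]
      if (cc > 0) hi <- min(hi, d / cc)
      else if (cc < 0) lo <- max(lo, d / cc)
      else if (d < 0) next
      if (lo > hi) next
      for (lam in unique(c(lo, (lo + hi) / 2, hi))) {
        cq <- lam * qaly[j] + (1 - lam) * qaly[k]
        cv <- lam * cost[j] + (1 - lam) * cost[k]
        if (cq >= qaly[i] && cv <= cost[i] && (cq > qaly[i] || cv < cost[i])) {
          return(TRUE)
        }
      }
    }
    FALSE
  }
  single <- vapply(seq_len(n), dominated_by_single, logical(1))
  pairwise <- vapply(seq_len(n), dominated_by_pair, logical(1))
  list(
    on_frontier = !(single | pairwise),
    absolutely = single,
    extendedly = !single & pairwise
  )
}

# plain-loop CEAC recount at one WTP
oracle_ceac_point <- function(psa_df, wtp) {
  strategies <- sort(unique(psa_df$strategy))
  counts <- setNames(rep(0, length(strategies)), strategies)
  for (d in unique(psa_df$draw)) {
    sub <- psa_df[psa_df$draw == d, ]
    nmb <- sub$qaly * wtp - sub$cost
    win <- which(nmb == max(nmb))
    counts[sub$strategy[win]] <- counts[sub$strategy[win]] + 1 / length(win)
  }
  counts / length(unique(psa_df$draw))
}

oracle_acceptance <- function(psa_df, a, b, wtp) {
  sa <- psa_df[psa_df$strategy == a, ]
  sb <- psa_df[psa_df$strategy == b, ]
  sa <- sa[order(sa$draw), ]; sb <- sb[order(sb$draw), ]
  mean((sa$qaly - sb$qaly) * wtp - (sa$cost - sb$cost) > 0)
}
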