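#' Generate a synthetic patient-level cohort
#'
#' Simulates the patient-level data structure the cost-utility analysis
#' assumes: per arm, each patient is assigned a DAS-28 outcome band from the
#' arm's categorical response distribution, an EQ-5D-style utility drawn from
#' the band's moment-matched beta distribution, and annual cost components
#' drawn from moment-matched gamma distributions (coefficient of variation
#' `cost_cv` on each component mean). A zero SD (or zero-mean cost) is a
#' degenerate point mass. All moment fits are checked before any sampling.
#'
#' @param params A [cea_params()] object; its `responses` table defines the
#'   band distribution and default arm sizes.
#' @param n_per_arm Optional common arm size; defaults to each arm's observed
#'   `n` (the sum of its response counts).
#' @param seed Integer RNG seed.
#' @param cost_cv Coefficient of variation for cost sampling, default 0.2.
#' @return A tibble with one row per patient: `arm`, `patient_id`,
#'   `das28_band` (living-state label), `utility`, and one column per cost
#'   component (PPP $ per year).
#' @examples
#' cohort <- generate_cohort(ra_biologics_params(), seed = 1)
#' nrow(cohort) # 53 + 48 + 53 patients
#' @export
generate_cohort <- function(params, n_per_arm = NULL, seed, cost_cv = 0.2) {
  stopifnot(inherits(params, "cea_params"))
  if (missing(seed)) abort("`seed` is required for a reproducible cohort.")
  if (!is.null(n_per_arm) && n_per_arm < 1) abort("`n_per_arm` must be positive.")
  check_psa_feasible(params)

  arms <- sort(unique(params$responses$strategy))
  withr::with_seed(seed, {
    purrr::map_dfr(arms, function(arm) {
      re <- dplyr::filter(params$responses, .data$strategy == arm)
      n <- if (is.null(n_per_arm)) sum(re$count) else as.integer(n_per_arm)
      if (sum(re$count) == 0) {
        abort(sprintf("arm '%s' has no response counts to define band proportions.", arm))
      }
      probs <- re$count / sum(re$count)
      bands <- sample(re$band, n, replace = TRUE, prob = probs)

      ut <- dplyr::filter(params$utilities, .data$strategy == arm)
      utility <- numeric(n)
      for (b in cea_living_states()) {
        idx <- which(bands == b)
        if (!length(idx)) next
        i <- match(b, ut$state)
        m <- ut$mean[i]; sdev <- ut$sd[i]
        utility[idx] <- if (sdev == 0) m else {
          sh <- beta_params_from_moments(m, sdev)
          rbeta(length(idx), sh$alpha, sh$beta)
        }
      }

      co <- dplyr::filter(params$costs, .data$strategy == arm) |>
        dplyr::arrange(.data$component)
      cost_cols <- purrr::map(co$annual_cost, function(m) {
        sdev <- cost_cv * m
        if (m == 0 || sdev == 0) return(rep(m, n))
        sh <- gamma_params_from_moments(m, sdev)
        rgamma(n, shape = sh$shape, rate = sh$rate)
      })
      names(cost_cols) <- co$component

      dplyr::bind_cols(
        tibble(arm = arm, patient_id = seq_len(n),
               das28_band = unname(bands), utility = unname(utility)),
        as_tibble(cost_cols)
      )
    })
  })
}

#' Summarise one arm of patient records
#'
#' Reduces patient-level records to the arm-level statistics the model
#' consumes: band counts and percentages (2 decimals), per-band utility mean
#' and sample SD (`n - 1` denominator; a single-patient band reports SD 0
#' with a degenerate flag), cost component means with within-category shares,
#' and category totals (DMC + DNMC + IC = total).
#'
#' @param records A patient tibble from [generate_cohort()] (or the same
#'   shape read from CSV).
#' @param arm Arm name to summarise.
#' @return A `cea_arm_summary` list: `arm`, `n`, `bands` (band, count,
#'   percent, utility_mean, utility_sd, degenerate), `costs` (component,
#'   category, mean, share), `totals` (category, total).
#' @export
summarize_arm <- function(records, arm) {
  df <- dplyr::filter(as_tibble(records), .data$arm == !!arm)
  if (!nrow(df)) abort(sprintf("no records for arm '%s'.", arm))
  n <- nrow(df)
  living <- cea_living_states()
  bad_bands <- setdiff(unique(df$das28_band), living)
  if (length(bad_bands)) {
    abort(sprintf("unknown DAS-28 band(s): %s", paste(bad_bands, collapse = ", ")))
  }

  bands <- purrr::map_dfr(living, function(b) {
    u <- df$utility[df$das28_band == b]
    k <- length(u)
    tibble(
      band = b, count = k,
      percent = round(100 * k / n, 2),
      utility_mean = if (k) mean(u) else NA_real_,
      utility_sd = if (k >= 2) sd(u) else if (k == 1) 0 else NA_real_,
      degenerate = k == 1
    )
  })

  comp_cat <- cea_cost_components()
  comps <- intersect(names(comp_cat), names(df))
  cost_means <- vapply(comps, function(cmp) mean(df[[cmp]]), numeric(1))
  costs <- tibble(
    component = comps, category = unname(comp_cat[comps]),
    mean = unname(cost_means)
  )
  costs <- dplyr::group_by(costs, .data$category) |>
    dplyr::mutate(share = round(100 * .data$mean / sum(.data$mean), 2)) |>
    dplyr::ungroup()

  cat_totals <- dplyr::group_by(costs, .data$category) |>
    dplyr::summarise(total = sum(.data$mean), .groups = "drop")
  totals <- dplyr::bind_rows(
    cat_totals,
    tibble(category = "total", total = sum(cat_totals$total))
  )

  structure(
    list(arm = arm, n = n, bands = bands, costs = costs, totals = totals),
    class = "cea_arm_summary"
  )
}

#' @export
print.cea_arm_summary <- function(x, ...) {
  cat(sprintf("<cea_arm_summary> %s (n = %d)\n", x$arm, x$n))
  print(x$bands)
  print(x$totals)
  invisible(x)
}

#' Recover generating parameters from patient records
#'
#' Estimates, per arm, the band proportions, per-band utility mean and SD,
#' and cost component means from patient-level records — the
#' generate-then-estimate loop that checks the whole pipeline's consistency.
#' Bands with fewer than `min_n` patients are flagged (`ok = FALSE`, SD
#' `NA`) rather than silently imputed.
#'
#' @param records A patient tibble from [generate_cohort()].
#' @param min_n Minimum patients per (arm, band) for an SD estimate, default 2.
#' @return A `cea_recovered` list of tibbles: `responses` (strategy, band,
#'   count, prop), `utilities` (strategy, state, mean, sd, n, ok), `costs`
#'   (strategy, component, annual_cost).
#' @export
recover_parameters <- function(records, min_n = 2) {
  df <- as_tibble(records)
  arms <- sort(unique(df$arm))
  living <- cea_living_states()
  comp_cat <- cea_cost_components()
  comps <- intersect(names(comp_cat), names(df))

  responses <- purrr::map_dfr(arms, function(a) {
    sub <- df[df$arm == a, ]
    counts <- vapply(living, function(b) sum(sub$das28_band == b), integer(1))
    tibble(strategy = a, band = living, count = unname(counts),
           prop = unname(counts) / nrow(sub))
  })
  utilities <- purrr::map_dfr(arms, function(a) {
    sub <- df[df$arm == a, ]
    purrr::map_dfr(living, function(b) {
      u <- sub$utility[sub$das28_band == b]
      k <- length(u)
      tibble(
        strategy = a, state = b,
        mean = if (k) mean(u) else NA_real_,
        sd = if (k >= min_n) sd(u) else NA_real_,
        n = k, ok = k >= min_n
      )
    })
  })
  costs <- purrr::map_dfr(arms, function(a) {
    sub <- df[df$arm == a, ]
    tibble(
      strategy = a, component = comps,
      annual_cost = unname(vapply(comps, function(cmp) mean(sub[[cmp]]), numeric(1)))
    )
  })

  structure(list(responses = responses, utilities = utilities, costs = costs),
            class = "cea_recovered")
}
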