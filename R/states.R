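#' Model health states and DAS-28 bands
#'
#' The cohort model tracks five mutually exclusive health states: four living
#' states defined by bands of the 28-joint Disease Activity Score (DAS-28) and
#' an absorbing Death state. The band boundaries are the standard clinical
#' cut-points: remission below 2.6, low activity 2.6-3.2, moderate 3.2-5.1,
#' severe above 5.1 (the usual threshold for starting a biologic).
#'
#' @return `health_states()` returns a tibble with one row per state and
#'   columns `state` (label), `das28_band` (interval as text, `"n/a"` for
#'   Death), and `living` (logical).
#' @examples
#' health_states()
#' @export
health_states <- function() {
  tibble(
    state = cea_states(),
    das28_band = c("< 2.6", "2.6 - 3.2", "3.2 - 5.1", "> 5.1", "n/a"),
    living = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
}

# canonical state order used by every matrix / vector in the package
cea_states <- function() c("Remission", "Low", "Moderate", "Severe", "Death")

cea_living_states <- function() cea_states()[1:4]

# cost components and their societal-perspective category
# DMC: direct medical; DNMC: direct nonmedical; IC: indirect (productivity loss)
cea_cost_components <- function() {
  c(
    visits = "DMC", medication = "DMC", tests = "DMC",
    physiotherapy_other = "DMC", diagnostics = "DMC", injection = "DMC",
    transportation = "DNMC", accommodation = "DNMC", meals = "DNMC",
    lost_revenue = "IC"
  )
}
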