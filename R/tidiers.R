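#' Tidy and glance methods
#'
#' broom-style accessors for the package's result objects: `tidy()` returns
#' the result as a plain tibble (one row per strategy, parameter, draw, or
#' band), `glance()` a one-row summary of the run.
#'
#' @param x A `cea_eval`, `cea_table`, `cea_owsa`, `cea_psa`, `cea_ceac`, or
#'   `cea_arm_summary` object.
#' @param ... Unused.
#' @return A tibble.
#' @name markovcea-tidiers
NULL

strip_cea_class <- function(x) {
  class(x) <- setdiff(class(x), c("cea_eval", "cea_table", "cea_owsa",
                                  "cea_psa", "cea_ceac", "cea_trace"))
  attr(x, "trace") <- NULL
  attr(x, "params") <- NULL
  attr(x, "base") <- NULL
  as_tibble(x)
}

#' @rdname markovcea-tidiers
#' @method tidy cea_eval
#' @export
tidy.cea_eval <- function(x, ...) strip_cea_class(x)

#' @rdname markovcea-tidiers
#' @method glance cea_eval
#' @export
glance.cea_eval <- function(x, ...) {
  trace <- attr(x, "trace")
  tibble(
    n_strategies = nrow(x),
    n_cycles = max(trace$cycle),
    best_qaly = x$strategy[which.max(x$qaly)],
    cheapest = x$strategy[which.min(x$cost)]
  )
}

#' @rdname markovcea-tidiers
#' @method tidy cea_table
#' @export
tidy.cea_table <- function(x, ...) strip_cea_class(x)

#' @rdname markovcea-tidiers
#' @method tidy cea_owsa
#' @export
tidy.cea_owsa <- function(x, ...) strip_cea_class(x)

#' @rdname markovcea-tidiers
#' @method glance cea_owsa
#' @export
glance.cea_owsa <- function(x, ...) {
  tibble(
    strategy = attr(x, "strategy"),
    comparator = attr(x, "comparator"),
    rel_change = attr(x, "rel_change"),
    base_icer = x$base_icer[1],
    n_parameters = nrow(x),
    widest = x$parameter[1]
  )
}

#' @rdname markovcea-tidiers
#' @method tidy cea_psa
#' @export
tidy.cea_psa <- function(x, ...) strip_cea_class(x)

#' @rdname markovcea-tidiers
#' @method glance cea_psa
#' @export
glance.cea_psa <- function(x, ...) {
  dplyr::group_by(strip_cea_class(x), .data$strategy) |>
    dplyr::summarise(mean_cost = mean(.data$cost), mean_qaly = mean(.data$qaly),
                     .groups = "drop") |>
    dplyr::mutate(n_draws = attr(x, "n_draws"), seed = attr(x, "seed"),
                  cost_cv = attr(x, "cost_cv"))
}

#' @rdname markovcea-tidiers
#' @method tidy cea_ceac
#' @export
tidy.cea_ceac <- function(x, ...) strip_cea_class(x)

#' @rdname markovcea-tidiers
#' @method tidy cea_arm_summary
#' @export
tidy.cea_arm_summary <- function(x, ...) {
  dplyr::mutate(x$bands, arm = x$arm, n = x$n, .before = 1)
}

#' @rdname markovcea-tidiers
#' @method glance cea_arm_summary
#' @export
glance.cea_arm_summary <- function(x, ...) {
  tot <- setNames(x$totals$total, x$totals$category)
  tibble(
    arm = x$arm, n = x$n,
    dmc = unname(tot["DMC"]), dnmc = unname(tot["DNMC"]), ic = unname(tot["IC"]),
    total_cost = unname(tot["total"])
  )
}
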