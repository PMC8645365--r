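#' Beta distribution parameters from a mean and SD
#'
#' Method-of-moments fit for quantities bounded on \[0, 1\] (utilities):
#' with `nu = mean * (1 - mean) / sd^2 - 1`, the shapes are
#' `alpha = mean * nu` and `beta = (1 - mean) * nu`. The fit is exact: a
#' Beta(alpha, beta) has precisely the requested mean and SD. Feasibility
#' requires `sd^2 < mean * (1 - mean)`; an SD at or beyond that bound has no
#' beta representation and must be shrunk by the caller.
#'
#' @param mean Mean(s) strictly inside (0, 1).
#' @param sd Standard deviation(s), strictly positive.
#' @return Tibble with columns `alpha`, `beta`.
#' @examples
#' beta_params_from_moments(0.836, 0.196)
#' @export
beta_params_from_moments <- function(mean, sd) {
  if (any(mean <= 0 | mean >= 1)) {
    abort("`mean` must lie strictly inside (0, 1) for a beta fit.")
  }
  if (any(sd <= 0)) abort("`sd` must be strictly positive.")
  bad <- sd^2 >= mean * (1 - mean)
  if (any(bad)) {
    abort(sprintf(
      "infeasible beta moments (sd^2 >= mean*(1-mean)) at mean = %.4g, sd = %.4g: shrink the SD below %.4g.",
      mean[bad][1], sd[bad][1], sqrt((mean * (1 - mean))[bad][1])
    ))
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  tibble(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Gamma distribution parameters from a mean and SD
#'
#' Method-of-moments fit for nonnegative quantities (costs):
#' `shape = mean^2 / sd^2`, `rate = mean / sd^2`. The fit reproduces the
#' requested mean and SD exactly.
#'
#' @param mean Mean(s), strictly positive.
#' @param sd Standard deviation(s), strictly positive.
#' @return Tibble with columns `shape`, `rate`.
#' @examples
#' gamma_params_from_moments(100, 10)
#' @export
gamma_params_from_moments <- function(mean, sd) {
  if (any(mean <= 0) || any(sd <= 0)) {
    abort("`mean` and `sd` must be strictly positive for a gamma fit.")
  }
  tibble(shape = mean^2 / sd^2, rate = mean / sd^2)
}

# sd cap for a feasible beta at a given mean; used to shrink perturbed SDs
beta_feasible_sd <- function(mean) sqrt(mean * (1 - mean))
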