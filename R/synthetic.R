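#' Specification of a synthetic declining-population scenario
#'
#' The generator produces yearly abundances from a piecewise-linear mean
#' trend with additive Gaussian noise, floored at zero:
#' `N_t = max(0, trend(t) + e_t)`, `e_t ~ Normal(0, noise_sd)`, where
#' `trend(t)` declines at `slope` per year and, if `recovery_year` is set,
#' flips to the opposite (positive) slope from that year on.  This emulates
#' the two regimes seen in real single-population declines: consistent,
#' near-deterministic declines, and noisy declines with transient or
#' sustained increases.
#'
#' @param N0 Initial abundance (individuals), positive.
#' @param slope Trend slope (individuals/year), usually negative.
#' @param noise_sd Standard deviation of additive yearly noise, >= 0.
#' @param n_years Number of yearly observations, >= 3.
#' @param recovery_year Optional 0-based year index after which the trend
#'   slope flips sign (`NULL` for none).
#' @param seed Integer RNG seed making the series reproducible.
#' @param start_year First calendar year (default 2000).
#' @return An object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(N0, slope, noise_sd = 0, n_years = 15L,
                          recovery_year = NULL, seed = 1L,
                          start_year = 2000L) {
  stopifnot(is.numeric(N0), N0 > 0, is.numeric(slope),
            is.numeric(noise_sd), noise_sd >= 0, n_years >= 3)
  if (!is.null(recovery_year))
    stopifnot(recovery_year >= 1, recovery_year < n_years)
  structure(list(N0 = N0, slope = slope, noise_sd = noise_sd,
                 n_years = as.integer(n_years),
                 recovery_year = if (is.null(recovery_year)) NULL else
                   as.integer(recovery_year),
                 seed = as.integer(seed),
                 start_year = as.integer(start_year)),
            class = "scenario_spec")
}

#' Generate a synthetic abundance series
#'
#' Draws the series described by a [scenario_spec()].  The global RNG state
#' is saved and restored, so the generator is reproducible per seed and
#' does not disturb the caller's random stream.
#'
#' @param spec A [scenario_spec()].
#' @return An [abundance_series()] of length `spec$n_years`.
#' @examples
#' generate_series(scenario_spec(N0 = 100, slope = -5, noise_sd = 2, seed = 7))
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  t <- 0:(spec$n_years - 1L)
  if (is.null(spec$recovery_year)) {
    trend <- spec$N0 + spec$slope * t
  } else {
    tr <- spec$recovery_year
    trend <- spec$N0 + spec$slope * pmin(t, tr) - spec$slope * pmax(0, t - tr)
  }
  eps <- with_local_seed(spec$seed,
                         stats::rnorm(spec$n_years, 0, spec$noise_sd))
  abundance_series(spec$start_year + t, pmax(0, trend + eps))
}

#' Built-in synthetic scenarios spanning the observed decline regimes
#'
#' Four named [scenario_spec()]s shaped like the canonical case-study
#' regimes:
#' \describe{
#'   \item{`steady`}{long, consistent, low-noise decline (porpoise-like).}
#'   \item{`steady_to_zero`}{shorter consistent decline that reaches zero
#'     (insectivorous-bat-like).}
#'   \item{`noisy_upturn`}{noisy decline with a sustained late recovery
#'     (wombat-like).}
#'   \item{`noisy_shallow`}{shallow decline with large year-to-year
#'     variation (turtle-like).}
#' }
#'
#' @return Named list of `"scenario_spec"` objects.
#' @export
builtin_fixtures <- function() {
  list(
    steady = scenario_spec(N0 = 600, slope = -22, noise_sd = 10,
                           n_years = 25L, seed = 101L, start_year = 1993L),
    steady_to_zero = scenario_spec(N0 = 120, slope = -8, noise_sd = 4,
                                   n_years = 16L, seed = 102L,
                                   start_year = 1994L),
    noisy_upturn = scenario_spec(N0 = 230, slope = -15, noise_sd = 12,
                                 n_years = 20L, recovery_year = 5L,
                                 seed = 103L, start_year = 1980L),
    noisy_shallow = scenario_spec(N0 = 160, slope = -6, noise_sd = 20,
                                  n_years = 18L, seed = 104L,
                                  start_year = 1975L)
  )
}

#' Generate one of the built-in scenarios by name
#'
#' @param name One of `"steady"`, `"steady_to_zero"`, `"noisy_upturn"`,
#'   `"noisy_shallow"`.
#' @return An [abundance_series()].
#' @export
builtin_series <- function(name) {
  fx <- builtin_fixtures()
  if (!name %in% names(fx))
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(names(fx), collapse = ", ")), call. = FALSE)
  generate_series(fx[[name]])
}

# Run expr with a temporary RNG seed, restoring the caller's stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
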