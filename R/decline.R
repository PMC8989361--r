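#' Fit a linear decline model to an abundance series
#'
#' Ordinary least-squares regression of abundance on time.  The fitted slope
#' `r` (individuals per year) carries its standard OLS sampling uncertainty,
#' which downstream steps treat as the decline-rate distribution `p(r)`.
#' Variation around the fitted line is attributed to environmental and
#' demographic stochasticity, not observation error, so the last observed
#' abundance is taken at face value as the reference abundance `N(t0)` from
#' which future decline is extrapolated (set `reference = "fitted"` to use
#' the regression prediction at the last year instead, which can be
#' preferable for very noisy series).
#'
#' @param series An [abundance_series()] with at least 3 observations.
#' @param slope_dist Sampling distribution assumed for the slope:
#'   `"normal"` (default; Gaussian error assumption) or `"t"` (Student-t
#'   with `n - 2` degrees of freedom, the small-sample OLS distribution).
#' @param reference How to set the reference abundance `N(t0)`:
#'   `"last_observed"` (default) or `"fitted"`.
#'
#' @return An object of class `"decline_model"` with elements `slope_mean`,
#'   `slope_se`, `intercept` (fitted abundance at the first observed year),
#'   `n_obs`, `N0`, `reference_year`, `residual_sd`, `slope_dist`, `df`.
#' @examples
#' s <- abundance_series(2000:2008, 100 - 5 * (0:8))
#' fit_decline(s)
#' @export
fit_decline <- function(series,
                        slope_dist = c("normal", "t"),
                        reference = c("last_observed", "fitted")) {
  stopifnot(inherits(series, "abundance_series"))
  slope_dist <- match.arg(slope_dist)
  reference <- match.arg(reference)
  n <- nrow(series)
  if (n < 3L)
    stop("insufficient data: at least 3 observations are required to fit",
         call. = FALSE)
  t_rel <- series$year - series$year[1L]
  if (stats::var(t_rel) == 0)
    stop("degenerate design: no variation in years", call. = FALSE)
  fit <- stats::lm(series$abundance ~ t_rel)
  sm <- suppressWarnings(summary(fit))  # "essentially perfect fit" is fine here
  co <- sm$coefficients
  # a perfect line gives residual variance ~0 up to rounding; clamp the se
  slope_se <- unname(co["t_rel", "Std. Error"])
  if (sm$sigma < 1e-10) slope_se <- 0
  N0 <- if (reference == "last_observed") {
    series$abundance[n]
  } else {
    max(0, unname(stats::predict(fit)[n]))
  }
  structure(list(
    slope_mean = unname(co["t_rel", "Estimate"]),
    slope_se = slope_se,
    intercept = unname(co["(Intercept)", "Estimate"]),
    n_obs = n,
    N0 = N0,
    reference_year = series$year[n],
    residual_sd = if (sm$sigma < 1e-10) 0 else sm$sigma,
    slope_dist = slope_dist,
    df = n - 2L
  ), class = "decline_model")
}

#' @export
print.decline_model <- function(x, ...) {
  cat("Linear decline model (OLS)\n")
  cat(sprintf("  slope r      : %.4g +/- %.4g individuals/year (%s)\n",
              x$slope_mean, x$slope_se, x$slope_dist))
  cat(sprintf("  reference N0 : %.4g individuals at year %d\n",
              x$N0, x$reference_year))
  cat(sprintf("  n = %d observations, residual sd %.4g\n",
              x$n_obs, x$residual_sd))
  invisible(x)
}

# Quantile of the slope sampling distribution at probability p.
slope_quantile <- function(model, p) {
  if (model$slope_se == 0) return(rep(model$slope_mean, length(p)))
  if (model$slope_dist == "t") {
    model$slope_mean + model$slope_se * stats::qt(p, df = model$df)
  } else {
    stats::qnorm(p, mean = model$slope_mean, sd = model$slope_se)
  }
}

#' Two-sided confidence interval for the decline rate
#'
#' Standard OLS interval, `slope_mean +/- t(df) * slope_se`.
#'
#' @param model A [fit_decline()] result.
#' @param level Coverage probability (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
slope_confint <- function(model, level = 0.95) {
  stopifnot(inherits(model, "decline_model"), level > 0, level < 1)
  half <- stats::qt(1 - (1 - level) / 2, df = model$df) * model$slope_se
  c(lower = model$slope_mean - half, upper = model$slope_mean + half)
}

#' Discretize the decline-rate distribution
#'
#' Places `n_nodes` rate values at the equal-probability mid-quantiles
#' `(k - 1/2)/n_nodes` of the slope sampling distribution, each with weight
#' `1/n_nodes`.  This deterministic quadrature replaces the integrals over
#' `p(r)` in the expected-abundance and terminal-value computations,
#' avoiding Monte-Carlo noise.
#'
#' @param model A [fit_decline()] result.
#' @param n_nodes Number of nodes (default 201); `n_nodes = 1` gives a
#'   point mass at the mean slope.
#' @return An object of class `"rate_distribution"`: list with sorted
#'   `nodes` (individuals/year) and `weights` summing to 1.
#' @export
rate_distribution <- function(model, n_nodes = 201L) {
  stopifnot(inherits(model, "decline_model"))
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 1L) stop("n_nodes must be >= 1", call. = FALSE)
  if (model$slope_se == 0 || n_nodes == 1L) {
    nodes <- model$slope_mean
    weights <- 1
    if (n_nodes > 1L && model$slope_se == 0) {
      nodes <- rep(model$slope_mean, n_nodes)
      weights <- rep(1 / n_nodes, n_nodes)
    }
  } else {
    p <- (seq_len(n_nodes) - 0.5) / n_nodes
    nodes <- slope_quantile(model, p)
    weights <- rep(1 / n_nodes, n_nodes)
  }
  structure(list(nodes = nodes, weights = weights),
            class = "rate_distribution")
}

# Point-mass rate distribution at a single rate (used by tests and the
# calibration identity).
point_rate <- function(r) {
  structure(list(nodes = r, weights = 1), class = "rate_distribution")
}

#' Point-mass decline-rate distribution
#'
#' Convenience constructor for a degenerate `p(r)` concentrated at one
#' decline rate, useful for deterministic analyses.
#'
#' @param r Decline rate (individuals/year).
#' @return A `"rate_distribution"` with a single node of weight 1.
#' @examples
#' rate_point_mass(-5)
#' @export
rate_point_mass <- function(r) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r))
  point_rate(r)
}

#' Forecast the extinction-time distribution and decision horizon
#'
#' Extrapolates each discretized decline rate `r < 0` forward from the
#' reference abundance: the first-crossing (extinction) year is
#' `t_E = ceiling(N0 / |r|)`, the first whole year at which
#' `N0 + r t <= 0`.  Node weights aggregated by `t_E` give the yearly
#' extinction-probability mass; rates `r >= 0` never cross zero and
#' contribute to the residual mass beyond the horizon.  The decision
#' horizon `tau` is the smallest year whose cumulative extinction mass
#' reaches `percentile`, beyond which extinction is treated as certain
#' (the dynamic program needs a finite horizon).  When the percentile is
#' unreachable (too much mass on non-declining rates) `tau` is set to
#' `cap` with a warning.
#'
#' @param model A [fit_decline()] result.
#' @param percentile Probability level defining the horizon (default 0.99,
#'   the upper 99th percentile of the extinction-time distribution).
#' @param cap Maximum allowed horizon in years.  Default `NULL` means
#'   `max(5 * observed span, 100)`.
#' @param n_nodes Number of rate nodes used for the discretization.
#' @return An object of class `"extinction_forecast"`: list with `tau`
#'   (years), `yearly_mass` (probability of first crossing in each year
#'   `1..tau`), `mass_beyond` (residual probability of no extinction by
#'   `tau`), `already_extinct` flag, and the `cap` used.
#' @export
extinction_forecast <- function(model, percentile = 0.99, cap = NULL,
                                n_nodes = 201L) {
  stopifnot(inherits(model, "decline_model"))
  if (!(percentile > 0 && percentile < 1))
    stop("percentile must be strictly between 0 and 1", call. = FALSE)
  if (is.null(cap)) cap <- max(5L * (model$n_obs - 1L), 100L)
  cap <- as.integer(cap)
  if (model$N0 <= 0) {
    return(structure(list(tau = 0L, yearly_mass = numeric(0), mass_beyond = 0,
                          already_extinct = TRUE, cap = cap),
                     class = "extinction_forecast"))
  }
  rd <- rate_distribution(model, n_nodes)
  declining <- rd$nodes < 0
  t_E <- rep(Inf, length(rd$nodes))
  t_E[declining] <- ceiling(model$N0 / abs(rd$nodes[declining]))
  # mass by extinction year over all finite crossing times
  max_year <- if (any(is.finite(t_E))) max(t_E[is.finite(t_E)]) else 0
  full_mass <- numeric(min(max_year, cap))
  beyond <- sum(rd$weights[!is.finite(t_E) | t_E > cap])
  finite_in <- is.finite(t_E) & t_E <= cap
  if (any(finite_in)) {
    agg <- tapply(rd$weights[finite_in], t_E[finite_in], sum)
    full_mass[as.integer(names(agg))] <- agg
  }
  cum <- cumsum(full_mass)
  reach <- which(cum >= percentile - 1e-12)
  if (length(reach) == 0L) {
    tau <- cap
    warning(sprintf(
      "no extinction within horizon cap: cumulative extinction probability %.3f < %.3f by year %d; using tau = %d",
      if (length(cum)) cum[length(cum)] else 0, percentile, cap, cap),
      call. = FALSE)
  } else {
    tau <- reach[1L]
  }
  yearly_mass <- if (tau >= 1L) {
    c(full_mass, numeric(max(0, tau - length(full_mass))))[seq_len(tau)]
  } else numeric(0)
  structure(list(tau = as.integer(tau), yearly_mass = yearly_mass,
                 mass_beyond = 1 - sum(yearly_mass),
                 already_extinct = FALSE, cap = cap),
            class = "extinction_forecast")
}

#' @export
print.extinction_forecast <- function(x, ...) {
  if (x$already_extinct) {
    cat("Extinction forecast: population already extinct (tau = 0)\n")
    return(invisible(x))
  }
  cat(sprintf("Extinction forecast: horizon tau = %d years\n", x$tau))
  cat(sprintf("  P(extinct by tau) = %.4f, residual mass beyond = %.4f\n",
              sum(x$yearly_mass), x$mass_beyond))
  mode_y <- which.max(x$yearly_mass)
  if (length(mode_y))
    cat(sprintf("  modal extinction year: %d (mass %.4f)\n",
                mode_y, x$yearly_mass[mode_y]))
  invisible(x)
}

#' Confidence band for the projected abundance trajectory
#'
#' For each future year `t = 1..horizon`, the interval between the
#' `(1 - level)/2` and `(1 + level)/2` quantiles of `N0 + r t` under the
#' slope sampling distribution, floored at 0.
#'
#' @param model A [fit_decline()] result.
#' @param horizon Number of future years.
#' @param level Interval coverage (default 0.95).
#' @return Data frame with columns `year_ahead`, `year`, `lower`, `fit`,
#'   `upper`.
#' @export
forecast_band <- function(model, horizon, level = 0.95) {
  stopifnot(inherits(model, "decline_model"))
  if (!(level > 0 && level < 1))
    stop("level must be strictly between 0 and 1", call. = FALSE)
  horizon <- as.integer(horizon)
  stopifnot(horizon >= 1L)
  t_ahead <- seq_len(horizon)
  lo_q <- slope_quantile(model, (1 - level) / 2)
  hi_q <- slope_quantile(model, (1 + level) / 2)
  data.frame(
    year_ahead = t_ahead,
    year = model$reference_year + t_ahead,
    lower = pmax(0, model$N0 + lo_q * t_ahead),
    fit = pmax(0, model$N0 + model$slope_mean * t_ahead),
    upper = pmax(0, model$N0 + hi_q * t_ahead)
  )
}
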