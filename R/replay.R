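#' Receding-horizon replay: locate the recommended trigger year
#'
#' Simulates a decision-maker who starts in situ management in the first
#' observed year and, each subsequent year, re-analyses the data gathered
#' so far: re-fit the decline, rebuild the extinction forecast and decision
#' model, re-solve the dynamic program, and read off the optimal action for
#' the current state.  Decisions begin once the minimum fitting window
#' (`config$fit_window`, default 3 observations) is available.  Every
#' pre-trigger management year counts as one in situ failure, so at the
#' j-th observation the belief state is `{n_u, 0, 0}` with `n_u = j - 1`,
#' queried at stage `n_u`.  The replay stops at the first year whose
#' recommendation is `ex_situ` (the trigger year), or when the observed
#' abundance reaches zero (extinction; the trigger is `"never"`), or at the
#' end of the series.
#'
#' When the yearly forecast horizon `tau` does not exceed the elapsed
#' failure count (late in a long decline), the decision model for that year
#' is built with horizon `n_u + 1` so the current state exists in the state
#' space.
#'
#' @param series An [abundance_series()].
#' @param params A [value_params()], or `NULL` to take `w1`, `w2`, `px`
#'   from `config`.
#' @param config A [run_config()].
#' @return An object of class `"trigger_result"`: list with `trigger_year`
#'   (calendar year, `NA` if never), `outcome` (`"triggered"`, `"extinct"`
#'   or `"end_of_series"`), `n_failures_at_trigger`, `extinction_year`,
#'   `yearly_log` (one row per decision year: fitted slope and se, horizon
#'   `tau`, expected success probability, reference abundance, recommended
#'   action and current-state value), `forecast_band` (95% interval of
#'   predicted abundance from the last analysis), `w1_used`, `params`, and
#'   `config`.
#' @examples
#' res <- replay(builtin_series("steady"))
#' res$trigger_year
#' @export
replay <- function(series, params = NULL, config = run_config()) {
  stopifnot(inherits(series, "abundance_series"),
            inherits(config, "run_config"))
  if (is.null(params)) params <- config_value_params(config)
  stopifnot(inherits(params, "value_params"))
  n <- nrow(series)
  if (n < config$fit_window)
    stop("insufficient data: series shorter than the fitting window",
         call. = FALSE)
  w1 <- if (is.null(params$w1)) calibrate_w1(series$abundance[1L]) else
    params$w1
  eff_params <- value_params(w1, params$w2, params$px)

  log_rows <- list()
  trigger_year <- NA_integer_
  n_fail_at_trigger <- NA_integer_
  extinction_year <- NA_integer_
  outcome <- "end_of_series"
  last_model <- NULL
  last_tau <- NA_integer_

  for (j in seq_len(n)) {
    if (series$abundance[j] <= 0) {
      extinction_year <- series$year[j]
      outcome <- "extinct"
      break
    }
    if (j < config$fit_window) next

    model <- fit_decline(series[seq_len(j)], slope_dist = config$slope_dist,
                         reference = config$reference)
    fc <- suppressWarnings(
      extinction_forecast(model, percentile = config$horizon_percentile,
                          cap = config$horizon_cap,
                          n_nodes = config$n_rate_nodes))
    if (fc$already_extinct) {
      extinction_year <- series$year[j]
      outcome <- "extinct"
      break
    }
    n_u <- j - 1L
    H <- max(fc$tau, n_u + 1L)
    rates <- rate_distribution(model, config$n_rate_nodes)
    T_s <- in_situ_matrix(H, config$belief_variant)
    T_e <- ex_situ_matrix(H, eff_params$px)
    term <- terminal_values(H, rates, model$N0, eff_params,
                            clamp = config$clamp)
    pol <- solve_sdp(T_s, T_e, term, H)
    i_now <- state_index(n_u, 0L, 0L)
    act <- pol$action[n_u + 1L, i_now]
    val <- pol$V[n_u + 1L, i_now]
    last_model <- model
    last_tau <- fc$tau

    log_rows[[length(log_rows) + 1L]] <- data.frame(
      year = series$year[j], n_obs = j, n_u = n_u,
      slope = model$slope_mean, slope_se = model$slope_se,
      N0 = model$N0, tau = fc$tau,
      expected_q = expected_success(n_u, config$belief_variant),
      action = act, value = val
    )
    if (config$verbosity >= 2L)
      message(sprintf("  year %d: slope %.3f +/- %.3f, tau %d, a* = %s",
                      series$year[j], model$slope_mean, model$slope_se,
                      fc$tau, act))

    if (act == "ex_situ") {
      trigger_year <- series$year[j]
      n_fail_at_trigger <- n_u
      outcome <- "triggered"
      break
    }
  }

  band <- if (!is.null(last_model))
    forecast_band(last_model, horizon = max(1L, last_tau), level = 0.95)
  else NULL

  structure(list(
    trigger_year = trigger_year,
    outcome = outcome,
    n_failures_at_trigger = n_fail_at_trigger,
    extinction_year = extinction_year,
    yearly_log = if (length(log_rows)) do.call(rbind, log_rows) else
      data.frame(),
    forecast_band = band,
    w1_used = w1,
    params = eff_params,
    config = config
  ), class = "trigger_result")
}

#' @export
print.trigger_result <- function(x, ...) {
  cat("Receding-horizon trigger analysis\n")
  if (x$outcome == "triggered") {
    cat(sprintf("  ex situ, in toto action recommended in %d (after %d unsuccessful in situ years)\n",
                x$trigger_year, x$n_failures_at_trigger))
  } else if (x$outcome == "extinct") {
    cat(sprintf("  trigger: never -- population reached zero in %d\n",
                x$extinction_year))
  } else {
    cat("  trigger: never within the observed series\n")
  }
  if (nrow(x$yearly_log)) {
    last <- x$yearly_log[nrow(x$yearly_log), ]
    cat(sprintf("  last analysis: slope %.3f +/- %.3f, horizon tau = %d, E[q] = %.3f\n",
                last$slope, last$slope_se, last$tau, last$expected_q))
  }
  cat(sprintf("  w1 = %.5g, w2 = %.4g, px = %.4g\n",
              x$w1_used, x$params$w2, x$params$px))
  invisible(x)
}

#' Sensitivity of the trigger year to a value-function parameter
#'
#' Repeats the full receding-horizon replay for each value in `values` of
#' one parameter (`w1`, `w2` or `px`), holding everything else fixed.
#'
#' @param series An [abundance_series()].
#' @param param One of `"w1"`, `"w2"`, `"px"`.
#' @param values Numeric grid of parameter values.
#' @param params Baseline [value_params()] (`NULL` = from `config`).
#' @param config A [run_config()].
#' @return Data frame with columns `param`, `value`, `trigger_year`
#'   (`NA` = never), `n_failures_at_trigger`, `outcome`.
#' @export
sensitivity_sweep <- function(series, param = c("w1", "w2", "px"), values,
                              params = NULL, config = run_config()) {
  param <- match.arg(param)
  stopifnot(is.numeric(values), length(values) >= 1L)
  if (is.null(params)) params <- config_value_params(config)
  rows <- lapply(values, function(v) {
    p <- params
    p[[param]] <- v
    p <- value_params(p$w1, p$w2, p$px)
    res <- replay(series, p, config)
    data.frame(param = param, value = v,
               trigger_year = res$trigger_year,
               n_failures_at_trigger = res$n_failures_at_trigger,
               outcome = res$outcome)
  })
  do.call(rbind, rows)
}
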