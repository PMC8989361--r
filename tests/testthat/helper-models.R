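# Hand-built model objects for tests that need exact control over the
# slope distribution, bypassing the OLS fit.

make_model <- function(slope, se, N0, n_obs = 10L, slope_dist = "normal",
                       ref_year = 2020L) {
  structure(list(
    slope_mean = slope, slope_se = se,
    intercept = N0 - slope * (n_obs - 1L),
    n_obs = as.integer(n_obs), N0 = N0, reference_year = ref_year,
    residual_sd = se * 10, slope_dist = slope_dist, df = n_obs - 2L
  ), class = "decline_model")
}

make_rates <- function(nodes, weights = rep(1 / length(nodes), length(nodes))) {
  structure(list(nodes = sort(nodes), weights = weights),
            class = "rate_distribution")
}

# Random small decision-model instance for oracle comparisons.
random_instance <- function(tau) {
  px <- runif(1)
  w2 <- runif(1, 0.3, 1)
  w1 <- runif(1, 0.005, 0.05)
  N0 <- runif(1, 20, 200)
  k <- sample(1:5, 1)
  rates <- make_rates(rnorm(k, mean = runif(1, -25, -2), sd = runif(1, 0, 8)))
  params <- value_params(w1 = w1, w2 = w2, px = px)
  list(
    T_s = in_situ_matrix(tau),
    T_e = ex_situ_matrix(tau, px),
    terminal = terminal_values(tau, rates, N0, params),
    tau = tau, px = px, w2 = w2
  )
}

quiet_cfg <- function(...) run_config(verbosity = 0L, ...)

trigger_rel <- function(res, start_year) {
  if (is.na(res$trigger_year)) Inf else res$trigger_year - start_year
}
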