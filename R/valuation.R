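#' Value-function parameters
#'
#' Three scalars shape the manager's utility.  `w1` (1/individuals) sets
#' how quickly larger populations deliver diminishing marginal benefit in
#' the saturating utility `1 - exp(-w1 N)`; the default calibration (used
#' when `w1 = NULL` and a series is available, see [replay()]) chooses
#' `w1 = ln(20)/N_pre` so that managers are 95% satisfied at the
#' pre-decline abundance `N_pre`.  `w2` in (0, 1] discounts states where
#' the species persists only ex situ, reflecting the preference for wild
#' populations (default 2/3).  `px` is the probability that an ex situ, in
#' toto capture succeeds (default 0.75, elicited rather than learned).
#'
#' @param w1 Satisfaction rate (1/individuals), positive, or `NULL` to
#'   request the 95%-satisfaction calibration from data.
#' @param w2 Ex situ preference discount in (0, 1].
#' @param px Ex situ success probability in \[0, 1\].
#' @return An object of class `"value_params"`.
#' @examples
#' value_params(w1 = log(20) / 100)
#' @export
value_params <- function(w1 = NULL, w2 = 2 / 3, px = 0.75) {
  if (!is.null(w1) && (!is.numeric(w1) || length(w1) != 1L || w1 <= 0))
    stop("w1 must be a positive scalar (or NULL for calibration)",
         call. = FALSE)
  if (!is.numeric(w2) || length(w2) != 1L || w2 <= 0 || w2 > 1)
    stop("w2 must be in (0, 1]", call. = FALSE)
  if (!is.numeric(px) || length(px) != 1L || px < 0 || px > 1)
    stop("invalid probability: px must be in [0, 1]", call. = FALSE)
  structure(list(w1 = w1, w2 = w2, px = px), class = "value_params")
}

#' @export
print.value_params <- function(x, ...) {
  cat(sprintf("Value parameters: w1 = %s, w2 = %.4g, px = %.4g\n",
              if (is.null(x$w1)) "calibrated (ln(20)/N_pre)" else
                sprintf("%.6g", x$w1), x$w2, x$px))
  invisible(x)
}

#' Expected abundance in a system state
#'
#' Linear extrapolation of the fitted decline: each state has elapsed time
#' `n_u + a_e + a_s` (success states are absorbing, so elapsed time equals
#' time-to-success), and the expected abundance is the rate-distribution
#' average of `N0 + r * elapsed`.  The result may be negative; valuation
#' floors it at zero.
#'
#' @param state A [system_state()].
#' @param rates A [rate_distribution()].
#' @param N0 Reference abundance (individuals) at the last observation.
#' @return Expected abundance (individuals), possibly negative.
#' @examples
#' expected_abundance(system_state(3, 0, 1), rate_point_mass(-10), 100)  # 60
#' @export
expected_abundance <- function(state, rates, N0) {
  stopifnot(inherits(state, "system_state"),
            inherits(rates, "rate_distribution"))
  elapsed <- state$n_u + state$a_e + state$a_s
  sum(rates$weights * (N0 + rates$nodes * elapsed))
}

#' Terminal value of a system state
#'
#' At the end of the horizon the fate of the species is known, and each
#' state is scored by a saturating function of its projected abundance,
#' discounted by `w2` if the population persists only ex situ:
#' `w2^a_e * E_r[ 1 - exp(-w1 * max(0, N0 + r * elapsed)) ]`.
#' With the default `clamp = "floor"`, per-rate-node abundances are floored
#' at zero inside the expectation, so trajectories that have crossed zero
#' contribute exactly 0, the natural species-lost anchor (`clamp = "raw"`
#' keeps the literal expression, which goes negative without bound on
#' extinct trajectories).  The complete-extinction sink `S_R` is always
#' worth exactly 0.
#'
#' @param state A [system_state()].
#' @param rates A [rate_distribution()].
#' @param N0 Reference abundance (individuals).
#' @param params A [value_params()] with explicit `w1`.
#' @param tau Horizon; needed only to recognise the sink `S_R = {tau,1,1}`.
#'   Default `NULL` skips the sink override.
#' @param clamp `"floor"` (default) or `"raw"`.
#' @return A value in \[0, 1\] (under `"floor"`).
#' @examples
#' p <- value_params(w1 = log(20) / 100)
#' terminal_value(system_state(0, 0, 1), rate_point_mass(0), 100, p)  # 0.95
#' @export
terminal_value <- function(state, rates, N0, params, tau = NULL,
                           clamp = c("floor", "raw")) {
  stopifnot(inherits(state, "system_state"),
            inherits(rates, "rate_distribution"),
            inherits(params, "value_params"))
  clamp <- match.arg(clamp)
  if (is.null(params$w1))
    stop("terminal_value() needs an explicit w1; calibrate first", call. = FALSE)
  if (!is.null(tau) && state$n_u == tau && state$a_e == 1L && state$a_s == 1L)
    return(0)
  elapsed <- state$n_u + state$a_e + state$a_s
  N <- N0 + rates$nodes * elapsed
  if (clamp == "floor") N <- pmax(0, N)
  params$w2^state$a_e * sum(rates$weights * (1 - exp(-params$w1 * N)))
}

#' Terminal values for every state of a horizon-tau model
#'
#' Vectorized [terminal_value()] over the full state enumeration, with the
#' extinction sink `S_R` forced to 0.
#'
#' @inheritParams terminal_value
#' @param tau Decision horizon (years).
#' @return An object of class `"terminal_values"`: numeric vector of length
#'   `R = 4 (tau + 1)`, with the state table as attribute `states`.
#' @export
terminal_values <- function(tau, rates, N0, params,
                            clamp = c("floor", "raw")) {
  tau <- check_tau(tau)
  clamp <- match.arg(clamp)
  stopifnot(inherits(rates, "rate_distribution"),
            inherits(params, "value_params"))
  if (is.null(params$w1))
    stop("terminal_values() needs an explicit w1; calibrate first",
         call. = FALSE)
  st <- enumerate_states(tau)
  R <- nrow(st)
  # E_r[1 - exp(-w1 max(0, N0 + r e))] for each distinct elapsed time
  v <- vapply(seq_len(R), function(i) {
    N <- N0 + rates$nodes * st$elapsed[i]
    if (clamp == "floor") N <- pmax(0, N)
    params$w2^st$a_e[i] * sum(rates$weights * (1 - exp(-params$w1 * N)))
  }, numeric(1))
  v[R] <- 0  # S_R = {tau, 1, 1}: complete extinction
  structure(v, class = "terminal_values", states = st, tau = tau)
}

#' Calibrate the satisfaction rate from a pre-decline abundance
#'
#' Returns `w1 = ln(20)/N_pre`, the rate at which a population of `N_pre`
#' individuals yields utility `1 - 1/20 = 0.95`, i.e. managers were 95%
#' satisfied with the abundance before the decline began.
#'
#' @param N_pre Pre-decline abundance (individuals), positive.
#' @return The calibrated `w1` (1/individuals).
#' @export
calibrate_w1 <- function(N_pre) {
  if (!is.numeric(N_pre) || length(N_pre) != 1L || N_pre <= 0)
    stop("N_pre must be a positive scalar", call. = FALSE)
  log(20) / N_pre
}
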