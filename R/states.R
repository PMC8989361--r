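#' System states of the trigger-point decision model
#'
#' The Markov chain tracks three quantities: `n_u`, the number of years in
#' situ management has been attempted without success (0..tau); `a_e`,
#' whether the ex situ, in toto action has been taken (0/1); and `a_s`,
#' whether an in situ action has succeeded (0/1).  Because the two actions
#' are never taken in the same year, the total elapsed management time in a
#' state is `n_u + a_e + a_s`.  States are enumerated 1-based by the index
#' `i = a_s + 2 a_e + 4 n_u + 1`, giving `R = 4 (tau + 1)` states; the last
#' state `S_R = {tau, 1, 1}` doubles as the complete-extinction sink for
#' failed ex situ attempts.
#'
#' @param n_u Unsuccessful in situ years (non-negative integer).
#' @param a_e Ex situ action taken (0 or 1).
#' @param a_s In situ success achieved (0 or 1).
#' @return `system_state()` returns a `"system_state"` object (list with
#'   `n_u`, `a_e`, `a_s`).
#' @examples
#' state_index(3, 0, 1)   # 14
#' state_from_index(14)
#' @export
system_state <- function(n_u, a_e, a_s) {
  if (n_u < 0 || n_u != round(n_u)) stop("n_u must be a non-negative integer",
                                         call. = FALSE)
  if (!a_e %in% c(0, 1) || !a_s %in% c(0, 1))
    stop("a_e and a_s must be 0 or 1", call. = FALSE)
  structure(list(n_u = as.integer(n_u), a_e = as.integer(a_e),
                 a_s = as.integer(a_s)),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("State {n_u = %d, a_e = %d, a_s = %d}, index %d, elapsed %d years\n",
              x$n_u, x$a_e, x$a_s, state_index(x$n_u, x$a_e, x$a_s),
              x$n_u + x$a_e + x$a_s))
  invisible(x)
}

#' @rdname system_state
#' @return `state_index()` returns the 1-based index `a_s + 2 a_e + 4 n_u + 1`
#'   (vectorized).
#' @export
state_index <- function(n_u, a_e, a_s) {
  as.integer(a_s + 2L * a_e + 4L * n_u + 1L)
}

#' @rdname system_state
#' @param i State index in `1..R`.
#' @return `state_from_index()` returns the `"system_state"` at index `i`.
#' @export
state_from_index <- function(i) {
  if (i < 1 || i != round(i)) stop("index must be a positive integer",
                                   call. = FALSE)
  i0 <- as.integer(i) - 1L
  system_state(n_u = i0 %/% 4L, a_e = (i0 %% 4L) %/% 2L, a_s = i0 %% 2L)
}

#' Enumerate all states of a horizon-tau decision model
#'
#' @param tau Decision horizon in years (integer, >= 1).
#' @return Data frame with `R = 4 (tau + 1)` rows and columns `index`,
#'   `n_u`, `a_e`, `a_s`, `elapsed`, `absorbing`, `live`, ordered so that
#'   row number equals the state index.
#' @export
enumerate_states <- function(tau) {
  tau <- check_tau(tau)
  n_u <- rep(0:tau, each = 4L)
  a_e <- rep(c(0L, 1L, 0L, 1L), tau + 1L)
  a_s <- rep(c(0L, 0L, 1L, 1L), tau + 1L)
  # (a_e, a_s) cycle must match i = a_s + 2 a_e + 4 n_u + 1
  ord <- order(state_index(n_u, a_e, a_s))
  n_u <- n_u[ord]; a_e <- a_e[ord]; a_s <- a_s[ord]
  live <- a_e == 0L & a_s == 0L
  data.frame(
    index = state_index(n_u, a_e, a_s),
    n_u = n_u, a_e = a_e, a_s = a_s,
    elapsed = n_u + a_e + a_s,
    absorbing = !live | n_u == tau,
    live = live
  )
}

check_tau <- function(tau) {
  if (length(tau) != 1L || is.na(tau) || tau < 1 || tau != round(tau))
    stop("horizon too short: tau must be an integer >= 1", call. = FALSE)
  as.integer(tau)
}

#' Transition matrix for continuing in situ management
#'
#' From a live state `{n_u, 0, 0}` (with `n_u < tau`) the in situ action
#' succeeds with probability `E[q | n_u]`, moving to `{n_u, 0, 1}`, and
#' fails with the complementary probability, moving to `{n_u + 1, 0, 0}`.
#' States with `a_e = 1` or `a_s = 1` are absorbing (identity rows), as is
#' `{tau, 0, 0}`, the live state at the end of the horizon.
#'
#' @param tau Decision horizon (years).
#' @param belief_variant Passed to [expected_success()].
#' @return A row-stochastic `R x R` matrix of class `"transition_matrix"`
#'   with attribute `kind = "in_situ"`.
#' @export
in_situ_matrix <- function(tau, belief_variant = c("conjugate", "as_printed")) {
  tau <- check_tau(tau)
  belief_variant <- match.arg(belief_variant)
  R <- 4L * (tau + 1L)
  T_s <- diag(1, R, R)
  for (n_u in 0:(tau - 1L)) {
    i <- state_index(n_u, 0L, 0L)
    q <- expected_success(n_u, belief_variant)
    T_s[i, i] <- 0
    T_s[i, state_index(n_u, 0L, 1L)] <- q
    T_s[i, state_index(n_u + 1L, 0L, 0L)] <- 1 - q
  }
  new_transition_matrix(T_s, "in_situ", tau)
}

#' Transition matrix for triggering the ex situ, in toto action
#'
#' From a live state `{n_u, 0, 0}` the capture succeeds with probability
#' `px`, moving to `{n_u, 1, 0}` (species persists ex situ, extinct in the
#' wild), and fails with probability `1 - px`, in which case the species is
#' entirely extinct: this is modelled as a transition to the last state
#' `S_R = {tau, 1, 1}`, a bookkeeping sink unreachable by any other route.
#' All non-live states are absorbing.
#'
#' @param tau Decision horizon (years).
#' @param px Probability that the ex situ, in toto action succeeds.
#' @return A row-stochastic `R x R` matrix of class `"transition_matrix"`
#'   with attribute `kind = "ex_situ"`.
#' @export
ex_situ_matrix <- function(tau, px) {
  tau <- check_tau(tau)
  if (length(px) != 1L || is.na(px) || px < 0 || px > 1)
    stop("invalid probability: px must be in [0, 1]", call. = FALSE)
  R <- 4L * (tau + 1L)
  T_e <- diag(1, R, R)
  for (n_u in 0:tau) {
    i <- state_index(n_u, 0L, 0L)
    T_e[i, i] <- 0
    T_e[i, state_index(n_u, 1L, 0L)] <- px
    T_e[i, R] <- T_e[i, R] + (1 - px)
  }
  new_transition_matrix(T_e, "ex_situ", tau)
}

new_transition_matrix <- function(m, kind, tau) {
  structure(m, class = c("transition_matrix", "matrix", "array"),
            kind = kind, tau = tau)
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("%s transition matrix: %d x %d (tau = %d)\n",
              attr(x, "kind"), nrow(x), ncol(x), attr(x, "tau")))
  invisible(x)
}

#' Export a transition matrix (or terminal values) with a state legend
#'
#' Writes the dense matrix as CSV plus a sidecar legend file mapping each
#' state index to its `{n_u, a_e, a_s}` triple, for manual inspection.
#'
#' @param m A `"transition_matrix"`.
#' @param path Output CSV path for the matrix; the legend goes to
#'   `<path-sans-ext>_states.csv`.
#' @return Invisibly, the two paths written.
#' @export
write_transition_csv <- function(m, path) {
  stopifnot(inherits(m, "transition_matrix"))
  tau <- attr(m, "tau")
  utils::write.table(unclass(m), path, sep = ",", row.names = FALSE,
                     col.names = paste0("S", seq_len(ncol(m))))
  legend_path <- paste0(sub("\\.csv$", "", path), "_states.csv")
  utils::write.csv(enumerate_states(tau)[, c("index", "n_u", "a_e", "a_s")],
                   legend_path, row.names = FALSE, quote = FALSE)
  invisible(c(matrix = path, legend = legend_path))
}
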