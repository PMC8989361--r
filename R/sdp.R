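#' Solve the optimal-stopping problem by backward induction
#'
#' Stochastic dynamic programming on the finite-horizon Markov decision
#' model: starting from the terminal values at stage `tau`, the Bellman
#' recursion
#' `V(S_i, t) = max_a sum_j T^(a)_ij V(S_j, t + 1)`
#' is iterated backwards for `t = tau - 1, ..., 0`, recording the optimal
#' action at every live state and stage.  Absorbing states carry their
#' value forward unchanged (their rows are identity in both matrices) and
#' have no action.  Ties within an absolute tolerance of 1e-12 are broken
#' in favour of continuing in situ: delaying preserves the option value of
#' the irreversible capture and makes output deterministic.
#'
#' @param T_s In situ transition matrix ([in_situ_matrix()]).
#' @param T_e Ex situ transition matrix ([ex_situ_matrix()]).
#' @param terminal Terminal values ([terminal_values()]), length `R`.
#' @param tau Decision horizon (years); must match the matrices.
#' @return An object of class `"policy_table"`: list with `V`, a
#'   `(tau + 1) x R` matrix of values (row `t + 1` is stage `t`), `action`,
#'   a `tau x R` character matrix over `"in_situ"`, `"ex_situ"`, `"none"`,
#'   plus `tau` and the state table.
#' @export
solve_sdp <- function(T_s, T_e, terminal, tau) {
  tau <- check_tau(tau)
  R <- 4L * (tau + 1L)
  if (nrow(T_s) != R || ncol(T_s) != R || nrow(T_e) != R || ncol(T_e) != R ||
      length(terminal) != R)
    stop("inconsistent state space: matrices and terminal values must all be for the same tau",
         call. = FALSE)
  st <- enumerate_states(tau)
  live <- st$live
  V <- matrix(NA_real_, nrow = tau + 1L, ncol = R)
  action <- matrix("none", nrow = tau, ncol = R)
  V[tau + 1L, ] <- as.numeric(terminal)
  Ts <- unclass(T_s); Te <- unclass(T_e)
  for (t in (tau - 1L):0L) {
    v_next <- V[t + 2L, ]
    v_s <- drop(Ts %*% v_next)
    v_e <- drop(Te %*% v_next)
    take_ex <- live & (v_e > v_s + 1e-12)
    V[t + 1L, ] <- ifelse(live, pmax(v_s, v_e), v_next)
    action[t + 1L, ] <- ifelse(live, ifelse(take_ex, "ex_situ", "in_situ"),
                               "none")
  }
  structure(list(V = V, action = action, tau = tau, states = st),
            class = "policy_table")
}

#' @export
print.policy_table <- function(x, ...) {
  cat(sprintf("Optimal policy: tau = %d, %d states x %d decision stages\n",
              x$tau, ncol(x$V), x$tau))
  i0 <- state_index(0L, 0L, 0L)
  cat(sprintf("  V({0,0,0}, 0) = %.6f, a*({0,0,0}, 0) = %s\n",
              x$V[1L, i0], x$action[1L, i0]))
  invisible(x)
}

#' Long-format view of a policy table
#'
#' @param x A `"policy_table"`.
#' @param row.names,optional,... Passed through for S3 compatibility;
#'   ignored.
#' @return Data frame with columns `t`, `state_index`, `n_u`, `a_e`, `a_s`,
#'   `action`, `value`, one row per (stage, state) pair for `t = 0..tau`
#'   (stage `tau` rows carry the terminal values and action `"none"`).
#' @export
as.data.frame.policy_table <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  st <- x$states
  R <- nrow(st)
  stages <- 0:x$tau
  out <- do.call(rbind, lapply(stages, function(t) {
    data.frame(
      t = t,
      state_index = st$index, n_u = st$n_u, a_e = st$a_e, a_s = st$a_s,
      action = if (t < x$tau) x$action[t + 1L, ] else rep("none", R),
      value = x$V[t + 1L, ]
    )
  }))
  rownames(out) <- NULL
  out
}

#' Write a policy table as long-format CSV
#'
#' @param policy A `"policy_table"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_policy_csv <- function(policy, path) {
  stopifnot(inherits(policy, "policy_table"))
  utils::write.csv(as.data.frame(policy), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Brute-force oracle for the value of the initial state
#'
#' Independent verification of [solve_sdp()] at small horizons: enumerates
#' every deterministic assignment of an action to the (state, stage) pairs
#' reachable from `{0, 0, 0}` (the only live state reachable at stage `t`
#' is `{t, 0, 0}`, so `2^tau` assignments cover all distinct policies;
#' action choices at unreachable pairs cannot affect the value), evaluates
#' each assignment's expected terminal value by explicit probability-tree
#' expansion, and returns the maximum.  No Bellman recursion is used.
#'
#' @inheritParams solve_sdp
#' @param tau Horizon, at most 4 (tractability guard).
#' @return The optimal expected value at state `{0, 0, 0}`, stage 0.
#' @export
brute_force_value <- function(T_s, T_e, terminal, tau) {
  tau <- check_tau(tau)
  if (tau > 4L) stop("oracle scale exceeded: tau must be <= 4", call. = FALSE)
  R <- 4L * (tau + 1L)
  if (nrow(T_s) != R || length(terminal) != R)
    stop("inconsistent state space", call. = FALSE)
  st <- enumerate_states(tau)
  live <- st$live
  terminal <- as.numeric(terminal)
  Ts <- unclass(T_s); Te <- unclass(T_e)

  eval_tree <- function(i, t, acts) {
    if (t == tau) return(terminal[i])
    if (!live[i]) return(terminal[i])  # absorbing: value propagates
    row <- if (acts[t + 1L] == 1L) Ts[i, ] else Te[i, ]
    js <- which(row > 0)
    sum(vapply(js, function(j) row[j] * eval_tree(j, t + 1L, acts),
               numeric(1)))
  }

  best <- -Inf
  i0 <- state_index(0L, 0L, 0L)
  for (mask in 0:(2^tau - 1L)) {
    acts <- 1L + ((mask %/% 2^(0:(tau - 1L))) %% 2L)  # 1 = in_situ, 2 = ex_situ
    best <- max(best, eval_tree(i0, 0L, acts))
  }
  best
}

#' Expected value of a fixed (non-adaptive) action policy
#'
#' Evaluates the policy that applies the same action at every live state
#' and stage, by forward propagation of the state distribution from
#' `{0, 0, 0}`.  Used to check that the optimal policy dominates both
#' fixed policies.
#'
#' @inheritParams solve_sdp
#' @param action `"in_situ"` or `"ex_situ"`.
#' @return Expected terminal value at `{0, 0, 0}`, stage 0.
#' @export
fixed_policy_value <- function(T_s, T_e, terminal, tau,
                               action = c("in_situ", "ex_situ")) {
  tau <- check_tau(tau)
  action <- match.arg(action)
  M <- unclass(if (action == "in_situ") T_s else T_e)
  R <- nrow(M)
  p <- numeric(R)
  p[state_index(0L, 0L, 0L)] <- 1
  for (t in seq_len(tau)) p <- drop(p %*% M)
  sum(p * as.numeric(terminal))
}
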