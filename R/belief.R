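#' Posterior belief about the annual in situ success probability
#'
#' The response of the population to an in situ management action in any
#' year is modelled as a Bernoulli trial with unknown, constant success
#' probability `q`.  Starting from a uniform Beta(1, 1) prior, after `n_u`
#' consecutive observed failures the conjugate posterior is
#' Beta(1, n_u + 1): repeated failures concentrate belief near zero and
#' make managers increasingly pessimistic that the action will ever work.
#'
#' @param n_u Number of unsuccessful in situ years (non-negative integer).
#' @return An object of class `"success_belief"`: list with `n_failures`,
#'   `alpha` (= 1), `beta` (= n_u + 1), and `mean`.
#' @examples
#' success_posterior(0)  # uniform prior
#' success_posterior(3)  # Beta(1, 4)
#' @export
success_posterior <- function(n_u) {
  n_u <- check_failure_count(n_u)
  structure(list(n_failures = n_u, alpha = 1, beta = n_u + 1,
                 mean = 1 / (n_u + 2)),
            class = "success_belief")
}

#' @export
print.success_belief <- function(x, ...) {
  cat(sprintf("Belief about in situ success q after %d failures: Beta(%g, %g), E[q] = %.4f\n",
              x$n_failures, x$alpha, x$beta, x$mean))
  invisible(x)
}

#' Posterior density of the in situ success probability
#'
#' @param x Quantiles in \[0, 1\].
#' @param belief A [success_posterior()] object.
#' @return Density values of Beta(alpha, beta) at `x`.
#' @export
dbelief <- function(x, belief) {
  stopifnot(inherits(belief, "success_belief"))
  stats::dbeta(x, belief$alpha, belief$beta)
}

#' Expected probability that next year's in situ action succeeds
#'
#' Under the conjugate Beta(1, n_u + 1) posterior the expectation of `q` is
#' `1/(n_u + 2)` (the `"conjugate"` variant, default), which decreases
#' towards 0 as failures accumulate.  The `"as_printed"` variant returns
#' the complementary expression `1 - 1/(n_u + 2)`, which instead grows with
#' failures; it is provided only for literal reproduction of an alternative
#' published form and is inconsistent with the posterior itself.
#'
#' @param n_u Number of unsuccessful in situ years.
#' @param variant `"conjugate"` (default) or `"as_printed"`.
#' @return Expected success probability in (0, 1).
#' @examples
#' expected_success(0)            # 0.5
#' expected_success(3)            # 0.2
#' expected_success(3, "as_printed")  # 0.8
#' @export
expected_success <- function(n_u, variant = c("conjugate", "as_printed")) {
  variant <- match.arg(variant)
  n_u <- check_failure_count(n_u)
  if (variant == "conjugate") 1 / (n_u + 2) else 1 - 1 / (n_u + 2)
}

check_failure_count <- function(n_u) {
  if (length(n_u) != 1L || is.na(n_u) || n_u < 0 || n_u != round(n_u))
    stop("invalid failure count: n_u must be a non-negative integer",
         call. = FALSE)
  as.integer(n_u)
}
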