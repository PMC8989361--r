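test_that("all-zero terminal values give an identically zero value function", {
  tau <- 3L
  pol <- solve_sdp(in_situ_matrix(tau), ex_situ_matrix(tau, 0.75),
                   structure(numeric(16), class = "terminal_values"), tau)
  expect_equal(unname(pol$V), matrix(0, tau + 1, 16))
})

test_that("terminal stage of the value function equals the terminal values", {
  inst <- local({set.seed(1); random_instance(3L)})
  pol <- solve_sdp(inst$T_s, inst$T_e, inst$terminal, inst$tau)
  expect_equal(pol$V[inst$tau + 1L, ], as.numeric(inst$terminal))
})

test_that("dimension mismatches are rejected", {
  expect_error(solve_sdp(in_situ_matrix(2), ex_situ_matrix(3, 0.5),
                         structure(numeric(12), class = "terminal_values"), 2),
               "inconsistent state space")
})

test_that("solver matches the brute-force oracle on random instances", {
  set.seed(20)
  for (k in seq_len(15)) {
    tau <- sample(1:3, 1)
    inst <- random_instance(tau)
    pol <- solve_sdp(inst$T_s, inst$T_e, inst$terminal, tau)
    oracle <- brute_force_value(inst$T_s, inst$T_e, inst$terminal, tau)
    expect_equal(pol$V[1L, state_index(0, 0, 0)], oracle, tolerance = 1e-10)
  }
  expect_error(brute_force_value(in_situ_matrix(5), ex_situ_matrix(5, 0.5),
                                 structure(numeric(24),
                                           class = "terminal_values"), 5),
               "oracle scale exceeded")
})

test_that("tau = 1 reduces to a closed-form one-shot comparison", {
  p <- value_params(w1 = 0.02, w2 = 0.5, px = 0.8)
  rd <- rate_point_mass(-12)
  tau <- 1L
  term <- terminal_values(tau, rd, 60, p)
  pol <- solve_sdp(in_situ_matrix(tau), ex_situ_matrix(tau, p$px), term, tau)
  v_in <- 0.5 * term[state_index(0, 0, 1)] + 0.5 * term[state_index(1, 0, 0)]
  v_ex <- 0.8 * term[state_index(0, 1, 0)]  # failure goes to the 0-valued sink
  expect_equal(pol$V[1L, state_index(0, 0, 0)], max(v_in, v_ex),
               tolerance = 1e-12)
  expect_equal(pol$action[1L, state_index(0, 0, 0)],
               if (v_ex > v_in + 1e-12) "ex_situ" else "in_situ")
})

test_that("worthless capture (px = 0) is never chosen while any live value remains", {
  set.seed(33)
  for (k in seq_len(5)) {
    tau <- sample(2:3, 1)
    inst <- random_instance(tau)
    T_e0 <- ex_situ_matrix(tau, 0)
    pol <- solve_sdp(inst$T_s, T_e0, inst$terminal, tau)
    live <- pol$states$live
    expect_false(any(pol$action[, live] == "ex_situ"))
    oracle <- brute_force_value(inst$T_s, T_e0, inst$terminal, tau)
    expect_equal(pol$V[1L, state_index(0, 0, 0)], oracle, tolerance = 1e-10)
  }
})

test_that("certain undiscounted capture dominates strictly before the last stage", {
  tau <- 6L
  p <- value_params(w1 = 0.01, w2 = 1, px = 1)
  rd <- make_rates(qnorm((1:51 - 0.5) / 51, -9, 2))
  term <- terminal_values(tau, rd, 80, p)
  pol <- solve_sdp(in_situ_matrix(tau), ex_situ_matrix(tau, 1), term, tau)
  live <- which(pol$states$live & pol$states$n_u < tau)
  for (t in 0:(tau - 2L)) {
    reachable <- live[pol$states$n_u[live] <= t]
    expect_true(all(pol$action[t + 1L, reachable] == "ex_situ"))
  }
  # at the last stage all successor values coincide (w2 = 1): tie -> in_situ
  expect_equal(pol$action[tau, state_index(0, 0, 0)], "in_situ")
})

test_that("the optimal policy dominates both fixed single-action policies", {
  set.seed(54)
  for (k in seq_len(8)) {
    tau <- sample(2:4, 1)
    inst <- random_instance(tau)
    pol <- solve_sdp(inst$T_s, inst$T_e, inst$terminal, tau)
    v_opt <- pol$V[1L, state_index(0, 0, 0)]
    v_in <- fixed_policy_value(inst$T_s, inst$T_e, inst$terminal, tau,
                               "in_situ")
    v_ex <- fixed_policy_value(inst$T_s, inst$T_e, inst$terminal, tau,
                               "ex_situ")
    expect_gte(v_opt, v_in - 1e-12)
    expect_gte(v_opt, v_ex - 1e-12)
    expect_true(all(pol$V >= -1e-12 & pol$V <= 1 + 1e-12))
  }
})

test_that("once capture is optimal it stays optimal at higher failure counts", {
  # empirical structure check on a grid of defaults-like parameters
  rd <- make_rates(qnorm((1:51 - 0.5) / 51, -10, 3))
  for (px in c(0.5, 0.75, 0.9)) {
    for (w2 in c(0.5, 2 / 3, 0.9)) {
      tau <- 8L
      p <- value_params(w1 = log(20) / 120, w2 = w2, px = px)
      term <- terminal_values(tau, rd, 120, p)
      pol <- solve_sdp(in_situ_matrix(tau), ex_situ_matrix(tau, px), term, tau)
      # among states reachable at stage t (n_u <= t along the live diagonal)
      for (t in 0:(tau - 1L)) {
        acts <- vapply(0:t, function(nu)
          pol$action[t + 1L, state_index(nu, 0, 0)], character(1))
        first_ex <- which(acts == "ex_situ")[1]
        if (!is.na(first_ex))
          expect_true(all(acts[first_ex:length(acts)] == "ex_situ"))
      }
    }
  }
})

test_that("policy tables export in long format", {
  tau <- 2L
  p <- value_params(w1 = 0.02)
  term <- terminal_values(tau, rate_point_mass(-10), 50, p)
  pol <- solve_sdp(in_situ_matrix(tau), ex_situ_matrix(tau, 0.75), term, tau)
  df <- as.data.frame(pol)
  expect_equal(nrow(df), 12L * (tau + 1L))  # R rows per stage, stages 0..tau
  expect_true(all(df$action %in% c("in_situ", "ex_situ", "none")))
  expect_true(all(df$action[df$a_e == 1 | df$a_s == 1] == "none"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_policy_csv(pol, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(df))
  expect_equal(back$value, df$value, tolerance = 1e-12)
})
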