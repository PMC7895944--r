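fit_toy_state_model <- function() {
  # identity-like state model for hand-built events: feature = state index
  structure(list(
    k = 2L, centroids = matrix(c(1, 2), 2, 1), center = 0, scale = 1,
    features = "feat_01", terminal = c(survival = 3L, death = 4L),
    n_states = 4L
  ), class = "state_model")
}

toy_events <- function() {
  vt_from_1 <- c(NA, rep(420, 6))
  g1 <- make_stay("surv", 0:6, vt = vt_from_1, peep = 6, fio2 = 40,
                  feats = matrix(c(1, 1, 1, 2, 2, 1, 1), 7, 1), d = 1)
  g2 <- make_stay("died", 0:6, vt = vt_from_1, peep = 8, fio2 = 50,
                  outcome = "died",
                  feats = matrix(c(2, 2, 1, 1, 2, 2, 2), 7, 1), d = 1)
  man <- tiny_manifest(1)
  ev <- define_ventilation_events(dplyr::bind_rows(g1, g2), man)
  ev
}

test_that("discretized trajectories carry terminal-only +/-100 rewards", {
  ev <- toy_events()
  sm <- fit_toy_state_model()
  tr <- discretize_trajectories(ev, sm, default_action_grid())
  expect_identical(nrow(tr), 12L)  # 6 post-onset bins per stay
  surv <- tr[tr$stay_id == "surv", ]
  died <- tr[tr$stay_id == "died", ]
  expect_equal(surv$r, c(0, 0, 0, 0, 0, 100))
  expect_equal(died$r, c(0, 0, 0, 0, 0, -100))
  expect_identical(surv$s_next[6], 3L)
  expect_identical(died$s_next[6], 4L)
  expect_true(all(tr$r[!tr$terminal] == 0))
  # states follow the feature values, next-state chains within the stay
  expect_identical(surv$s, c(1L, 1L, 2L, 2L, 1L, 1L))
  expect_identical(surv$s_next[1:5], surv$s[2:6])
})

test_that("estimate_mdp matches the hand-computed collapse R(s,a)", {
  # 7 transitions to survival, 3 to death from one (s, a)
  tr <- tibble::tibble(
    stay_id = sprintf("x%02d", 1:10), step = 1L, s = 1L, a = 2L,
    r = c(rep(100, 7), rep(-100, 3)),
    s_next = c(rep(3L, 7), rep(4L, 3)), terminal = TRUE
  )
  mdp <- estimate_mdp(tr, n_states = 4, n_actions = 3, gamma = 0.9,
                      min_count = 1, terminal = c(survival = 3L, death = 4L))
  expect_equal(transition_probs(mdp, 1, 2)[3:4], c(0.7, 0.3))
  expect_equal(mdp$R[1, 2], 40)
  expect_equal(mdp$N_sa[1, 2], 10)
  # terminal states are absorbing with zero reward
  expect_equal(transition_probs(mdp, 3, 1), c(0, 0, 1, 0))
  expect_equal(transition_probs(mdp, 4, 2), c(0, 0, 0, 1))
  expect_true(all(mdp$R[3:4, ] == 0))
})

test_that("deterministic chains give 0/1 transition rows summing to 1", {
  toy <- toy_chain_kernel()
  tr <- kernel_transitions(toy$kernel, toy$n_phys, reps = 1)
  mdp <- estimate_mdp(tr, n_states = 5, n_actions = 2, gamma = 0.9,
                      min_count = 1, terminal = toy$terminal)
  probs <- as.matrix(mdp$trans)
  expect_true(all(probs %in% c(0, 1)))
  observed <- rowSums(mdp$N_sa) > 0
  row_sums <- Matrix::rowSums(mdp$trans)
  for (s in which(observed)) {
    for (a in 1:2) {
      if (mdp$N_sa[s, a] > 0) {
        expect_equal(row_sums[(s - 1) * 2 + a], 1, tolerance = 1e-9)
      }
    }
  }
})

test_that("value iteration matches the policy-enumeration oracle", {
  for (toy in list(toy_chain_kernel(), toy_stochastic_kernel())) {
    mdp <- make_mdp(toy$kernel, toy$R, gamma = 0.9, n_phys = toy$n_phys,
                    terminal = toy$terminal)
    sol <- solve_optimal_policy(mdp, tol = 1e-12)
    oracle <- oracle_enumerate(toy$kernel, toy$R, 0.9, toy$n_phys)
    expect_equal(sol$v[seq_len(toy$n_phys)], oracle$v, tolerance = 1e-6)
    expect_equal(sol$q[seq_len(toy$n_phys), ], oracle$q, tolerance = 1e-6)
  }
})

test_that("gamma = 0 collapses Q to the reward table", {
  toy <- toy_stochastic_kernel()
  mdp <- make_mdp(toy$kernel, toy$R, gamma = 1e-12, n_phys = 3,
                  terminal = toy$terminal)
  sol <- solve_optimal_policy(mdp, tol = 1e-13)
  expect_equal(sol$q[1:3, ], toy$R[1:3, ], tolerance = 1e-9)
})

test_that("a two-step deterministic chain into survival is worth gamma*100", {
  toy <- toy_chain_kernel()
  mdp <- make_mdp(toy$kernel, toy$R, gamma = 0.9, n_phys = 3,
                  terminal = toy$terminal)
  sol <- solve_optimal_policy(mdp, tol = 1e-12)
  # state 3 is one step from survival, state 2 two steps
  expect_equal(sol$v[3], 100, tolerance = 1e-9)
  expect_equal(sol$v[2], 90, tolerance = 1e-9)
  expect_equal(sol$v[1], 81, tolerance = 1e-9)
})

test_that("sample-based Q-learning reaches the value-iteration fixed point", {
  toy <- toy_stochastic_kernel()
  mdp <- make_mdp(toy$kernel, toy$R, gamma = 0.9, n_phys = 3,
                  terminal = toy$terminal)
  tr <- kernel_transitions(toy$kernel, 3, reps = 10)
  vi <- solve_optimal_policy(mdp, tol = 1e-12)
  ql <- solve_optimal_policy(mdp, method = "q_learning", transitions = tr,
                             passes = 8000, seed = 2)
  expect_lt(max(abs(ql$q[1:3, ] - vi$q[1:3, ])), 1e-3)
  expect_identical(max.col(ql$q[1:3, ]), max.col(vi$q[1:3, ]))
})

test_that("solving errors when a visited state has no eligible action", {
  tr <- tibble::tibble(stay_id = c("a", "b"), step = 1L, s = c(1L, 2L),
                       a = 1L, r = 100, s_next = 3L, terminal = TRUE)
  mdp <- estimate_mdp(tr, n_states = 4, n_actions = 2, gamma = 0.9,
                      min_count = 5, terminal = c(survival = 3L, death = 4L))
  expect_error(solve_optimal_policy(mdp), "eligible")
})

test_that("the empirical behavior policy reproduces action frequencies", {
  tr <- tibble::tibble(
    stay_id = sprintf("t%d", 1:4), step = 1L,
    s = 1L, a = c(1L, 1L, 1L, 2L), r = 0, s_next = 2L, terminal = FALSE
  )
  pib <- estimate_behavior_policy(tr, n_states = 4, n_actions = 3,
                                  quiet = TRUE)
  expect_equal(pib[1, ], c(0.75, 0.25, 0))
  expect_equal(rowSums(pib), rep(1, 4))
  expect_equal(pib[2, ], rep(1 / 3, 3))  # unvisited -> uniform
  expect_message(estimate_behavior_policy(tr, 4, 3), "uniform")
})

test_that("softening spreads epsilon mass over eligible actions", {
  pol <- matrix(0, 2, 5)
  pol[, 3] <- 1
  mask <- matrix(TRUE, 2, 5)
  pol <- ventrl:::new_policy_table(pol, "deterministic-greedy", mask = mask)
  soft <- soften_policy(pol, 0.05)
  expect_equal(soft[1, 3], 0.96)
  expect_equal(soft[1, 1], 0.01)
  expect_equal(rowSums(soft), c(1, 1))
  expect_equal(unclass(soften_policy(pol, 0)), unclass(pol),
               ignore_attr = TRUE)
  # restricted eligibility concentrates the epsilon mass
  mask2 <- mask
  mask2[1, 4:5] <- FALSE
  soft2 <- soften_policy(pol, 0.3, mask = mask2)
  expect_equal(soft2[1, ], c(0.1, 0.1, 0.8, 0, 0))
})

test_that("the random policy is uniform over eligible actions", {
  toy <- toy_stochastic_kernel()
  mdp <- make_mdp(toy$kernel, toy$R, gamma = 0.9, n_phys = 3,
                  terminal = toy$terminal)
  mdp$mask[1, 2] <- FALSE
  rp <- random_policy(mdp)
  expect_equal(rp[1, ], c(1, 0))
  expect_equal(rp[2, ], c(0.5, 0.5))
  expect_equal(rowSums(rp), rep(1, 5))
  # its linear-solve value matches the oracle
  ev <- evaluate_policy(mdp, rp)
  vo <- oracle_policy_value(toy$kernel, toy$R, 0.9,
                            rbind(c(1, 0), c(0.5, 0.5), c(0.5, 0.5)), 3)
  expect_equal(ev$v[1:3], vo, tolerance = 1e-6)
})

test_that("TD(0) evaluation converges to the linear-solve value", {
  toy <- toy_stochastic_kernel()
  tr <- kernel_transitions(toy$kernel, 3, reps = 10)
  # behavior here: uniform over the two actions (transitions are balanced)
  mdp <- estimate_mdp(tr, n_states = 5, n_actions = 2, gamma = 0.9,
                      min_count = 1, terminal = toy$terminal)
  pib <- estimate_behavior_policy(tr, 5, 2, quiet = TRUE)
  target <- evaluate_policy(mdp, pib)
  td <- evaluate_clinician_td(tr, gamma = 0.9, n_states = 5,
                              terminal = c(4L, 5L), passes = 4000, seed = 4)
  expect_lt(max(abs(td$v[1:3] - target$v[1:3])), 1e-3)
  # zero learning rate leaves the initialization untouched
  td0 <- evaluate_clinician_td(tr, gamma = 0.9, n_states = 5,
                               terminal = c(4L, 5L), passes = 5, alpha = 0)
  expect_equal(td0$value, 0)

  # all-survivor data at gamma = 1 values every state at 100
  surv <- tibble::tibble(
    stay_id = rep(sprintf("s%d", 1:30), each = 2),
    step = rep(1:2, 30),
    s = rep(c(1L, 2L), 30), a = 1L,
    r = rep(c(0, 100), 30),
    s_next = rep(c(2L, 3L), 30),
    terminal = rep(c(FALSE, TRUE), 30)
  )
  td1 <- evaluate_clinician_td(surv, gamma = 1, n_states = 4,
                               terminal = c(3L, 4L), passes = 3000, seed = 1)
  expect_equal(td1$value, 100, tolerance = 1e-2)
})

test_that("the optimal value dominates behavior, random and clinician", {
  toy <- toy_stochastic_kernel()
  mdp <- make_mdp(toy$kernel, toy$R, gamma = 0.9, n_phys = 3,
                  terminal = toy$terminal)
  sol <- solve_optimal_policy(mdp, tol = 1e-12)
  tr <- kernel_transitions(toy$kernel, 3, reps = 10)
  pib <- estimate_behavior_policy(tr, 5, 2, quiet = TRUE)
  for (pol in list(pib, random_policy(mdp),
                   soften_policy(sol$policy, 0.4))) {
    v_pol <- evaluate_policy(mdp, pol)$v
    expect_true(all(sol$v[1:3] >= v_pol[1:3] - 1e-9))
  }
})

test_that("returns and Q values stay within the terminal-reward range", {
  withr::with_seed(33, {
    for (rep_i in 1:5) {
      n <- sample(2:6, 1)
      A <- sample(2:4, 1)
      S <- n + 2L
      k <- array(0, dim = c(S, A, S))
      for (s in seq_len(n)) {
        for (a in seq_len(A)) {
          p <- rgamma(S - 0, 1)
          p <- p / sum(p)
          k[s, a, ] <- p
        }
      }
      for (t in (n + 1):S) {
        k[t, , ] <- 0
        k[t, , t] <- 1
      }
      R <- matrix(0, S, A)
      for (s in seq_len(n)) {
        R[s, ] <- 100 * (k[s, , n + 1] - k[s, , n + 2])
      }
      mdp <- make_mdp(k, R, gamma = runif(1, 0.5, 1), n_phys = n,
                      terminal = c(survival = n + 1L, death = n + 2L))
      sol <- solve_optimal_policy(mdp, tol = 1e-10)
      expect_true(all(abs(sol$q[seq_len(n), ]) <= 100 + 1e-9))
      expect_true(all(abs(sol$v) <= 100 + 1e-9))
    }
  })
})

test_that("mdp tidiers report transitions and summary counts", {
  toy <- toy_chain_kernel()
  tr <- kernel_transitions(toy$kernel, 3, reps = 1)
  mdp <- estimate_mdp(tr, n_states = 5, n_actions = 2, gamma = 0.9,
                      min_count = 1, terminal = toy$terminal)
  td <- tidy(mdp)
  expect_true(all(c("s", "a", "s_next", "prob") %in% names(td)))
  row <- td[td$s == 1 & td$a == 1, ]
  expect_equal(row$s_next, 2L)
  expect_equal(row$prob, 1)
  gl <- glance(mdp)
  expect_identical(gl$n_visited, 3L)
  expect_identical(gl$n_transitions, 6)
})
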