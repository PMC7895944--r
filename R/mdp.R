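#' Discretize ventilation events into MDP transitions
#'
#' Each post-onset 4-h bin of an event yields one (state, action) decision:
#' the state is the nearest-centroid patient state of the bin's feature
#' vector, the action is the flat bin index of the clinician's ventilator
#' settings. The final observed bin transitions into the survival or death
#' absorbing state carrying the terminal reward (+100 / -100); all
#' intermediate rewards are 0.
#'
#' @param events Fully imputed event tibble (see [impute_events()]).
#' @param model A `state_model`.
#' @param grid An `action_grid`.
#' @param reward Terminal reward magnitude (default 100).
#' @return Transition tibble: `stay_id`, `step`, `s`, `a`, `r`, `s_next`,
#'   `terminal`. Events with no post-onset bins are skipped.
#' @export
discretize_trajectories <- function(events, model, grid = default_action_grid(),
                                    reward = 100) {
  stopifnot(inherits(model, "state_model"), inherits(grid, "action_grid"))
  ev <- dplyr::filter(tibble::as_tibble(events), .data$rel_bin >= 1)
  if (nrow(ev) == 0) stop("no post-onset bins in events", call. = FALSE)
  ev <- dplyr::arrange(ev, .data$stay_id, .data$rel_bin)
  ev$s <- assign_state(model, ev)
  ev$a <- encode_action(ev$vt_set_ml, ev$ibw_kg, ev$peep_cmh2o, ev$fio2_pct,
                        grid)
  by_id <- ev$stay_id
  last_of_stay <- c(by_id[-1] != by_id[-length(by_id)], TRUE)
  s_next <- c(ev$s[-1], NA_integer_)
  s_next[last_of_stay] <- ifelse(ev$outcome[last_of_stay] == "died",
                                 model$terminal[["death"]],
                                 model$terminal[["survival"]])
  r <- rep(0, nrow(ev))
  r[last_of_stay] <- ifelse(ev$outcome[last_of_stay] == "died",
                            -reward, reward)
  tibble::tibble(
    stay_id = ev$stay_id,
    step = stats::ave(seq_len(nrow(ev)), ev$stay_id,
                      FUN = seq_along),
    s = ev$s, a = ev$a, r = r, s_next = as.integer(s_next),
    terminal = last_of_stay
  )
}

#' Estimate a tabular MDP from observed transitions
#'
#' Maximum-likelihood transition probabilities
#' `T(s, a, s') = N(s, a, s') / N(s, a)` and the reward table obtained by
#' collapsing the terminal-only reward over the next-state dimension:
#' `R(s, a) = sum_{s'} T(s, a, s') * r(s')` with `r(s')` equal to +100 for
#' the survival state, -100 for the death state and 0 elsewhere. Terminal
#' states are absorbing with zero onward reward. Actions observed fewer than
#' `min_count` times in a state are masked as ineligible.
#'
#' The transition tensor is stored sparsely as an `(S * A) x S` matrix (row
#' `(s - 1) * A + a`) so the published scale (650 states x 343 actions) fits
#' comfortably in memory.
#'
#' @param transitions Transition tibble from [discretize_trajectories()].
#' @param n_states Total states including the two terminal states.
#' @param n_actions Flat action count.
#' @param gamma Discount factor in (0, 1].
#' @param min_count Eligibility threshold.
#' @param terminal Named integer vector `c(survival =, death =)`.
#' @param reward Terminal reward magnitude.
#' @return An `mdp_model`.
#' @export
estimate_mdp <- function(transitions, n_states, n_actions, gamma = 0.99,
                         min_count = 5L,
                         terminal = c(survival = n_states - 1L,
                                      death = n_states),
                         reward = 100) {
  stopifnot(nrow(transitions) > 0, gamma > 0, gamma <= 1)
  A <- as.integer(n_actions)
  S <- as.integer(n_states)
  terminal <- stats::setNames(as.integer(terminal), names(terminal))
  cnt <- dplyr::count(transitions, .data$s, .data$a, .data$s_next,
                      name = "n")
  sa_cnt <- dplyr::count(transitions, .data$s, .data$a, name = "n_sa")
  N_sa <- matrix(0, S, A)
  N_sa[cbind(sa_cnt$s, sa_cnt$a)] <- sa_cnt$n_sa
  cnt <- dplyr::left_join(cnt, sa_cnt, by = c("s", "a"))
  rows <- (cnt$s - 1L) * A + cnt$a
  # absorbing terminal self-loops for every action
  term_rows <- as.vector(vapply(terminal, function(t) (t - 1L) * A +
                                  seq_len(A), integer(A)))
  trans <- Matrix::sparseMatrix(
    i = c(rows, term_rows),
    j = c(cnt$s_next, rep(terminal, each = A)),
    x = c(cnt$n / cnt$n_sa, rep(1, 2L * A)),
    dims = c(S * A, S)
  )
  r_next <- numeric(S)
  r_next[terminal[["survival"]]] <- reward
  r_next[terminal[["death"]]] <- -reward
  Rvec <- as.numeric(trans %*% r_next)
  R <- t(matrix(Rvec, nrow = A))
  R[terminal, ] <- 0
  mask <- N_sa >= min_count
  mask[terminal, ] <- FALSE
  visited <- rep(FALSE, S)
  visited[unique(transitions$s)] <- TRUE
  visited[terminal] <- FALSE
  first <- transitions[transitions$step == 1L, ]
  init_dist <- numeric(S)
  tab <- table(first$s)
  init_dist[as.integer(names(tab))] <- as.numeric(tab) / nrow(first)
  structure(list(
    trans = trans, R = R, gamma = gamma, N_sa = N_sa, mask = mask,
    n_states = S, n_actions = A, terminal = terminal, visited = visited,
    init_dist = init_dist, min_count = as.integer(min_count),
    reward = reward
  ), class = "mdp_model")
}

#' @export
print.mdp_model <- function(x, ...) {
  cat("<mdp_model>", x$n_states, "states x", x$n_actions,
      "actions, gamma =", x$gamma, "\n")
  cat("  visited states:", sum(x$visited), " eligible (s,a):", sum(x$mask),
      "\n")
  invisible(x)
}

#' Transition probabilities of one (state, action) pair
#' @param mdp An `mdp_model`.
#' @param s,a State and action index.
#' @return Numeric vector over next states.
#' @export
transition_probs <- function(mdp, s, a) {
  as.numeric(mdp$trans[(s - 1L) * mdp$n_actions + a, ])
}

new_policy_table <- function(pi, kind, mask = NULL) {
  stopifnot(is.matrix(pi))
  structure(pi, class = c("policy_table", "matrix"), kind = kind,
            mask = mask)
}

#' @export
print.policy_table <- function(x, ...) {
  cat("<policy_table>", attr(x, "kind"), ":", nrow(x), "states x", ncol(x),
      "actions\n")
  invisible(x)
}

#' Solve for the optimal policy
#'
#' Model-based value iteration on the estimated `(T, R, gamma)` to a Bellman
#' residual below `tol` (the default), or sample-based tabular Q-learning
#' replayed over the observed transitions; both converge to the same fixed
#' point of the empirical MDP. The greedy policy maximizes Q over eligible
#' actions, ties broken to the lowest flat action index. Terminal states are
#' pinned at value 0; states never visited in the data get value 0 and a
#' uniform policy (flagged); a *visited* state with no eligible action is an
#' error (lower `min_count`).
#'
#' @param mdp An `mdp_model`.
#' @param tol Bellman residual tolerance (value iteration).
#' @param max_iter Iteration cap.
#' @param method `"value_iteration"` or `"q_learning"`.
#' @param transitions Required for Q-learning: the observed transitions.
#' @param passes Replay sweeps for Q-learning.
#' @param alpha Q-learning learning rate: a constant, or a function of the
#'   per-pair visit count `n`; default `10 / (10 + n)`.
#' @param shuffle Shuffle the replay order each pass.
#' @param seed Seed for Q-learning replay.
#' @return List: `q` (S x A matrix), `v`, `policy` (greedy `policy_table`),
#'   `iterations`, `residual`.
#' @export
solve_optimal_policy <- function(mdp, tol = 1e-8, max_iter = 20000L,
                                 method = c("value_iteration", "q_learning"),
                                 transitions = NULL, passes = 500L,
                                 alpha = NULL, shuffle = TRUE, seed = 1L) {
  method <- match.arg(method)
  check_eligibility(mdp)
  if (method == "value_iteration") {
    sol <- value_iteration(mdp, tol, max_iter)
  } else {
    if (is.null(transitions)) {
      stop("q_learning requires the observed transitions", call. = FALSE)
    }
    sol <- q_learn(mdp, transitions, passes = passes, alpha = alpha,
                   shuffle = shuffle, seed = seed)
  }
  q_masked <- sol$q
  q_masked[!mdp$mask] <- -Inf
  greedy <- max.col(q_masked, ties.method = "first")
  pi <- matrix(0, mdp$n_states, mdp$n_actions)
  pi[cbind(seq_len(mdp$n_states), greedy)] <- 1
  open <- !mdp$visited & !is_terminal(mdp)
  pi[open, ] <- 1 / mdp$n_actions
  sol$policy <- new_policy_table(pi, "deterministic-greedy", mask = mdp$mask)
  attr(sol$policy, "unvisited_states") <- which(open)
  sol
}

is_terminal <- function(mdp) seq_len(mdp$n_states) %in% mdp$terminal

check_eligibility <- function(mdp) {
  bad <- which(mdp$visited & rowSums(mdp$mask) == 0)
  if (length(bad) > 0) {
    stop("state(s) with zero eligible actions: ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (lower min_count)", call. = FALSE)
  }
  invisible(TRUE)
}

value_iteration <- function(mdp, tol, max_iter) {
  S <- mdp$n_states
  A <- mdp$n_actions
  Rvec <- as.vector(t(mdp$R))
  solve_states <- mdp$visited
  V <- numeric(S)
  q_masked_template <- ifelse(mdp$mask, 0, -Inf)
  iter <- 0L
  residual <- Inf
  repeat {
    iter <- iter + 1L
    Qvec <- Rvec + mdp$gamma * as.numeric(mdp$trans %*% V)
    Qm <- t(matrix(Qvec, nrow = A)) + q_masked_template
    V_new <- numeric(S)
    best <- max.col(Qm, ties.method = "first")
    V_new[solve_states] <- Qm[cbind(seq_len(S), best)][solve_states]
    residual <- max(abs(V_new - V))
    V <- V_new
    if (residual < tol || iter >= max_iter) break
  }
  Q <- t(matrix(Rvec + mdp$gamma * as.numeric(mdp$trans %*% V), nrow = A))
  list(q = Q, v = V, iterations = iter, residual = residual,
       method = "value_iteration")
}

q_learn <- function(mdp, transitions, passes = 500L, alpha = NULL,
                    shuffle = TRUE, seed = 1L) {
  if (is.null(alpha)) alpha <- function(n) 10 / (10 + n)
  alpha_fun <- if (is.function(alpha)) alpha else function(n) alpha
  S <- mdp$n_states
  A <- mdp$n_actions
  Q <- matrix(0, S, A)
  N <- matrix(0L, S, A)
  term <- is_terminal(mdp)
  mask <- mdp$mask
  s <- transitions$s
  a <- transitions$a
  r <- transitions$r
  sn <- transitions$s_next
  m <- length(s)
  withr::with_seed(seed, {
    for (p in seq_len(passes)) {
      ord <- if (shuffle) sample.int(m) else seq_len(m)
      for (i in ord) {
        si <- s[i]; ai <- a[i]; sni <- sn[i]
        target <- if (term[sni]) r[i] else {
          elig <- mask[sni, ]
          r[i] + mdp$gamma * if (any(elig)) max(Q[sni, elig]) else 0
        }
        N[si, ai] <- N[si, ai] + 1L
        al <- alpha_fun(N[si, ai])
        Q[si, ai] <- Q[si, ai] + al * (target - Q[si, ai])
      }
    }
  })
  V <- numeric(S)
  Qm <- ifelse(mask, Q, -Inf)
  vis <- mdp$visited
  V[vis] <- apply(Qm[vis, , drop = FALSE], 1, max)
  list(q = Q, v = V, iterations = passes, residual = NA_real_,
       method = "q_learning")
}

#' Evaluate a policy on the estimated MDP by linear solve
#'
#' Exact policy evaluation: `V = (I - gamma * P_pi)^(-1) R_pi` over
#' non-terminal states, with `P_pi(s, s') = sum_a pi(a|s) T(s, a, s')` and
#' `R_pi(s) = sum_a pi(a|s) R(s, a)`. Terminal states have value 0; states
#' never visited as transition sources have all-zero transition rows and
#' hence value 0.
#'
#' @param mdp An `mdp_model`.
#' @param policy A `policy_table` (or plain S x A row-stochastic matrix).
#' @param init_dist Initial-state distribution for the scalar performance
#'   return; defaults to the empirical distribution of trajectory-initial
#'   states.
#' @return List: `value` (scalar performance return), `v` (per-state values).
#' @export
evaluate_policy <- function(mdp, policy, init_dist = mdp$init_dist) {
  S <- mdp$n_states
  A <- mdp$n_actions
  stopifnot(nrow(policy) == S, ncol(policy) == A)
  pi_vec <- as.vector(t(policy))
  W <- Matrix::Diagonal(x = pi_vec) %*% mdp$trans
  G <- Matrix::sparseMatrix(i = rep(seq_len(S), each = A),
                            j = seq_len(S * A), x = 1,
                            dims = c(S, S * A))
  P <- as.matrix(G %*% W)
  R_pi <- rowSums(policy * mdp$R)
  nt <- !is_terminal(mdp)
  V <- numeric(S)
  V[nt] <- solve(diag(sum(nt)) - mdp$gamma * P[nt, nt, drop = FALSE],
                 R_pi[nt])
  list(value = sum(init_dist * V), v = V)
}

#' Empirical clinician (behavior) policy
#'
#' `pi_b(a | s) = N(s, a) / N(s)` from the observed transitions. States with
#' no observations (including, formally, the terminal states) get a uniform
#' distribution over the full action grid, with a logged warning.
#'
#' @param transitions Transition tibble.
#' @param n_states,n_actions State/action space sizes.
#' @param quiet Suppress the unvisited-state message.
#' @return A `policy_table` of kind `"behavior-empirical"`.
#' @export
estimate_behavior_policy <- function(transitions, n_states, n_actions,
                                     quiet = FALSE) {
  stopifnot(nrow(transitions) > 0)
  pi <- matrix(0, n_states, n_actions)
  cnt <- dplyr::count(transitions, .data$s, .data$a, name = "n")
  pi[cbind(cnt$s, cnt$a)] <- cnt$n
  tot <- rowSums(pi)
  unvisited <- tot == 0
  pi[!unvisited, ] <- pi[!unvisited, , drop = FALSE] / tot[!unvisited]
  pi[unvisited, ] <- 1 / n_actions
  if (any(unvisited) && !quiet) {
    message(sum(unvisited),
            " state(s) without observed actions set to uniform")
  }
  new_policy_table(pi, "behavior-empirical")
}

#' Soften a deterministic policy
#'
#' Epsilon-greedy softening over the eligible actions of each state: the
#' greedy action keeps mass `1 - epsilon + epsilon / m` and each other
#' eligible action gets `epsilon / m`, with `m` the eligible-action count.
#' A deterministic evaluation target gives degenerate importance-sampling
#' weights, so the learned policy is softened before WIS.
#'
#' @param policy A `policy_table` (typically deterministic-greedy).
#' @param epsilon Softening mass in `[0, 1)`.
#' @param mask Eligibility matrix; defaults to the mask the policy carries,
#'   else to the policy's own support.
#' @return A `policy_table` of kind `"softened"`.
#' @export
soften_policy <- function(policy, epsilon, mask = NULL) {
  stopifnot(epsilon >= 0, epsilon < 1)
  if (is.null(mask)) mask <- attr(policy, "mask")
  if (is.null(mask)) mask <- policy > 0
  m <- rowSums(mask)
  out <- unclass(policy)
  rows <- m > 0
  out[rows, ] <- (1 - epsilon) * out[rows, , drop = FALSE] +
    epsilon * mask[rows, , drop = FALSE] / m[rows]
  new_policy_table(out, "softened", mask = mask)
}

#' Uniform random policy over eligible actions
#'
#' @param mdp An `mdp_model`.
#' @return A `policy_table` of kind `"random"`; masked actions get zero
#'   mass, unvisited states are uniform over the full grid.
#' @export
random_policy <- function(mdp) {
  pi <- mdp$mask / pmax(rowSums(mdp$mask), 1)
  pi[rowSums(mdp$mask) == 0, ] <- 1 / mdp$n_actions
  new_policy_table(pi, "random", mask = mdp$mask)
}

#' Temporal-difference evaluation of the clinician policy
#'
#' On-policy TD(0) over the observed `(s, r, s')` tuples, replayed for
#' `passes` sweeps with a decreasing learning rate; converges to the batch
#' fixed point, i.e. the linear-solve evaluation of the empirical behavior
#' policy on the empirical MDP. The scalar value weights the state values by
#' the empirical initial-state distribution.
#'
#' @param transitions Transition tibble.
#' @param gamma Discount factor.
#' @param n_states Total number of states.
#' @param terminal Terminal state ids (value pinned at 0).
#' @param passes Replay sweeps.
#' @param alpha Learning rate: constant or function of the per-state visit
#'   count; default `5 / (5 + n)`.
#' @param shuffle Shuffle replay order each pass.
#' @param seed Replay seed.
#' @return List: `value`, `v` (per-state), `passes`.
#' @export
evaluate_clinician_td <- function(transitions, gamma, n_states,
                                  terminal = c(n_states - 1L, n_states),
                                  passes = 200L, alpha = NULL,
                                  shuffle = TRUE, seed = 1L) {
  stopifnot(nrow(transitions) > 0)
  if (is.null(alpha)) alpha <- function(n) 5 / (5 + n)
  alpha_fun <- if (is.function(alpha)) alpha else function(n) alpha
  V <- numeric(n_states)
  Ncnt <- integer(n_states)
  term <- seq_len(n_states) %in% terminal
  s <- transitions$s
  r <- transitions$r
  sn <- transitions$s_next
  m <- length(s)
  withr::with_seed(seed, {
    for (p in seq_len(passes)) {
      ord <- if (shuffle) sample.int(m) else seq_len(m)
      for (i in ord) {
        si <- s[i]
        target <- if (term[sn[i]]) r[i] else r[i] + gamma * V[sn[i]]
        Ncnt[si] <- Ncnt[si] + 1L
        V[si] <- V[si] + alpha_fun(Ncnt[si]) * (target - V[si])
      }
    }
  })
  first <- transitions[transitions$step == 1L, ]
  init <- numeric(n_states)
  tab <- table(first$s)
  init[as.integer(names(tab))] <- as.numeric(tab) / nrow(first)
  list(value = sum(init * V), v = V, passes = passes)
}

#' @export
tidy.mdp_model <- function(x, ...) {
  tr <- Matrix::summary(x$trans)
  A <- x$n_actions
  tibble::tibble(
    s = as.integer((tr$i - 1L) %/% A + 1L),
    a = as.integer((tr$i - 1L) %% A + 1L),
    s_next = as.integer(tr$j),
    prob = tr$x
  )
}

#' @export
glance.mdp_model <- function(x, ...) {
  tibble::tibble(
    n_states = x$n_states, n_actions = x$n_actions, gamma = x$gamma,
    n_visited = sum(x$visited), n_eligible = sum(x$mask),
    n_transitions = sum(x$N_sa)
  )
}
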