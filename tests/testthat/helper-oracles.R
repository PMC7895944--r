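# Independent oracles: exhaustive policy enumeration and closed-form policy
# evaluation by linear solve, written against raw dense kernels so they share
# no code with the package's sparse solvers.

# V^pi by linear solve on a dense kernel; pi is a deterministic action vector
# or a row-stochastic matrix over the n_phys physiologic states.
oracle_policy_value <- function(kernel, R, gamma, pi, n_phys) {
  A <- dim(kernel)[2]
  if (is.vector(pi) && !is.matrix(pi)) {
    pm <- matrix(0, n_phys, A)
    pm[cbind(seq_len(n_phys), pi)] <- 1
    pi <- pm
  }
  P <- matrix(0, n_phys, n_phys)
  r <- numeric(n_phys)
  for (s in seq_len(n_phys)) {
    for (a in seq_len(A)) {
      P[s, ] <- P[s, ] + pi[s, a] * kernel[s, a, seq_len(n_phys)]
      r[s] <- r[s] + pi[s, a] * R[s, a]
    }
  }
  solve(diag(n_phys) - gamma * P, r)
}

# V* and Q* by brute-force enumeration of all |A|^n deterministic policies.
oracle_enumerate <- function(kernel, R, gamma, n_phys) {
  A <- dim(kernel)[2]
  combos <- expand.grid(rep(list(seq_len(A)), n_phys))
  best_v <- rep(-Inf, n_phys)
  for (i in seq_len(nrow(combos))) {
    v <- oracle_policy_value(kernel, R, gamma, as.integer(combos[i, ]),
                             n_phys)
    best_v <- pmax(best_v, v)
  }
  q <- matrix(0, n_phys, A)
  for (s in seq_len(n_phys)) {
    for (a in seq_len(A)) {
      q[s, a] <- R[s, a] + gamma * sum(kernel[s, a, seq_len(n_phys)] * best_v)
    }
  }
  list(v = best_v, q = q)
}

# Wrap a dense kernel + reward table as an mdp_model so the package solvers
# can run on exactly specified dynamics.
make_mdp <- function(kernel, R, gamma, n_phys,
                     terminal = c(survival = n_phys + 1L,
                                  death = n_phys + 2L)) {
  S <- dim(kernel)[1]
  A <- dim(kernel)[2]
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (s in seq_len(S)) {
    for (a in seq_len(A)) {
      nz <- which(kernel[s, a, ] > 0)
      i <- c(i, rep((s - 1L) * A + a, length(nz)))
      j <- c(j, nz)
      x <- c(x, kernel[s, a, nz])
    }
  }
  trans <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(S * A, S))
  mask <- matrix(TRUE, S, A)
  mask[terminal, ] <- FALSE
  visited <- rep(TRUE, S)
  visited[terminal] <- FALSE
  init <- numeric(S)
  init[seq_len(n_phys)] <- 1 / n_phys
  structure(list(
    trans = trans, R = R, gamma = gamma,
    N_sa = matrix(100L, S, A), mask = mask, n_states = S, n_actions = A,
    terminal = terminal, visited = visited, init_dist = init,
    min_count = 1L, reward = 100
  ), class = "mdp_model")
}

# Transitions whose empirical frequencies reproduce the kernel exactly:
# probabilities must be multiples of 1/reps.
kernel_transitions <- function(kernel, n_phys, reps = 10L,
                               terminal = c(survival = n_phys + 1L,
                                            death = n_phys + 2L)) {
  A <- dim(kernel)[2]
  S <- dim(kernel)[1]
  rows <- list()
  id <- 0L
  for (s in seq_len(n_phys)) {
    for (a in seq_len(A)) {
      counts <- kernel[s, a, ] * reps
      stopifnot(max(abs(counts - round(counts))) < 1e-9)
      counts <- round(counts)
      for (sn in which(counts > 0)) {
        for (rep_i in seq_len(counts[sn])) {
          id <- id + 1L
          rows[[id]] <- data.frame(
            stay_id = sprintf("t%05d", id), step = 1L, s = s, a = a,
            s_next = sn,
            r = if (sn == terminal[["death"]]) -100
                else if (sn == terminal[["survival"]]) 100 else 0,
            terminal = sn %in% terminal
          )
        }
      }
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}

# Deterministic 3-state chain: action 1 advances toward survival, action 2
# jumps straight to death. All transition entries are 0 or 1.
toy_chain_kernel <- function() {
  n <- 3L
  S <- n + 2L
  k <- array(0, dim = c(S, 2L, S))
  k[1, 1, 2] <- 1; k[2, 1, 3] <- 1; k[3, 1, 4] <- 1  # -> survival (state 4)
  k[1, 2, 5] <- 1; k[2, 2, 5] <- 1; k[3, 2, 5] <- 1  # -> death (state 5)
  for (t in 4:5) k[t, , t] <- 1
  R <- matrix(0, S, 2L)
  R[3, 1] <- 100
  R[, 2] <- c(-100, -100, -100, 0, 0)
  list(kernel = k, R = R, n_phys = n,
       terminal = c(survival = 4L, death = 5L))
}

# Stochastic 3-state, 2-action toy with tenth-valued probabilities.
toy_stochastic_kernel <- function() {
  n <- 3L
  S <- n + 2L
  k <- array(0, dim = c(S, 2L, S))
  k[1, 1, ] <- c(0.2, 0.5, 0.1, 0.2, 0.0)
  k[1, 2, ] <- c(0.1, 0.2, 0.3, 0.1, 0.3)
  k[2, 1, ] <- c(0.0, 0.3, 0.3, 0.3, 0.1)
  k[2, 2, ] <- c(0.4, 0.1, 0.1, 0.0, 0.4)
  k[3, 1, ] <- c(0.1, 0.1, 0.1, 0.6, 0.1)
  k[3, 2, ] <- c(0.2, 0.2, 0.2, 0.1, 0.3)
  for (t in 4:5) k[t, , t] <- 1
  R <- matrix(0, S, 2L)
  for (s in 1:3) for (a in 1:2) R[s, a] <- 100 * (k[s, a, 4] - k[s, a, 5])
  list(kernel = k, R = R, n_phys = n,
       terminal = c(survival = 4L, death = 5L))
}

# 4-state, 2-action toy for OPE calibration, tenth-valued probabilities.
toy_ope_kernel <- function() {
  n <- 4L
  S <- n + 2L
  k <- array(0, dim = c(S, 2L, S))
  k[1, 1, ] <- c(0.2, 0.3, 0.2, 0.1, 0.2, 0.0)
  k[1, 2, ] <- c(0.1, 0.1, 0.2, 0.2, 0.1, 0.3)
  k[2, 1, ] <- c(0.1, 0.2, 0.3, 0.1, 0.3, 0.0)
  k[2, 2, ] <- c(0.2, 0.2, 0.1, 0.2, 0.1, 0.2)
  k[3, 1, ] <- c(0.1, 0.1, 0.2, 0.3, 0.2, 0.1)
  k[3, 2, ] <- c(0.3, 0.1, 0.1, 0.1, 0.0, 0.4)
  k[4, 1, ] <- c(0.1, 0.1, 0.1, 0.2, 0.4, 0.1)
  k[4, 2, ] <- c(0.2, 0.2, 0.1, 0.1, 0.1, 0.3)
  for (t in 5:6) k[t, , t] <- 1
  R <- matrix(0, S, 2L)
  for (s in 1:4) for (a in 1:2) R[s, a] <- 100 * (k[s, a, 5] - k[s, a, 6])
  list(kernel = k, R = R, n_phys = n,
       terminal = c(survival = 5L, death = 6L))
}

# Wrap a raw kernel as a ground_truth_mdp-alike for the package simulator.
as_ground_truth <- function(toy, gamma = 0.95) {
  n <- toy$n_phys
  structure(list(
    n_states = n, n_actions = dim(toy$kernel)[2], gamma = gamma,
    kernel = toy$kernel, R = toy$R,
    terminal = toy$terminal,
    init_dist = c(rep(1 / n, n), 0, 0),
    reward = 100
  ), class = "ground_truth_mdp")
}

# Monte-Carlo standard error of a WIS estimate from per-trajectory weights
# and returns (delta-method for the ratio estimator).
wis_mc_se <- function(w, g) {
  wbar <- mean(w)
  est <- sum(w * g) / sum(w)
  sqrt(sum((w / wbar)^2 * (g - est)^2)) / length(w)
}
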