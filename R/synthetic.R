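#' Generate a ground-truth MDP for synthetic cohorts
#'
#' Builds a known tabular MDP so that every pipeline stage has an oracle:
#' the true transition kernel, the true optimal and behavior policy values
#' (computed by linear solve at construction) and the per-state feature
#' emission model. Per (state, action) the kernel mixes a Dirichlet draw
#' over next physiologic states with severity-linked absorption into the
#' death/survival terminal states; a per-(state, action) "quality" score
#' shifts the death odds so that action choice matters. A scalar severity
#' per state drives both the death-absorption odds and the emission mean of
#' the first feature, so features are informative of prognosis.
#'
#' The behavior (clinician-like) policy is a softmax of the optimal Q values
#' perturbed by Gaussian noise, at temperature `tau` (in reward points):
#' mostly sensible, sometimes suboptimal; `tau = 0` is exactly greedy.
#'
#' @param n_states Physiologic states (>= 2).
#' @param grid An `action_grid` (defaults to the 343-action grid; reduced
#'   grids are convenient for simulation studies).
#' @param manifest Feature manifest for the emission model.
#' @param gamma Discount factor.
#' @param dirichlet Dirichlet concentration for next-state draws (sparse,
#'   ICU-like branching at the 0.5 default).
#' @param tau Behavior softmax temperature on per-state standardized action
#'   preferences; 0 is exactly greedy, 2 (default) is a mostly-sensible,
#'   sometimes-suboptimal clinician.
#' @param behavior_noise SD of the preference perturbation for the behavior
#'   policy (standardized scale).
#' @param absorb_base,absorb_slope Per-step absorption probability
#'   `absorb_base + absorb_slope * severity`.
#' @param drift Strength of the quality-linked tilt of the next-state
#'   distribution toward lower-severity states (treatment affects disease
#'   progression, not only terminal mortality).
#' @param emission_mean_sd Between-state SD of emission means (within-state
#'   noise SD is 1, so this is the cluster-separation scale).
#' @param reward Terminal reward magnitude.
#' @param seed Seed; construction is deterministic given it.
#' @return A `ground_truth_mdp`.
#' @export
generate_ground_truth <- function(n_states = 20L,
                                  grid = default_action_grid(),
                                  manifest = default_manifest(),
                                  gamma = 0.99, dirichlet = 0.5, tau = 2,
                                  behavior_noise = 0.25, drift = 2,
                                  absorb_base = 0.08, absorb_slope = 0.17,
                                  emission_mean_sd = 5, reward = 100,
                                  seed = 1L) {
  stopifnot(n_states >= 2)
  n_states <- as.integer(n_states)
  validate_manifest(manifest)
  A <- n_actions(grid)
  S <- n_states + 2L
  term <- c(survival = n_states + 1L, death = n_states + 2L)
  gt <- withr::with_seed(seed, {
    severity <- sort(stats::runif(n_states, 0.05, 0.95))
    # each state has one designated beneficial regime (quality 1); the
    # remaining actions are comparably mediocre, so the action effect on the
    # death odds is identifiable from cohorts of realistic size
    quality <- matrix(stats::runif(n_states * A, 0, 0.5), n_states, A)
    quality[cbind(seq_len(n_states),
                  sample.int(A, n_states, replace = TRUE))] <- 1
    p_abs <- absorb_base + absorb_slope * severity
    kernel <- array(0, dim = c(S, A, S))
    for (s in seq_len(n_states)) {
      for (a in seq_len(A)) {
        d_death <- stats::plogis(2.5 * (severity[s] - 0.5) + 2 -
                                   4 * quality[s, a])
        dir <- stats::rgamma(n_states, shape = dirichlet)
        # treatment quality also drives disease progression: good regimes
        # tilt the next-state mix toward lower-severity states
        dir <- dir * exp(drift * (quality[s, a] - 0.5) * (0.5 - severity))
        dir <- dir / sum(dir)
        kernel[s, a, seq_len(n_states)] <- (1 - p_abs[s]) * dir
        kernel[s, a, term[["survival"]]] <- p_abs[s] * (1 - d_death)
        kernel[s, a, term[["death"]]] <- p_abs[s] * d_death
      }
    }
    kernel[term, , ] <- 0
    for (t in term) kernel[t, , t] <- 1
    d <- nrow(manifest)
    emission_mean <- matrix(stats::rnorm(n_states * d, sd = emission_mean_sd),
                            n_states, d)
    emission_mean[, 1] <- (severity - 0.5) * 2 * emission_mean_sd
    noise <- matrix(stats::rnorm(n_states * A, sd = behavior_noise),
                    n_states, A)
    list(severity = severity, quality = quality, kernel = kernel,
         emission_mean = emission_mean, noise = noise)
  })
  R <- reward * (gt$kernel[, , term[["survival"]]] -
                   gt$kernel[, , term[["death"]]])
  R[term, ] <- 0
  sol <- dense_value_iteration(gt$kernel, R, gamma, n_states, A)
  behavior <- matrix(1 / A, S, A)
  # action preferences are standardized per state before the softmax so the
  # temperature acts on a comparable scale across states (raw Q values span
  # +/-100 and would make any fixed tau either greedy or uniform)
  qn <- sol$q[seq_len(n_states), , drop = FALSE]
  qn <- (qn - rowMeans(qn)) / pmax(apply(qn, 1, stats::sd), 1e-9)
  behavior[seq_len(n_states), ] <-
    softmax_rows(qn + gt$noise[seq_len(n_states), , drop = FALSE], tau)
  init_dist <- c(rep(1 / n_states, n_states), 0, 0)
  obj <- structure(list(
    n_states = as.integer(n_states), n_actions = A, grid = grid,
    manifest = manifest, gamma = gamma, tau = tau,
    kernel = gt$kernel, R = R, q_star = sol$q, v_star = sol$v,
    behavior = new_policy_table(behavior, "behavior-true"),
    severity = gt$severity, quality = gt$quality,
    emission_mean = gt$emission_mean, emission_sd = 1,
    terminal = term, init_dist = init_dist, reward = reward,
    seed = as.integer(seed)
  ), class = "ground_truth_mdp")
  vb <- true_policy_value(obj, behavior)
  obj$v_behavior <- vb$v
  obj$value_behavior <- vb$value
  obj$value_star <- sum(init_dist * c(sol$v, 0, 0)[seq_len(S)])
  obj
}

softmax_rows <- function(x, tau) {
  if (tau <= 0) {
    out <- matrix(0, nrow(x), ncol(x))
    out[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))] <- 1
    return(out)
  }
  z <- x / tau
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# dense value iteration on a full kernel; terminal states pinned at 0
dense_value_iteration <- function(kernel, R, gamma, n_states, A,
                                  tol = 1e-10, max_iter = 100000L) {
  S <- dim(kernel)[1]
  V <- numeric(S)
  Rn <- R[seq_len(n_states), , drop = FALSE]
  Tm <- matrix(aperm(kernel, c(3, 2, 1)), nrow = S)  # S x (A*S), col-major
  repeat {
    Q <- matrix(crossprod(Tm, V), nrow = A)           # A x S
    Q <- t(Q)[seq_len(n_states), , drop = FALSE] * gamma + Rn
    V_new <- numeric(S)
    V_new[seq_len(n_states)] <- apply(Q, 1, max)
    if (max(abs(V_new - V)) < tol) {
      V <- V_new
      break
    }
    V <- V_new
    max_iter <- max_iter - 1L
    if (max_iter <= 0L) break
  }
  Qfull <- matrix(0, S, A)
  Qfull[seq_len(n_states), ] <- Q
  list(q = Qfull, v = V)
}

#' @export
print.ground_truth_mdp <- function(x, ...) {
  cat("<ground_truth_mdp>", x$n_states, "states x", x$n_actions,
      "actions, gamma =", x$gamma, "\n")
  cat("  V* =", format(x$value_star), " V^behavior =",
      format(x$value_behavior), "\n")
  invisible(x)
}

#' Exact policy value on the true MDP
#'
#' Linear-solve policy evaluation on the true kernel with the terminal
#' +/-100 reward scheme: the oracle against which off-policy estimates and
#' recovered policies are judged.
#'
#' @param gt A `ground_truth_mdp`.
#' @param policy Row-stochastic matrix over all states (or just the
#'   physiologic states) x actions.
#' @return List: `value` (initial-distribution-weighted scalar), `v`
#'   (per-state values including terminal zeros).
#' @export
true_policy_value <- function(gt, policy) {
  n <- gt$n_states
  A <- gt$n_actions
  if (nrow(policy) == n + 2L) policy <- policy[seq_len(n), , drop = FALSE]
  stopifnot(nrow(policy) == n, ncol(policy) == A)
  P <- matrix(0, n, n)
  R_pi <- numeric(n)
  for (s in seq_len(n)) {
    P[s, ] <- policy[s, ] %*% gt$kernel[s, , seq_len(n)]
    R_pi[s] <- sum(policy[s, ] * gt$R[s, ])
  }
  M <- diag(n) - gt$gamma * P
  if (abs(det(M)) < 1e-300) {
    stop("singular policy-evaluation system (gamma = 1 with a ",
         "non-absorbing recurrent class)", call. = FALSE)
  }
  Vn <- solve(M, R_pi)
  v <- c(Vn, 0, 0)
  list(value = sum(gt$init_dist * v), v = v)
}

#' Simulate raw trajectories from a known MDP
#'
#' Rolls out `n` trajectories under `policy` on the true kernel, recording
#' `(s, a, r, s_next)` per step with the terminal +/-100 reward on the
#' absorbing transition. Useful for estimator-calibration studies where the
#' feature-emission layer is not needed.
#'
#' @param gt A `ground_truth_mdp`.
#' @param policy Row-stochastic policy over the physiologic states.
#' @param n Number of trajectories.
#' @param max_steps Hard cap on trajectory length.
#' @param seed Seed.
#' @return Transition tibble (`stay_id`, `step`, `s`, `a`, `r`, `s_next`,
#'   `terminal`).
#' @export
simulate_mdp_trajectories <- function(gt, policy, n, max_steps = 200L,
                                      seed = 1L) {
  nst <- gt$n_states
  A <- gt$n_actions
  if (nrow(policy) == nst + 2L) policy <- policy[seq_len(nst), , drop = FALSE]
  term <- gt$terminal
  withr::with_seed(seed, {
    state <- sample.int(nst, n, replace = TRUE,
                        prob = gt$init_dist[seq_len(nst)])
    active <- rep(TRUE, n)
    out_s <- out_a <- out_sn <- out_id <- out_t <- vector("list", max_steps)
    for (t in seq_len(max_steps)) {
      idx <- which(active)
      if (length(idx) == 0) break
      a <- vapply(state[idx], function(s) {
        sample.int(A, 1, prob = policy[s, ])
      }, integer(1))
      sn <- vapply(seq_along(idx), function(i) {
        sample.int(nst + 2L, 1, prob = gt$kernel[state[idx[i]], a[i], ])
      }, integer(1))
      out_id[[t]] <- idx
      out_t[[t]] <- rep(t, length(idx))
      out_s[[t]] <- state[idx]
      out_a[[t]] <- a
      out_sn[[t]] <- sn
      absorbed <- sn %in% term
      active[idx[absorbed]] <- FALSE
      state[idx[!absorbed]] <- sn[!absorbed]
    }
    sn_all <- unlist(out_sn)
    tr <- tibble::tibble(
      stay_id = sprintf("traj%06d", unlist(out_id)),
      step = unlist(out_t),
      s = unlist(out_s),
      a = unlist(out_a),
      s_next = sn_all,
      terminal = sn_all %in% term,
      r = ifelse(sn_all == term[["death"]], -gt$reward,
                 ifelse(sn_all == term[["survival"]], gt$reward, 0))
    )
    dplyr::arrange(tr, .data$stay_id, .data$step)
  })
}

#' Simulate an ICU-like cohort with known ground truth
#'
#' Rolls out stays under the ground truth's behavior policy until absorption
#' or `max_bins` post-onset bins, emitting per-bin features from the
#' per-state Gaussian emission model and ventilator settings sampled
#' uniformly inside the behavior action's bin ranges (so settings decode
#' back to the generating action). Stays still unresolved at the end of the
#' observation window are continued, unrecorded, until absorption to obtain
#' the outcome -- mirroring mortality that is ascertained after the 72-h
#' window. Missingness (MCAR, or MAR driven by the first feature) and gross
#' outliers are then injected into the feature cells.
#'
#' The table conforms to the trajectory schema: one pre-onset bin
#' (`time_bin` 0, features only) plus post-onset bins from 1, settings
#' present from onset.
#'
#' @param gt A `ground_truth_mdp`.
#' @param n_stays Number of stays.
#' @param max_bins Post-onset observation bins (default 18 = 72 h).
#' @param missing_rate Per-cell missingness probability.
#' @param mechanism `"MCAR"` or `"MAR"` (missingness of every feature but
#'   the first driven by the first feature's value).
#' @param outlier_rate Per-cell gross-outlier probability (cell scaled x8).
#' @param seed Seed.
#' @return List of class `synthetic_cohort`: `table` (trajectory tibble),
#'   `truth` (per-bin true latent states) and `per_stay` (outcome,
#'   absorption step, discounted true return).
#' @export
simulate_cohort <- function(gt, n_stays = 5000L, max_bins = 18L,
                            missing_rate = 0.10,
                            mechanism = c("MCAR", "MAR"),
                            outlier_rate = 0.01, seed = 1L) {
  mechanism <- match.arg(mechanism)
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            outlier_rate >= 0, outlier_rate <= 1)
  nst <- gt$n_states
  A <- gt$n_actions
  term <- gt$terminal
  d <- nrow(gt$manifest)
  feats <- gt$manifest$feature
  caps <- list(vt_per_kg = 18, peep = 18, fio2 = 80)
  withr::with_seed(seed, {
    sex <- ifelse(stats::runif(n_stays) < 0.6, "male", "female")
    height <- pmax(stats::rnorm(n_stays, ifelse(sex == "male", 170, 160), 10),
                   120)
    age <- stats::runif(n_stays, 19, 90)
    ibw <- ideal_body_weight(sex, height)

    # latent rollout (behavior policy), observed up to max_bins
    state <- sample.int(nst, n_stays, replace = TRUE,
                        prob = gt$init_dist[seq_len(nst)])
    states_mat <- matrix(NA_integer_, n_stays, max_bins)
    actions_mat <- matrix(NA_integer_, n_stays, max_bins)
    absorb_state <- rep(NA_integer_, n_stays)
    absorb_step <- rep(NA_integer_, n_stays)
    active <- rep(TRUE, n_stays)
    t <- 0L
    while (any(active) && t < 500L) {
      t <- t + 1L
      idx <- which(active)
      a <- vapply(state[idx], function(s) {
        sample.int(A, 1, prob = gt$behavior[s, ])
      }, integer(1))
      sn <- vapply(seq_along(idx), function(i) {
        sample.int(nst + 2L, 1, prob = gt$kernel[state[idx[i]], a[i], ])
      }, integer(1))
      if (t <= max_bins) {
        states_mat[cbind(idx, t)] <- state[idx]
        actions_mat[cbind(idx, t)] <- a
      }
      absorbed <- sn %in% term
      absorb_state[idx[absorbed]] <- sn[absorbed]
      absorb_step[idx[absorbed]] <- t
      active[idx[absorbed]] <- FALSE
      state[idx[!absorbed]] <- sn[!absorbed]
    }
    absorb_state[is.na(absorb_state)] <- term[["survival"]]
    absorb_step[is.na(absorb_step)] <- 500L
    outcome <- ifelse(absorb_state == term[["death"]], "died", "survived")
    n_obs <- pmin(absorb_step, max_bins)

    # long format: pre-onset bin 0 + post-onset bins
    stay_idx <- rep(seq_len(n_stays), n_obs + 1L)
    time_bin <- unlist(lapply(n_obs, function(k) 0:k))
    post <- time_bin >= 1L
    true_state <- integer(length(stay_idx))
    true_state[post] <- states_mat[cbind(stay_idx[post], time_bin[post])]
    true_state[!post] <- states_mat[cbind(stay_idx[!post], 1L)]
    action <- rep(NA_integer_, length(stay_idx))
    action[post] <- actions_mat[cbind(stay_idx[post], time_bin[post])]

    X <- gt$emission_mean[true_state, , drop = FALSE] +
      matrix(stats::rnorm(length(true_state) * d, sd = gt$emission_sd),
             ncol = d)
    colnames(X) <- feats

    # settings sampled inside the chosen action's bin ranges
    vt_set <- peep <- fio2 <- rep(NA_real_, length(stay_idx))
    dec <- decode_action(action[post], gt$grid)
    runifbin <- function(lo, hi, cap) {
      hi <- pmin(hi, cap)
      lo + stats::runif(length(lo)) * (hi - lo)
    }
    vtkg <- runifbin(dec$vt_per_kg_lo, dec$vt_per_kg_hi, caps$vt_per_kg)
    vt_set[post] <- vtkg * ibw[stay_idx[post]]
    peep[post] <- runifbin(dec$peep_lo, dec$peep_hi, caps$peep)
    fio2[post] <- runifbin(dec$fio2_lo, dec$fio2_hi, caps$fio2)

    # missingness and outliers on feature cells
    n_cells <- length(true_state) * d
    if (missing_rate > 0) {
      if (mechanism == "MCAR") {
        miss <- matrix(stats::runif(n_cells) < missing_rate,
                       ncol = d)
      } else {
        z1 <- scale(X[, 1])[, 1]
        p <- stats::plogis(stats::qlogis(missing_rate) + 1.5 * z1)
        miss <- matrix(stats::runif(n_cells) < p, ncol = d)
        miss[, 1] <- FALSE  # the driver stays observed
      }
      X[miss] <- NA_real_
    }
    if (outlier_rate > 0) {
      out_mask <- matrix(stats::runif(n_cells) < outlier_rate, ncol = d)
      X[out_mask & !is.na(X)] <- X[out_mask & !is.na(X)] * 8
    }

    stay_id <- sprintf("sim%06d", stay_idx)
    table <- tibble::as_tibble(as.data.frame(X))
    table <- dplyr::bind_cols(
      tibble::tibble(
        stay_id = stay_id, time_bin = as.integer(time_bin),
        vt_set_ml = vt_set, peep_cmh2o = peep, fio2_pct = fio2,
        height_cm = height[stay_idx], sex = sex[stay_idx],
        age_years = age[stay_idx],
        extubation = FALSE, niv_start = FALSE, suppl_o2 = FALSE,
        withdrawal = FALSE,
        outcome = outcome[stay_idx]
      ),
      table
    )
    truth <- tibble::tibble(stay_id = stay_id,
                            time_bin = as.integer(time_bin),
                            true_state = true_state,
                            true_action = action)
    per_stay <- tibble::tibble(
      stay_id = sprintf("sim%06d", seq_len(n_stays)),
      outcome = outcome,
      absorb_step = absorb_step,
      n_observed_bins = n_obs,
      true_return = ifelse(outcome == "died", -gt$reward, gt$reward) *
        gt$gamma^(absorb_step - 1)
    )
    structure(list(table = table, truth = truth, per_stay = per_stay,
                   seed = as.integer(seed)),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$per_stay), "stays,", nrow(x$table),
      "rows\n")
  invisible(x)
}

#' Map a cluster-space policy onto the true latent states
#'
#' For validation against the ground truth: each true latent state is mapped
#' to the learned cluster that the majority of its simulated bins were
#' assigned to, and the (greedy) learned action for that cluster becomes the
#' action recommended in the true state. The result can be fed to
#' [true_policy_value()].
#'
#' @param gt A `ground_truth_mdp`.
#' @param assignments Tibble pairing `true_state` with the learned `s` for
#'   simulated decision bins.
#' @param policy Learned `policy_table` over cluster states.
#' @return Deterministic policy matrix over the true states.
#' @export
induced_true_policy <- function(gt, assignments, policy) {
  greedy <- max.col(unclass(policy), ties.method = "first")
  pi_true <- matrix(0, gt$n_states, gt$n_actions)
  for (s in seq_len(gt$n_states)) {
    rows <- assignments$true_state == s
    if (!any(rows)) {
      pi_true[s, ] <- gt$behavior[s, ]  # unseen true state: defer
      next
    }
    cl <- assignments$s[rows]
    maj <- as.integer(names(sort(table(cl), decreasing = TRUE))[1])
    pi_true[s, greedy[maj]] <- 1
  }
  pi_true
}
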