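#' Weighted-importance-sampling off-policy evaluation
#'
#' Estimates the performance return of a target policy `pi_e` from
#' trajectories generated under the behavior policy `pi_b`.
#'
#' * `"trajectory"` WIS: per-trajectory weight
#'   `w_i = prod_t pi_e(a_t | s_t) / pi_b(a_t | s_t)`, return
#'   `G_i = sum_t gamma^(t-1) r_t`, estimate `sum(w G) / sum(w)`.
#' * `"stepwise"` (default): consistent weighted per-decision importance
#'   sampling -- per-step self-normalized cumulative weights with per-step
#'   reward accumulation. This variance-reduced estimator stands in for an
#'   unspecified multiplicative control variate and is labelled as such via
#'   the `estimator` field.
#'
#' Trajectories containing a step with `pi_b(a|s) = 0` get weight zero (their
#' count is reported); if every weight is zero the estimate is undefined and
#' an error is raised.
#'
#' @param trajectories Transition tibble (`stay_id`, `step`, `s`, `a`, `r`).
#' @param policy_e,policy_b Target and behavior `policy_table`s (S x A).
#' @param gamma Discount factor.
#' @param estimator `"stepwise"` or `"trajectory"`.
#' @return An `ope_result`: `estimate`, per-trajectory `weights` and
#'   `returns`, effective sample size `ess`, `n_zero_weight`; bootstrap
#'   `bounds` are `NULL` until [bootstrap_bounds()] is used.
#' @export
wis_evaluate <- function(trajectories, policy_e, policy_b, gamma,
                         estimator = c("stepwise", "trajectory")) {
  estimator <- match.arg(estimator)
  parts <- wis_parts(trajectories, policy_e, policy_b, gamma)
  est <- wis_estimate_from_parts(parts, estimator, gamma)
  structure(list(
    estimate = est,
    estimator = estimator,
    weights = parts$W,
    returns = parts$G,
    cum_rho = parts$cum_rho,
    disc_rew = parts$disc_rew,
    gamma = gamma,
    n_trajectories = parts$n,
    ess = sum(parts$W)^2 / sum(parts$W^2),
    n_zero_weight = sum(parts$W == 0),
    bounds = NULL,
    boot = NULL
  ), class = "ope_result")
}

# Per-trajectory importance-weighting building blocks shared by the point
# estimate and the bootstrap: cumulative weight and discounted reward
# matrices (trajectories x steps), with the final cumulative weight carried
# past termination (the terminal state is absorbing with zero reward and a
# probability-one dummy action under both policies).
wis_parts <- function(trajectories, policy_e, policy_b, gamma) {
  tr <- dplyr::arrange(tibble::as_tibble(trajectories), .data$stay_id,
                       .data$step)
  id <- match(tr$stay_id, unique(tr$stay_id))
  t_step <- stats::ave(seq_along(id), id, FUN = seq_along)
  n <- max(id)
  Tmax <- max(t_step)
  pe <- policy_e[cbind(tr$s, tr$a)]
  pb <- policy_b[cbind(tr$s, tr$a)]
  rho <- ifelse(pb == 0, 0, pe / pb)
  Rho <- matrix(1, n, Tmax)
  Rho[cbind(id, t_step)] <- rho
  cum_rho <- t(apply(Rho, 1, cumprod))
  if (Tmax == 1) cum_rho <- matrix(cum_rho, ncol = 1)
  Rew <- matrix(0, n, Tmax)
  Rew[cbind(id, t_step)] <- tr$r
  disc <- gamma^(seq_len(Tmax) - 1)
  disc_rew <- sweep(Rew, 2, disc, "*")
  W <- cum_rho[, Tmax]
  G <- as.numeric(disc_rew %*% rep(1, Tmax))
  list(n = n, cum_rho = cum_rho, disc_rew = disc_rew, W = W, G = G)
}

wis_estimate_from_parts <- function(parts, estimator, gamma) {
  if (all(parts$W == 0) && all(colSums(parts$cum_rho) == 0)) {
    stop("undefined estimate: all importance weights are zero", call. = FALSE)
  }
  if (estimator == "trajectory") {
    if (sum(parts$W) == 0) {
      stop("undefined estimate: all importance weights are zero",
           call. = FALSE)
    }
    sum(parts$W * parts$G) / sum(parts$W)
  } else {
    num <- colSums(parts$cum_rho * parts$disc_rew)
    den <- colSums(parts$cum_rho)
    sum(ifelse(den > 0, num / den, 0))
  }
}

#' Bootstrap confidence bounds for a WIS estimate
#'
#' Resamples whole trajectories with replacement `B` times, recomputes the
#' WIS estimate per resample and reports percentile bounds: at level `L` the
#' lower bound is the `(1 - L)` quantile and the upper bound the `L`
#' quantile of the bootstrap distribution.
#'
#' @inheritParams wis_evaluate
#' @param B Bootstrap resamples (>= 1).
#' @param levels Confidence levels, default `c(0.90, 0.95)`.
#' @param seed Seed; the procedure is deterministic given it.
#' @return An `ope_result` with `bounds` (tibble: level, lower, upper) and
#'   the bootstrap sample in `boot`.
#' @export
bootstrap_bounds <- function(trajectories, policy_e, policy_b, gamma,
                             B = 1000L, levels = c(0.90, 0.95), seed = 1L,
                             estimator = c("stepwise", "trajectory")) {
  estimator <- match.arg(estimator)
  stopifnot(B >= 1)
  res <- wis_evaluate(trajectories, policy_e, policy_b, gamma, estimator)
  n <- res$n_trajectories
  if (n < 2) warning("fewer than 2 trajectories: bounds are degenerate")
  counts <- withr::with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    cts <- apply(idx, 1, tabulate, nbins = n)  # n x B (vector when n = 1)
    if (is.null(dim(cts))) cts <- matrix(cts, nrow = n)
    t(cts)
  })
  boot <- if (estimator == "trajectory") {
    num <- counts %*% (res$weights * res$returns)
    den <- counts %*% res$weights
    as.numeric(ifelse(den > 0, num / den, NA_real_))
  } else {
    Num <- counts %*% (res$cum_rho * res$disc_rew)
    Den <- counts %*% res$cum_rho
    frac <- ifelse(Den > 0, Num / Den, 0)
    as.numeric(frac %*% rep(1, ncol(frac)))
  }
  boot <- boot[is.finite(boot)]
  res$boot <- boot
  res$bounds <- tibble::tibble(
    level = levels,
    lower = stats::quantile(boot, 1 - levels, names = FALSE, type = 7),
    upper = stats::quantile(boot, levels, names = FALSE, type = 7)
  )
  res
}

#' Extract a bootstrap bound
#' @param result An `ope_result` with bounds.
#' @param side `"lower"` or `"upper"`.
#' @param level Confidence level present in the result.
#' @return Scalar bound.
#' @export
ope_bound <- function(result, side = c("lower", "upper"), level = 0.95) {
  side <- match.arg(side)
  b <- result$bounds
  if (is.null(b)) stop("result has no bootstrap bounds", call. = FALSE)
  i <- which(abs(b$level - level) < 1e-9)
  if (length(i) != 1) stop("level ", level, " not in bounds", call. = FALSE)
  b[[side]][i]
}

#' @export
print.ope_result <- function(x, ...) {
  cat("<ope_result>", x$estimator, "estimate:", format(x$estimate),
      " (n =", x$n_trajectories, ", ESS =", format(round(x$ess, 1)), ")\n")
  if (!is.null(x$bounds)) {
    for (i in seq_len(nrow(x$bounds))) {
      cat(sprintf("  %2.0f%% bounds: [%s, %s]\n", 100 * x$bounds$level[i],
                  format(x$bounds$lower[i]), format(x$bounds$upper[i])))
    }
  }
  invisible(x)
}

#' @export
tidy.ope_result <- function(x, ...) {
  if (is.null(x$bounds)) {
    return(tibble::tibble(estimate = x$estimate, level = NA_real_,
                          lower = NA_real_, upper = NA_real_))
  }
  dplyr::mutate(x$bounds, estimate = x$estimate, .before = 1)
}

#' @export
glance.ope_result <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate, estimator = x$estimator,
    n_trajectories = x$n_trajectories, ess = x$ess,
    n_zero_weight = x$n_zero_weight,
    n_boot = length(x$boot %||% numeric(0))
  )
}

#' Ensemble model building, off-policy evaluation and selection
#'
#' Repeats the whole learning cycle `n_models` times: draw a fresh random
#' train/validation/test split of stays, fit the k-means state model on the
#' training split, estimate the MDP and solve for the greedy policy, soften
#' it, then evaluate the AI, clinician (empirical behavior) and random
#' policies on the validation split by bootstrap WIS. The selected model
#' maximizes the configured confidence lower bound of the AI policy; its
#' softened policy is then re-evaluated on the held-out test split. Models
#' that fail (e.g. a visited state with no eligible action) are logged and
#' skipped.
#'
#' @param events Fully imputed event tibble.
#' @param features Feature column names used for clustering.
#' @param grid An `action_grid`.
#' @param config A `run_config`; `n_models`, `n_states`, `gamma`,
#'   `min_count`, `epsilon`, `bootstrap_b`, `conf_levels`, `select_level`
#'   and `split` are honoured.
#' @param seed Master seed (per-model seeds derive from it).
#' @param estimator WIS estimator passed through.
#' @param nstart k-means restarts per model.
#' @return An `ensemble_result`: `models` (per-model record tibble),
#'   `selected` (model id), `curve` (best-so-far selection criterion with
#'   up-to-the-point cumulative standard deviation), `test_result` (OPE of
#'   the selected policy on its test split) and the selected model's
#'   `artifacts`.
#' @export
run_ensemble <- function(events, features, grid = default_action_grid(),
                         config = load_config(), seed = config$seed,
                         estimator = "stepwise", nstart = 3L) {
  events <- tibble::as_tibble(events)
  stays <- unique(events$stay_id)
  n_stay <- length(stays)
  stopifnot(n_stay >= 3)
  A <- n_actions(grid)
  rows <- vector("list", config$n_models)
  best <- NULL
  best_lb <- -Inf
  for (m in seq_len(config$n_models)) {
    seed_m <- as.integer(seed + m)
    fit <- tryCatch(
      fit_one_model(events, features, grid, config, seed_m, estimator,
                    nstart),
      error = function(e) conditionMessage(e)
    )
    if (is.character(fit)) {
      rows[[m]] <- tibble::tibble(model = m, seed = seed_m, status = fit)
      next
    }
    fit$record$model <- m
    rows[[m]] <- fit$record
    if (fit$select_lb > best_lb) {
      best_lb <- fit$select_lb
      best <- c(fit, model = m)
    }
  }
  models <- dplyr::bind_rows(rows)
  if (is.null(best)) stop("every ensemble model failed", call. = FALSE)
  test_result <- bootstrap_bounds(
    best$test_transitions, best$policy_soft, best$behavior, config$gamma,
    B = config$bootstrap_b, levels = config$conf_levels,
    seed = best$record$seed, estimator = estimator
  )
  if (is.null(models$ai_select_lb)) models$ai_select_lb <- NA_real_
  lbs <- models$ai_select_lb
  curve <- tibble::tibble(
    model = models$model,
    select_lb = lbs,
    best_so_far = cummax(ifelse(is.na(lbs), -Inf, lbs)),
    cum_sd = vapply(seq_along(lbs), function(i) {
      stats::sd(lbs[seq_len(i)][!is.na(lbs[seq_len(i)])])
    }, numeric(1))
  )
  structure(list(
    models = models,
    selected = best$model,
    curve = curve,
    test_result = test_result,
    artifacts = list(
      state_model = best$state_model,
      mdp = best$mdp,
      policy_greedy = best$policy_greedy,
      policy_soft = best$policy_soft,
      behavior = best$behavior,
      q = best$q,
      splits = best$splits
    ),
    config = config,
    seed = seed
  ), class = "ensemble_result")
}

fit_one_model <- function(events, features, grid, config, seed_m, estimator,
                          nstart) {
  stays <- unique(events$stay_id)
  n_stay <- length(stays)
  A <- n_actions(grid)
  split_id <- withr::with_seed(seed_m, {
    sample(cut(seq_len(n_stay), include.lowest = TRUE, labels = c("train", "validation", "test"),
               breaks = round(c(0, cumsum(config$split)) * n_stay)))
  })
  splits <- split(stays, split_id)
  ev_train <- events[events$stay_id %in% splits$train, ]
  ev_val <- events[events$stay_id %in% splits$validation, ]
  ev_test <- events[events$stay_id %in% splits$test, ]
  sm <- fit_state_model(ev_train, features, k = config$n_states,
                        nstart = nstart, seed = seed_m)
  tr_train <- discretize_trajectories(ev_train, sm, grid)
  tr_val <- discretize_trajectories(ev_val, sm, grid)
  tr_test <- discretize_trajectories(ev_test, sm, grid)
  mdp <- estimate_mdp(tr_train, n_states = sm$n_states, n_actions = A,
                      gamma = config$gamma, min_count = config$min_count,
                      terminal = sm$terminal)
  sol <- solve_optimal_policy(mdp)
  ai <- soften_policy(sol$policy, config$epsilon)
  pib <- estimate_behavior_policy(dplyr::bind_rows(tr_train, tr_val),
                                  sm$n_states, A, quiet = TRUE)
  ai_res <- bootstrap_bounds(tr_val, ai, pib, config$gamma,
                             B = config$bootstrap_b,
                             levels = config$conf_levels, seed = seed_m,
                             estimator = estimator)
  clin_res <- bootstrap_bounds(tr_val, pib, pib, config$gamma,
                               B = config$bootstrap_b,
                               levels = config$conf_levels, seed = seed_m,
                               estimator = estimator)
  rand_res <- bootstrap_bounds(tr_val, random_policy(mdp), pib, config$gamma,
                               B = config$bootstrap_b,
                               levels = config$conf_levels, seed = seed_m,
                               estimator = estimator)
  select_lb <- ope_bound(ai_res, "lower", config$select_level)
  record <- tibble::tibble(
    model = NA_integer_, seed = seed_m, status = "ok",
    n_train = length(splits$train), n_validation = length(splits$validation),
    n_test = length(splits$test),
    ai_estimate = ai_res$estimate,
    ai_select_lb = select_lb,
    ai_lb90 = ope_bound(ai_res, "lower", 0.90),
    ai_ub90 = ope_bound(ai_res, "upper", 0.90),
    ai_ub95 = ope_bound(ai_res, "upper", 0.95),
    clinician_estimate = clin_res$estimate,
    clinician_ub95 = ope_bound(clin_res, "upper", 0.95),
    random_estimate = rand_res$estimate,
    ai_ess = ai_res$ess
  )
  list(record = record, select_lb = select_lb, state_model = sm, mdp = mdp,
       policy_greedy = sol$policy, policy_soft = ai, behavior = pib,
       q = sol$q, splits = splits, test_transitions = tr_test)
}

#' @export
print.ensemble_result <- function(x, ...) {
  ok <- sum(x$models$status == "ok")
  cat("<ensemble_result>", nrow(x$models), "models (", ok, "ok ), selected",
      x$selected, "\n")
  cat("  test estimate:", format(x$test_result$estimate), "\n")
  invisible(x)
}

#' @export
tidy.ensemble_result <- function(x, ...) {
  out <- x$models
  out$model <- seq_len(nrow(out))
  out
}

#' @export
glance.ensemble_result <- function(x, ...) {
  sel <- x$models[x$selected, ]
  tibble::tibble(
    n_models = nrow(x$models),
    n_ok = sum(x$models$status == "ok"),
    selected = x$selected,
    selected_lb = sel$ai_select_lb,
    validation_estimate = sel$ai_estimate,
    test_estimate = x$test_result$estimate,
    clinician_estimate = sel$clinician_estimate,
    random_estimate = sel$random_estimate
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
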