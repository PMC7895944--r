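#' Action-frequency comparison between the AI policy and the clinicians
#'
#' For every decision instance in the test transitions, records the
#' clinician's binned action and the greedy AI action, marginalizes per
#' action dimension and reports, per dimension x bin: clinician count, AI
#' count, absolute delta, delta as percent of all decision instances, and
#' relative percent change `(AI - clinician) / clinician * 100`. The
#' relative change is undefined (marked `NA` with `below_threshold`) when
#' the clinician count is zero, and bins whose absolute delta is below 1% of
#' the total decision instances are flagged, mirroring the reporting
#' threshold used for such comparisons.
#'
#' @param transitions Test transition tibble (clinician actions in `a`).
#' @param policy_ai Deterministic AI `policy_table` defined on all states.
#' @param grid The `action_grid`.
#' @param threshold Flagging threshold as a fraction of all instances.
#' @return An `action_frequency_table` tibble: `dimension`, `bin`, `range`,
#'   `clinician_n`, `ai_n`, `delta_n`, `delta_pct_total`, `rel_change_pct`,
#'   `below_threshold`; total instances in the `n_instances` attribute.
#' @export
action_frequency_comparison <- function(transitions, policy_ai,
                                        grid = default_action_grid(),
                                        threshold = 0.01) {
  tr <- tibble::as_tibble(transitions)
  greedy <- max.col(unclass(policy_ai), ties.method = "first")
  if (any(rowSums(policy_ai > 0) > 1)) {
    # a softened/stochastic policy still has a well-defined modal action
    greedy <- max.col(unclass(policy_ai), ties.method = "first")
  }
  a_clin <- tr$a
  a_ai <- greedy[tr$s]
  n_total <- nrow(tr)
  dec_clin <- decode_action(a_clin, grid)
  dec_ai <- decode_action(a_ai, grid)
  dims <- names(grid$edges)
  out <- lapply(dims, function(nm) {
    nb <- length(grid$edges[[nm]])
    e <- c(grid$edges[[nm]], Inf)
    cl <- tabulate(dec_clin[[paste0(nm, "_bin")]], nbins = nb)
    ai <- tabulate(dec_ai[[paste0(nm, "_bin")]], nbins = nb)
    tibble::tibble(
      dimension = nm,
      bin = seq_len(nb),
      range = sprintf("[%s, %s)", e[-length(e)], e[-1]),
      clinician_n = cl,
      ai_n = ai,
      delta_n = ai - cl,
      delta_pct_total = (ai - cl) / n_total * 100,
      rel_change_pct = ifelse(cl > 0, (ai - cl) / cl * 100, NA_real_),
      below_threshold = abs(ai - cl) < threshold * n_total
    )
  })
  res <- dplyr::bind_rows(out)
  attr(res, "n_instances") <- n_total
  class(res) <- c("action_frequency_table", class(res))
  res
}

#' Relative action changes per 4-h time step
#'
#' For every time bin `t >= 2` of the observation grid, counts the patients
#' whose flat action differs from their action at `t - 1`, divided by the
#' number of patients still ventilated at `t` -- separately for the
#' clinician's recorded actions and for the AI policy's recommendations.
#' Per-patient total change counts are also returned.
#'
#' @param actions Tibble with `stay_id`, `step` (1-based bin within event),
#'   `clinician` and `ai` flat action columns.
#' @return List of class `action_change_result`: `per_step` tibble (`step`,
#'   `n_ventilated`, `clinician_changes`, `ai_changes`,
#'   `clinician_rel`, `ai_rel`) and `per_patient` totals.
#' @export
action_changes_per_step <- function(actions) {
  ac <- dplyr::arrange(tibble::as_tibble(actions), .data$stay_id, .data$step)
  same_stay <- c(FALSE, ac$stay_id[-1] == ac$stay_id[-nrow(ac)])
  chg_clin <- same_stay & c(NA, diff(ac$clinician)) != 0
  chg_ai <- same_stay & c(NA, diff(ac$ai)) != 0
  ac$chg_clin <- ifelse(same_stay, chg_clin, NA)
  ac$chg_ai <- ifelse(same_stay, chg_ai, NA)
  per_step <- ac |>
    dplyr::filter(.data$step >= 2) |>
    dplyr::group_by(.data$step) |>
    dplyr::summarise(
      n_ventilated = dplyr::n(),
      clinician_changes = sum(.data$chg_clin, na.rm = TRUE),
      ai_changes = sum(.data$chg_ai, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      clinician_rel = .data$clinician_changes / .data$n_ventilated,
      ai_rel = .data$ai_changes / .data$n_ventilated
    )
  per_patient <- ac |>
    dplyr::group_by(.data$stay_id) |>
    dplyr::summarise(
      n_steps = dplyr::n(),
      clinician_changes = sum(.data$chg_clin, na.rm = TRUE),
      ai_changes = sum(.data$chg_ai, na.rm = TRUE),
      .groups = "drop"
    )
  structure(list(per_step = per_step, per_patient = per_patient),
            class = "action_change_result")
}

#' Out-of-bag random-forest feature importance per action dimension
#'
#' Fits one random-forest regressor per action dimension with the
#' continuous chosen setting as target and reports the out-of-bag
#' permutation importance (increase in mean squared error), floored at zero
#' and normalized to sum 1. The number of top-ranked features reaching a
#' cumulative importance of 0.80 is reported per dimension.
#'
#' @param features Decision-instance feature data frame (numeric columns).
#' @param targets Data frame with one numeric column per action dimension
#'   (e.g. `vt_per_kg`, `peep`, `fio2`), the continuous chosen settings.
#' @param seed Seed for the forest fits.
#' @param num_trees Trees per forest.
#' @return A `feature_importance_result`: `importance` tibble (`dimension`,
#'   `feature`, `weight`, `rank`) and `top80` tibble (`dimension`,
#'   `n_features_80pct`).
#' @export
feature_importance_oob <- function(features, targets, seed = 1L,
                                   num_trees = 500L) {
  X <- as.data.frame(features)
  stopifnot(nrow(X) >= 50)
  rows <- list()
  top <- list()
  for (nm in names(targets)) {
    y <- targets[[nm]]
    if (stats::sd(y) == 0) {
      warning("constant target for dimension ", nm,
              "; importances set to zero")
      imp <- stats::setNames(rep(0, ncol(X)), names(X))
    } else {
      rf <- withr::with_seed(seed, randomForest::randomForest(
        x = X, y = y, ntree = num_trees, importance = TRUE
      ))
      imp <- rf$importance[, "%IncMSE"]
      imp <- pmax(imp, 0)
      if (sum(imp) > 0) imp <- imp / sum(imp)
    }
    ord <- order(imp, decreasing = TRUE)
    rows[[nm]] <- tibble::tibble(
      dimension = nm, feature = names(X),
      weight = unname(imp),
      rank = match(seq_along(imp), ord)
    )
    csum <- cumsum(imp[ord])
    top[[nm]] <- tibble::tibble(
      dimension = nm,
      n_features_80pct = if (sum(imp) > 0) which(csum >= 0.80)[1]
                         else NA_integer_
    )
  }
  structure(list(importance = dplyr::bind_rows(rows),
                 top80 = dplyr::bind_rows(top)),
            class = "feature_importance_result")
}

#' Performance return versus observed mortality
#'
#' Bins per-trajectory evaluated returns into `n_bins` equal-width intervals
#' and reports the empirical mortality fraction per bin with an exact
#' binomial confidence interval. Empty bins are marked, not interpolated.
#'
#' @param returns Numeric per-trajectory returns.
#' @param outcomes Character vector, `"survived"` / `"died"`.
#' @param n_bins Number of equal-width return bins.
#' @param conf_level Binomial interval level.
#' @return Tibble: `bin`, `return_lo`, `return_hi`, `n`, `deaths`,
#'   `mortality`, `ci_lo`, `ci_hi`, `empty`.
#' @export
return_vs_mortality <- function(returns, outcomes, n_bins = 10,
                                conf_level = 0.95) {
  stopifnot(length(returns) == length(outcomes), all(is.finite(returns)))
  died <- outcomes == "died"
  rng <- range(returns)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(findInterval(returns, edges, rightmost.closed = TRUE), n_bins)
  out <- lapply(seq_len(n_bins), function(b) {
    i <- bin == b
    n <- sum(i)
    d <- sum(died[i])
    ci <- if (n > 0) stats::binom.test(d, n, conf.level = conf_level)$conf.int
          else c(NA_real_, NA_real_)
    tibble::tibble(bin = b, return_lo = edges[b], return_hi = edges[b + 1],
                   n = n, deaths = d,
                   mortality = if (n > 0) d / n else NA_real_,
                   ci_lo = ci[1], ci_hi = ci[2], empty = n == 0)
  })
  dplyr::bind_rows(out)
}

#' State-versus-time correlation per stay
#'
#' Rank correlation (Spearman) of the assigned state index against the time
#' bin within each stay, summarizing whether disease states separate over
#' the observation window. Constant state sequences are reported as 0 with a
#' flag.
#'
#' @param states Tibble with `stay_id`, `step`, `s`.
#' @return List of class `state_time_result`: `per_stay` tibble (`stay_id`,
#'   `rho`, `n_bins`, `constant`) and `summary` (mean/median rho, fraction
#'   constant).
#' @export
state_time_correlation <- function(states) {
  st <- dplyr::arrange(tibble::as_tibble(states), .data$stay_id, .data$step)
  per_stay <- st |>
    dplyr::group_by(.data$stay_id) |>
    dplyr::summarise(
      n_bins = dplyr::n(),
      constant = length(unique(.data$s)) == 1,
      rho = if (dplyr::n() < 2 || length(unique(.data$s)) == 1) 0 else
        suppressWarnings(stats::cor(.data$s, .data$step,
                                    method = "spearman")),
      .groups = "drop"
    )
  if (any(per_stay$n_bins < 2)) {
    stop("every stay needs at least 2 bins", call. = FALSE)
  }
  summary <- tibble::tibble(
    n_stays = nrow(per_stay),
    mean_rho = mean(per_stay$rho),
    median_rho = stats::median(per_stay$rho),
    fraction_constant = mean(per_stay$constant)
  )
  structure(list(per_stay = per_stay, summary = summary),
            class = "state_time_result")
}
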