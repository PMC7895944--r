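#' Predicted ideal body weight
#'
#' Height- and sex-predicted body weight used to index set tidal volume:
#' `50 + 0.91 * (height_cm - 152.4)` kg for males and
#' `45.5 + 0.91 * (height_cm - 152.4)` kg for females.
#'
#' @param sex Character vector, `"male"` or `"female"` (recycled).
#' @param height_cm Height in centimeters, positive.
#' @return Ideal body weight in kg.
#' @examples
#' ideal_body_weight("male", 152.4)   # 50
#' ideal_body_weight("female", 152.4) # 45.5
#' @export
ideal_body_weight <- function(sex, height_cm) {
  if (any(is.na(height_cm)) || any(height_cm <= 0)) {
    stop("validation error: height_cm must be positive", call. = FALSE)
  }
  if (!all(sex %in% c("male", "female"))) {
    stop("validation error: sex must be 'male' or 'female'", call. = FALSE)
  }
  intercept <- ifelse(sex == "male", 50, 45.5)
  intercept + 0.91 * (height_cm - 152.4)
}

#' Define mechanical-ventilation events
#'
#' Applies the cohort rules that turn raw binned stays into analyzable
#' ventilation events. A documented set tidal volume starts a new event; the
#' event continues while any of the three ventilator settings (set Vt, PEEP,
#' FiO2) is documented within two sample periods (8 h, i.e. 2 bins) of the
#' previous documentation; documentation of extubation, the start of
#' non-invasive ventilation, or supplemental oxygen ends it. Inclusion
#' filters: age > 18, no treatment-withdrawal flag inside the event window,
#' documented outcome, documented height (needed for ideal body weight), and
#' duration of at least 24 h (>= 6 post-onset bins). Only the first
#' qualifying event per stay is retained and the event is clipped to the
#' observation window of one pre-onset bin plus 18 post-onset bins
#' (-4 h to +72 h around onset).
#'
#' Within an event the three setting columns are forward-filled (and leading
#' gaps back-filled from the first documentation) so every bin carries a
#' complete clinician action; feature columns are left untouched for the
#' imputation stage.
#'
#' @param table Validated trajectory tibble (see [read_cohort()]).
#' @param manifest Feature manifest.
#' @param min_duration_bins Minimum post-onset bins, default 6 (24 h).
#' @param max_post_onset_bins Window clip, default 18 (72 h).
#' @return Event tibble: one row per retained (stay, bin) with `rel_bin`
#'   (0 = pre-onset bin, 1 = onset), `onset_bin`, `ibw_kg`, settings,
#'   manifest features and outcome. Stays dropped by a filter are counted in
#'   the `drop_log` attribute.
#' @export
define_ventilation_events <- function(table, manifest = default_manifest(),
                                      min_duration_bins = 6,
                                      max_post_onset_bins = 18) {
  validate_manifest(manifest)
  table <- dplyr::arrange(tibble::as_tibble(table), .data$stay_id,
                          .data$time_bin)
  feats <- manifest$feature
  by_stay <- split(seq_len(nrow(table)), table$stay_id)
  out <- vector("list", length(by_stay))
  reasons <- character(0)
  for (i in seq_along(by_stay)) {
    idx <- by_stay[[i]]
    stay <- table[idx, , drop = FALSE]
    res <- first_qualifying_event(stay, min_duration_bins, max_post_onset_bins)
    if (is.character(res)) {
      reasons <- c(reasons, res)
      next
    }
    ev <- res
    ev$vt_set_ml <- fill_setting(ev$vt_set_ml)
    ev$peep_cmh2o <- fill_setting(ev$peep_cmh2o)
    ev$fio2_pct <- fill_setting(ev$fio2_pct)
    height <- ev$height_cm[!is.na(ev$height_cm)][1]
    sex <- ev$sex[!is.na(ev$sex)][1]
    ev$ibw_kg <- ideal_body_weight(sex, height)
    out[[i]] <- ev
  }
  events <- dplyr::bind_rows(out)
  if (nrow(events) > 0) {
    events <- dplyr::select(
      events, "stay_id", "time_bin", "rel_bin", "onset_bin", "ibw_kg",
      "vt_set_ml", "peep_cmh2o", "fio2_pct", "sex", "age_years", "height_cm",
      "outcome", dplyr::all_of(feats)
    )
  }
  attr(events, "drop_log") <-
    tibble::as_tibble(as.data.frame(table(reason = reasons),
                                    stringsAsFactors = FALSE))
  events
}

# Scan one stay for its first qualifying event; returns the event tibble or a
# drop-reason string.
first_qualifying_event <- function(stay, min_duration_bins,
                                   max_post_onset_bins) {
  bins <- stay$time_bin
  any_setting <- !is.na(stay$vt_set_ml) | !is.na(stay$peep_cmh2o) |
    !is.na(stay$fio2_pct)
  flag_end <- isTRUE_vec(stay$extubation) | isTRUE_vec(stay$niv_start) |
    isTRUE_vec(stay$suppl_o2)
  reason <- "no_ventilation_event"
  pos <- 1L
  while (pos <= nrow(stay)) {
    onset_i <- which(!is.na(stay$vt_set_ml) & seq_len(nrow(stay)) >= pos &
                       !flag_end)[1]
    if (is.na(onset_i)) break
    # chain setting documentations with gaps <= 2 bins, stopping at end flags
    last_i <- onset_i
    j <- onset_i + 1L
    while (j <= nrow(stay)) {
      if (flag_end[j]) break
      if (bins[j] - bins[last_i] > 2L) break
      if (any_setting[j]) last_i <- j
      j <- j + 1L
    }
    rel <- bins[onset_i:last_i] - bins[onset_i] + 1L
    keep_i <- (onset_i:last_i)[rel <= max_post_onset_bins]
    reason <- qualify_event(stay, keep_i, min_duration_bins)
    if (is.null(reason)) {
      pre_i <- which(bins == bins[onset_i] - 1L)
      ev <- stay[c(pre_i, keep_i), , drop = FALSE]
      ev$onset_bin <- bins[onset_i]
      ev$rel_bin <- ev$time_bin - ev$onset_bin + 1L
      return(ev)
    }
    pos <- last_i + 1L
  }
  reason
}

qualify_event <- function(stay, keep_i, min_duration_bins) {
  age <- stay$age_years[!is.na(stay$age_years)][1]
  outcome <- stay$outcome[!is.na(stay$outcome)][1]
  height <- stay$height_cm[!is.na(stay$height_cm)][1]
  sex <- stay$sex[!is.na(stay$sex)][1]
  if (length(keep_i) < min_duration_bins) return("too_short")
  if (is.na(age) || age <= 18) return("age_18_or_under")
  if (any(isTRUE_vec(stay$withdrawal[keep_i]))) return("treatment_withdrawal")
  if (is.na(outcome)) return("outcome_undocumented")
  if (is.na(height) || is.na(sex)) return("height_or_sex_undocumented")
  NULL
}

isTRUE_vec <- function(x) !is.na(x) & x

# forward-fill then back-fill a ventilator-setting column within one event
fill_setting <- function(x) {
  obs <- which(!is.na(x))
  if (length(obs) == 0) return(x)
  idx <- cummax(ifelse(!is.na(x), seq_along(x), 0L))
  filled <- ifelse(idx > 0, x[pmax(idx, 1L)], x[obs[1]])
  filled
}

#' Estimate per-feature sample-and-hold limits
#'
#' Frequency analysis of how often each feature is measured: the hold limit
#' is the median gap (in 4-h bins) between consecutive observations of the
#' feature within a stay, pooled across the cohort. Features observed fewer
#' than twice anywhere get the configured fallback limit.
#'
#' @param table Trajectory or event tibble containing the manifest features.
#' @param manifest Feature manifest.
#' @param fallback Fallback limit in bins (default 2, the 8-h
#'   event-continuation horizon).
#' @return Named integer vector of limits, one per feature.
#' @export
estimate_hold_limits <- function(table, manifest = default_manifest(),
                                 fallback = 2L) {
  validate_manifest(manifest)
  if (nrow(table) == 0) stop("empty table", call. = FALSE)
  table <- dplyr::arrange(tibble::as_tibble(table), .data$stay_id,
                          .data$time_bin)
  stay <- table$stay_id
  bins <- table$time_bin
  limits <- integer(0)
  for (f in manifest$feature) {
    obs <- !is.na(table[[f]])
    if (sum(obs) < 2) {
      limits[f] <- as.integer(fallback)
      next
    }
    same_stay <- stay[obs][-1] == stay[obs][-sum(obs)]
    gaps <- diff(bins[obs])[same_stay]
    limits[f] <- if (length(gaps) == 0) as.integer(fallback) else
      max(1L, as.integer(floor(stats::median(gaps))))
  }
  limits
}

#' Sample-and-hold a single series
#'
#' Propagates each observed value forward for at most `limit` bins or until
#' the next observation; bins before the first observation stay missing.
#'
#' @param x Numeric vector with `NA` gaps (one feature, one stay, bins
#'   assumed consecutive).
#' @param limit Hold limit in bins, >= 1.
#' @return Filled vector of the same length.
#' @examples
#' sample_and_hold(c(7, NA, NA, NA), limit = 2) # 7 7 7 NA
#' @export
sample_and_hold <- function(x, limit) {
  stopifnot(limit >= 1)
  obs <- !is.na(x)
  if (!any(obs)) return(x)
  idx <- seq_along(x)
  last <- cummax(ifelse(obs, idx, 0L))
  fill <- last > 0 & (idx - last) <= limit
  out <- x
  out[fill] <- x[pmax(last[fill], 1L)]
  out
}

#' Apply sample-and-hold across a cohort
#'
#' Runs [sample_and_hold()] per stay and feature using per-feature limits,
#' measuring gaps on the `time_bin` axis (non-consecutive recorded bins count
#' as their true bin distance).
#'
#' @param table Trajectory or event tibble.
#' @param manifest Feature manifest.
#' @param limits Named limits from [estimate_hold_limits()]; a single number
#'   is recycled.
#' @return The table with feature gaps filled.
#' @export
apply_sample_and_hold <- function(table, manifest = default_manifest(),
                                  limits = estimate_hold_limits(table, manifest)) {
  validate_manifest(manifest)
  table <- dplyr::arrange(tibble::as_tibble(table), .data$stay_id,
                          .data$time_bin)
  if (length(limits) == 1 && is.null(names(limits))) {
    limits <- stats::setNames(rep(limits, nrow(manifest)), manifest$feature)
  }
  stay <- table$stay_id
  bins <- table$time_bin
  idx <- seq_len(nrow(table))
  for (f in manifest$feature) {
    x <- table[[f]]
    obs <- !is.na(x)
    if (!any(obs)) next
    last <- cummax(ifelse(obs, idx, 0L))
    ok <- last > 0
    ok[ok] <- stay[last[ok]] == stay[ok] &
      (bins[ok] - bins[last[ok]]) <= limits[[f]]
    x[ok] <- x[last[ok]]
    table[[f]] <- x
  }
  table
}

#' Tukey range outlier filter
#'
#' Flags values outside the Tukey fences `[Q1 - k * IQR, Q3 + k * IQR]`
#' (default multiplier 1.5). An optional frequency mode additionally flags
#' values outside the central 90% empirical interval.
#'
#' @param x Numeric vector (one feature across the cohort).
#' @param k Fence multiplier.
#' @param frequency_interval Also flag outside the central 90% interval.
#' @return Logical mask, `TRUE` where flagged (`NA` cells are `FALSE`).
#' @export
tukey_outlier_filter <- function(x, k = 1.5, frequency_interval = FALSE) {
  flag <- rep(FALSE, length(x))
  obs <- !is.na(x)
  if (!any(obs)) {
    warning("all values missing; nothing to flag")
    return(flag)
  }
  if (sum(obs) < 4) {
    warning("fewer than 4 observed values; nothing flagged")
    return(flag)
  }
  q <- stats::quantile(x[obs], c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  flag[obs] <- x[obs] < q[1] - k * iqr | x[obs] > q[2] + k * iqr
  if (frequency_interval) {
    f <- stats::quantile(x[obs], c(0.05, 0.95), names = FALSE)
    flag[obs] <- flag[obs] | x[obs] < f[1] | x[obs] > f[2]
  }
  flag
}

#' Apply the outlier filter to all manifest features
#'
#' Flagged cells are set to missing so they are re-estimated during
#' imputation. Binary features are skipped. Outlier filtering runs before
#' sample-and-hold so held values are never outliers.
#'
#' @inheritParams apply_sample_and_hold
#' @param k Tukey fence multiplier.
#' @param frequency_interval See [tukey_outlier_filter()].
#' @return The table with flagged cells set to `NA`; per-feature flag counts
#'   in the `outlier_counts` attribute.
#' @export
apply_outlier_filter <- function(table, manifest = default_manifest(),
                                 k = 1.5, frequency_interval = FALSE) {
  validate_manifest(manifest)
  table <- tibble::as_tibble(table)
  counts <- integer(0)
  for (i in seq_len(nrow(manifest))) {
    f <- manifest$feature[i]
    if (manifest$kind[i] == "binary") next
    if (sum(!is.na(table[[f]])) < 4) next
    mask <- tukey_outlier_filter(table[[f]], k = k,
                                 frequency_interval = frequency_interval)
    table[[f]][mask] <- NA_real_
    counts[f] <- sum(mask)
  }
  attr(table, "outlier_counts") <- counts
  table
}

#' Impute remaining missing feature cells
#'
#' Events whose post-hold missing fraction (over manifest feature cells)
#' exceeds `discard_threshold` are discarded. Remaining gaps are filled by
#' k-nearest-neighbour imputation over z-scored feature rows (falling back to
#' the column mean when no neighbour shares an observed coordinate), by an
#' iterative low-rank SVD completion, or by plain column means. Observed
#' cells are never altered and the output contains no missing feature cells.
#'
#' For cohort-scale data the kNN search uses a deterministic subsample of at
#' most `max_candidates` donor rows.
#'
#' @param events Event tibble from [define_ventilation_events()], after
#'   [apply_sample_and_hold()].
#' @param manifest Feature manifest.
#' @param method `"knn"` (default), `"svd"` or `"mean"`.
#' @param k Neighbours for kNN.
#' @param discard_threshold Maximum tolerated missing fraction per event.
#' @param svd_rank Rank for SVD completion; default `min(10, floor(d / 4))`.
#' @param max_iter,tol SVD completion iteration controls.
#' @param max_candidates kNN donor-pool cap.
#' @param seed Seed for the donor-pool subsample.
#' @return List of class `imputation_result`: `events` (fully imputed),
#'   `diagnostics` (per-feature imputed fractions), `n_discarded`,
#'   `discarded_stays`.
#' @export
impute_events <- function(events, manifest = default_manifest(),
                          method = c("knn", "svd", "mean"), k = 3,
                          discard_threshold = 0.5, svd_rank = NULL,
                          max_iter = 50, tol = 1e-4, max_candidates = 2000,
                          seed = 1) {
  method <- match.arg(method)
  validate_manifest(manifest)
  feats <- intersect(manifest$feature, names(events))
  if (length(feats) == 0) stop("no manifest features found in events",
                               call. = FALSE)
  events <- dplyr::arrange(tibble::as_tibble(events), .data$stay_id,
                           .data$time_bin)
  X <- as.matrix(events[, feats, drop = FALSE])

  miss_frac <- tapply(rowMeans(is.na(X)), events$stay_id, mean)
  discarded <- names(miss_frac)[miss_frac > discard_threshold]
  keep <- !(events$stay_id %in% discarded)
  events <- events[keep, , drop = FALSE]
  X <- X[keep, , drop = FALSE]
  if (nrow(X) == 0) stop("all events discarded during imputation",
                         call. = FALSE)

  miss <- is.na(X)
  imputed_frac <- colMeans(miss)
  X_filled <- switch(method,
    mean = impute_mean(X),
    knn = impute_knn(X, k = k, max_candidates = max_candidates, seed = seed),
    svd = impute_svd(X, rank = svd_rank, max_iter = max_iter, tol = tol)
  )
  # a column observed nowhere cannot be estimated; fill 0 with a warning
  if (anyNA(X_filled)) {
    bad <- colnames(X_filled)[colSums(is.na(X_filled)) > 0]
    warning("feature(s) with no observed values filled with 0: ",
            paste(bad, collapse = ", "))
    X_filled[is.na(X_filled)] <- 0
  }
  X_filled[!miss] <- X[!miss]
  events[, feats] <- tibble::as_tibble(X_filled)
  structure(list(
    events = events,
    diagnostics = tibble::tibble(feature = feats,
                                 imputed_fraction = unname(imputed_frac)),
    n_discarded = length(discarded),
    discarded_stays = discarded,
    method = method
  ), class = "imputation_result")
}

impute_mean <- function(X) {
  mu <- colMeans(X, na.rm = TRUE)
  miss <- is.na(X)
  X[miss] <- mu[col(X)[miss]]
  X
}

impute_knn <- function(X, k = 3, max_candidates = 2000, seed = 1) {
  n <- nrow(X)
  mu <- colMeans(X, na.rm = TRUE)
  sdv <- apply(X, 2, stats::sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  M <- !is.na(Z)
  P <- Z
  P[!M] <- 0
  targets <- which(rowSums(!M) > 0)
  if (length(targets) == 0) return(X)
  cand <- seq_len(n)
  if (n > max_candidates) {
    cand <- withr::with_seed(seed, sort(sample.int(n, max_candidates)))
  }
  Pc <- P[cand, , drop = FALSE]
  Mc <- M[cand, , drop = FALSE] * 1
  out <- X
  chunk <- 512L
  for (start in seq(1, length(targets), by = chunk)) {
    rows <- targets[start:min(start + chunk - 1L, length(targets))]
    Pt <- P[rows, , drop = FALSE]
    Mt <- M[rows, , drop = FALSE] * 1
    shared <- Mt %*% t(Mc)
    d2 <- (Pt^2) %*% t(Mc) - 2 * Pt %*% t(Pc) + Mt %*% t(Pc^2)
    d2 <- d2 / shared
    d2[shared == 0] <- Inf
    for (ri in seq_along(rows)) {
      r <- rows[ri]
      dist_r <- d2[ri, ]
      dist_r[cand == r] <- Inf
      for (j in which(!M[r, ])) {
        donors <- which(Mc[, j] == 1 & is.finite(dist_r))
        if (length(donors) == 0) {
          out[r, j] <- mu[j]
          next
        }
        nb <- donors[order(dist_r[donors])][seq_len(min(k, length(donors)))]
        out[r, j] <- mean(X[cand[nb], j])
      }
    }
  }
  out
}

impute_svd <- function(X, rank = NULL, max_iter = 50, tol = 1e-4) {
  d <- ncol(X)
  if (is.null(rank)) rank <- max(1L, min(10L, floor(d / 4)))
  rank <- min(rank, d, nrow(X))
  miss <- is.na(X)
  Xf <- impute_mean(X)
  Xf[is.na(Xf)] <- 0
  for (it in seq_len(max_iter)) {
    sv <- svd(Xf, nu = rank, nv = rank)
    recon <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
    new_vals <- recon[miss]
    delta <- sqrt(sum((new_vals - Xf[miss])^2)) /
      max(sqrt(sum(Xf[miss]^2)), 1e-12)
    Xf[miss] <- new_vals
    if (delta < tol) break
  }
  Xf
}

#' Missing-data mechanism diagnostic
#'
#' For each feature with both missing and observed cells, tests whether its
#' missingness indicator is associated with the observed values of the other
#' features (Spearman rank correlation per covariate, Bonferroni-combined to
#' one p-value per feature). Small p-values argue against missing completely
#' at random (MCAR) in favour of missing at random (MAR) given the observed
#' data. Fully observed (or fully missing) features are reported as
#' not applicable.
#'
#' @param table Trajectory or event tibble.
#' @param manifest Feature manifest.
#' @return Tibble with `feature`, `n_missing`, `statistic` (rank correlation
#'   of the strongest covariate), `covariate`, `p_value`, `status`.
#' @export
missingness_diagnostic <- function(table, manifest = default_manifest()) {
  validate_manifest(manifest)
  table <- tibble::as_tibble(table)
  feats <- intersect(manifest$feature, names(table))
  rows <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[i]
    m <- is.na(table[[f]])
    if (!any(m) || all(m)) {
      rows[[i]] <- tibble::tibble(feature = f, n_missing = sum(m),
                                  statistic = NA_real_,
                                  covariate = NA_character_,
                                  p_value = NA_real_,
                                  status = "not_applicable")
      next
    }
    best_p <- Inf
    best_rho <- NA_real_
    best_cov <- NA_character_
    n_tested <- 0L
    for (g in setdiff(feats, f)) {
      x <- table[[g]]
      ok <- !is.na(x)
      if (sum(ok) < 10 || length(unique(m[ok])) < 2 ||
          length(unique(x[ok])) < 2) next
      ct <- suppressWarnings(
        stats::cor.test(as.numeric(m[ok]), x[ok], method = "spearman",
                        exact = FALSE)
      )
      n_tested <- n_tested + 1L
      if (ct$p.value < best_p) {
        best_p <- ct$p.value
        best_rho <- unname(ct$estimate)
        best_cov <- g
      }
    }
    p_comb <- if (n_tested == 0) NA_real_ else min(1, best_p * n_tested)
    rows[[i]] <- tibble::tibble(feature = f, n_missing = sum(m),
                                statistic = best_rho, covariate = best_cov,
                                p_value = p_comb,
                                status = if (n_tested == 0) "not_applicable"
                                         else "tested")
  }
  dplyr::bind_rows(rows)
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper: outlier filtering, ventilation-event definition,
#' hold-limit estimation, sample-and-hold, then imputation.
#'
#' @param table Validated trajectory tibble.
#' @param manifest Feature manifest.
#' @param config A `run_config` (see [load_config()]).
#' @return An `imputation_result` whose `events` member is the fully imputed
#'   event tibble.
#' @export
preprocess_cohort <- function(table, manifest = default_manifest(),
                              config = load_config()) {
  table <- apply_outlier_filter(table, manifest, k = config$tukey_k)
  events <- define_ventilation_events(table, manifest)
  if (nrow(events) == 0) stop("no qualifying ventilation events", call. = FALSE)
  limits <- estimate_hold_limits(events, manifest,
                                 fallback = config$hold_fallback)
  events <- apply_sample_and_hold(events, manifest, limits)
  impute_events(events, manifest, method = config$impute_method,
                k = config$knn_k, discard_threshold = config$discard_threshold,
                svd_rank = config$svd_rank, seed = config$seed)
}
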