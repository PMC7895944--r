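#' Construct a discrete ventilator-setting action grid
#'
#' The action space discretizes the three controlled settings into seven
#' half-open bins each, `[lower, upper)` with the last bin open-ended,
#' giving `7^3 = 343` flat actions by default:
#'
#' * ideal-body-weight-indexed tidal volume (mL/kg):
#'   0-2.5 / 2.5-5 / 5-7.5 / 7.5-10 / 10-12.5 / 12.5-15 / >15
#' * PEEP (cmH2O): 0-5 / 5-7 / 7-9 / 9-11 / 11-13 / 13-15 / >15
#' * FiO2 (%): <30 / 30-35 / 35-40 / 40-45 / 45-50 / 50-55 / >55
#'
#' FiO2 below the first printed edge is folded into the first bin (inspired
#' oxygen below 21% is non-physical). Extra named dimensions (e.g. a
#' respiratory-rate axis) may be appended with user-supplied edges; the grid
#' size multiplies accordingly.
#'
#' @param vt_per_kg,peep,fio2 Strictly increasing lower bin edges.
#' @param ... Further named numeric edge vectors for extra dimensions.
#' @return An `action_grid` object.
#' @examples
#' n_actions(default_action_grid()) # 343
#' @export
action_grid <- function(vt_per_kg = c(0, 2.5, 5, 7.5, 10, 12.5, 15),
                        peep = c(0, 5, 7, 9, 11, 13, 15),
                        fio2 = c(0, 30, 35, 40, 45, 50, 55), ...) {
  dims <- c(list(vt_per_kg = vt_per_kg, peep = peep, fio2 = fio2), list(...))
  for (nm in names(dims)) {
    e <- dims[[nm]]
    if (length(e) < 1 || any(diff(e) <= 0)) {
      stop("bin edges for ", nm, " must be strictly increasing", call. = FALSE)
    }
  }
  structure(list(edges = dims), class = "action_grid")
}

#' @rdname action_grid
#' @export
default_action_grid <- function() action_grid()

#' Number of flat actions in a grid
#' @param grid An `action_grid`.
#' @return Integer product of per-dimension bin counts.
#' @export
n_actions <- function(grid) {
  stopifnot(inherits(grid, "action_grid"))
  prod(vapply(grid$edges, length, integer(1)))
}

#' @export
print.action_grid <- function(x, ...) {
  cat("<action_grid>", n_actions(x), "actions\n")
  for (nm in names(x$edges)) {
    cat(" ", nm, ": ", paste(x$edges[[nm]], collapse = ", "), ", Inf\n",
        sep = "")
  }
  invisible(x)
}

# per-dimension bin index for non-negative values; below the first edge
# folds into bin 1
bin_index <- function(x, edges) {
  pmax(1L, findInterval(x, edges))
}

# row-major flat index from a matrix/list of per-dimension bin indices
flatten_bins <- function(bins, grid) {
  sizes <- vapply(grid$edges, length, integer(1))
  nd <- length(sizes)
  flat <- rep(0L, nrow(bins))
  for (i in seq_len(nd)) {
    mult <- if (i < nd) prod(sizes[(i + 1):nd]) else 1L
    flat <- flat + (bins[, i] - 1L) * mult
  }
  flat + 1L
}

#' Encode ventilator settings as a flat action index
#'
#' Tidal volume is first indexed per kg of ideal body weight
#' (`vt_set_ml / ibw_kg`); each dimension then maps to its half-open bin and
#' the bin tuple is encoded row-major (first dimension slowest).
#'
#' @param vt_set_ml Set tidal volume in mL.
#' @param ibw_kg Ideal body weight in kg (see [ideal_body_weight()]).
#' @param peep PEEP in cmH2O.
#' @param fio2 FiO2 in percent.
#' @param grid An `action_grid` (3 dimensions).
#' @param extra Optional named list of values for extra grid dimensions.
#' @return Integer vector of flat action indices in `1..n_actions(grid)`.
#' @export
encode_action <- function(vt_set_ml, ibw_kg, peep, fio2,
                          grid = default_action_grid(), extra = NULL) {
  stopifnot(inherits(grid, "action_grid"))
  if (any(ibw_kg <= 0, na.rm = TRUE)) {
    stop("validation error: ibw_kg must be positive", call. = FALSE)
  }
  vals <- list(vt_per_kg = vt_set_ml / ibw_kg, peep = peep, fio2 = fio2)
  extra_dims <- setdiff(names(grid$edges), names(vals))
  if (length(extra_dims) > 0) {
    if (is.null(extra) || !all(extra_dims %in% names(extra))) {
      stop("values required for extra grid dimension(s): ",
           paste(extra_dims, collapse = ", "), call. = FALSE)
    }
    vals <- c(vals, extra[extra_dims])
  }
  if (any(unlist(vals) < 0, na.rm = TRUE)) {
    stop("validation error: settings must be non-negative", call. = FALSE)
  }
  bins <- do.call(cbind, lapply(names(grid$edges), function(nm) {
    bin_index(vals[[nm]], grid$edges[[nm]])
  }))
  as.integer(flatten_bins(bins, grid))
}

#' Decode a flat action index into per-dimension bin ranges
#'
#' @param action Integer flat action indices.
#' @param grid An `action_grid`.
#' @return Tibble with one row per action: per-dimension bin index and
#'   `[lower, upper)` range columns.
#' @export
decode_action <- function(action, grid = default_action_grid()) {
  stopifnot(inherits(grid, "action_grid"))
  sizes <- vapply(grid$edges, length, integer(1))
  nd <- length(sizes)
  if (any(action < 1 | action > prod(sizes))) {
    stop("action index out of range", call. = FALSE)
  }
  rem <- action - 1L
  out <- tibble::tibble(action = as.integer(action))
  bins <- matrix(0L, length(action), nd)
  for (i in seq_len(nd)) {
    mult <- if (i < nd) prod(sizes[(i + 1):nd]) else 1L
    bins[, i] <- as.integer(rem %/% mult) + 1L
    rem <- rem %% mult
  }
  for (i in seq_len(nd)) {
    nm <- names(grid$edges)[i]
    e <- c(grid$edges[[i]], Inf)
    out[[paste0(nm, "_bin")]] <- bins[, i]
    out[[paste0(nm, "_lo")]] <- e[bins[, i]]
    out[[paste0(nm, "_hi")]] <- e[bins[, i] + 1L]
  }
  out
}

#' Fit the k-means patient-state model
#'
#' Discretizes patient physiology into `k` states by k-means clustering of
#' the z-scored data fingerprint. Scaling parameters come from the supplied
#' (training) rows only; new rows are projected with the frozen scaler. Two
#' absorbing terminal states (survival, death) are appended after the `k`
#' physiologic states, giving `k + 2` states in total.
#'
#' @param events Event tibble carrying the manifest features (training split).
#' @param features Character vector of feature column names.
#' @param k Number of physiologic states (default 650).
#' @param nstart Random restarts.
#' @param iter_max k-means iteration cap.
#' @param seed Seed making the fit deterministic.
#' @return A `state_model`: centroids (k x d, scaled space), scaler, terminal
#'   state ids, within-cluster sum of squares.
#' @export
fit_state_model <- function(events, features, k = 650L, nstart = 5L,
                            iter_max = 100L, seed = 1L) {
  X <- as.matrix(tibble::as_tibble(events)[, features, drop = FALSE])
  if (anyNA(X)) stop("events must be fully imputed before clustering",
                     call. = FALSE)
  if (nrow(X) < k ||
      (nrow(X) < 10 * k && nrow(unique(X)) < k)) {
    stop("k (", k, ") exceeds the number of distinct feature rows",
         call. = FALSE)
  }
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scale, "/")
  km <- withr::with_seed(seed, stats::kmeans(Z, centers = k, nstart = nstart,
                                             iter.max = iter_max))
  structure(list(
    k = as.integer(k),
    centroids = km$centers,
    center = center,
    scale = scale,
    features = features,
    terminal = c(survival = as.integer(k) + 1L, death = as.integer(k) + 2L),
    n_states = as.integer(k) + 2L,
    tot_withinss = km$tot.withinss,
    size = km$size,
    seed = as.integer(seed)
  ), class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat("<state_model> k =", x$k, "physiologic states (+2 terminal),",
      length(x$features), "features\n")
  invisible(x)
}

#' Assign feature rows to patient states
#'
#' Membership is the Euclidean-nearest cluster centroid in scaled feature
#' space; ties break to the lowest centroid index.
#'
#' @param model A `state_model`.
#' @param newdata Data frame or matrix of feature rows (manifest order or
#'   named columns).
#' @return Integer state ids in `1..k`.
#' @export
assign_state <- function(model, newdata) {
  stopifnot(inherits(model, "state_model"))
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(newdata[, model$features, drop = FALSE])
  }
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(model$features)) {
    stop("feature vector length does not match the model", call. = FALSE)
  }
  if (!all(is.finite(newdata))) {
    stop("non-finite feature values", call. = FALSE)
  }
  Z <- sweep(sweep(newdata, 2, model$center), 2, model$scale, "/")
  C <- model$centroids
  # squared distances via |z|^2 - 2 z.c + |c|^2; |z|^2 constant per row
  cross <- Z %*% t(C)
  d2 <- sweep(-2 * cross, 2, rowSums(C^2), "+")
  max.col(-d2, ties.method = "first")
}

#' Choose the number of states by information criteria
#'
#' Fits k-means for each candidate `k` and scores the solutions with BIC and
#' AIC under a spherical-Gaussian likelihood of the clustered data. The
#' BIC-minimizing `k` is returned; the full criterion table (including AIC
#' and within-cluster sum of squares) is attached for inspection.
#'
#' @param events Event tibble (training split).
#' @param features Feature column names.
#' @param ks Candidate cluster counts.
#' @param nstart,iter_max,seed Passed to the k-means fits.
#' @return List: `k` (chosen), `criteria` (tibble over candidates).
#' @export
select_k <- function(events, features, ks, nstart = 5L, iter_max = 100L,
                     seed = 1L) {
  stopifnot(length(ks) >= 1)
  X <- as.matrix(tibble::as_tibble(events)[, features, drop = FALSE])
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scale, "/")
  n <- nrow(Z)
  d <- ncol(Z)
  rows <- lapply(ks, function(k) {
    km <- withr::with_seed(seed + k, stats::kmeans(Z, centers = k,
                                                   nstart = nstart,
                                                   iter.max = iter_max))
    ll <- kmeans_loglik(n, d, k, km$tot.withinss, km$size)
    p <- (k - 1) + k * d + 1
    tibble::tibble(k = k, wss = km$tot.withinss, loglik = ll,
                   bic = -2 * ll + p * log(n), aic = -2 * ll + 2 * p)
  })
  criteria <- dplyr::bind_rows(rows)
  list(k = criteria$k[which.min(criteria$bic)], criteria = criteria)
}

# spherical-Gaussian log-likelihood of a k-means partition (x-means style)
kmeans_loglik <- function(n, d, k, wss, sizes) {
  if (n <= k) return(-Inf)
  sigma2 <- max(wss / (d * (n - k)), 1e-12)
  sum(sizes * log(pmax(sizes, 1) / n)) -
    n * d / 2 * log(2 * pi * sigma2) - d * (n - k) / 2
}

#' @export
tidy.state_model <- function(x, ...) {
  centroids <- tibble::as_tibble(x$centroids)
  names(centroids) <- x$features
  dplyr::bind_cols(tibble::tibble(state = seq_len(x$k), size = x$size),
                   centroids)
}

#' @export
glance.state_model <- function(x, ...) {
  tibble::tibble(k = x$k, n_states = x$n_states,
                 n_features = length(x$features),
                 tot_withinss = x$tot_withinss)
}
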