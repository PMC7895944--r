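#' Read an ICU trajectory cohort
#'
#' Reads a cohort of mechanically ventilated ICU stays binned in 4-hour time
#' steps. Delimited text (`.csv`, comma-separated, header row, UTF-8) and the
#' equivalent columnar binary dialect (`.parquet`, via the arrow package) are
#' supported. The table is validated against the manifest plus the fixed
#' columns: `stay_id`, `time_bin`, ventilator settings (`vt_set_ml`,
#' `peep_cmh2o`, `fio2_pct`), `height_cm`, `sex`, `age_years`, event flags
#' (`extubation`, `niv_start`, `suppl_o2`, `withdrawal`) and `outcome`.
#'
#' Unparseable cells become missing (`NA`) and their count is reported via a
#' message; a missing mandatory column raises a schema error naming the
#' column, and a duplicated `(stay_id, time_bin)` key raises an integrity
#' error.
#'
#' @param path File path (`.csv` or `.parquet`).
#' @param manifest Feature manifest, default [default_manifest()].
#' @param quiet Suppress informational messages.
#' @return A validated trajectory tibble ordered by `stay_id`, `time_bin`.
#' @export
read_cohort <- function(path, manifest = default_manifest(), quiet = FALSE) {
  validate_manifest(manifest)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("reading parquet requires the arrow package", call. = FALSE)
    }
    tab <- tibble::as_tibble(arrow::read_parquet(path))
    n_bad <- 0L
  } else {
    spec <- cohort_col_types(manifest)
    tab <- suppressWarnings(
      readr::read_csv(path, col_types = spec, na = c("", "NA"),
                      progress = FALSE)
    )  # schema mismatches are re-raised as named errors by validate_cohort
    probs <- readr::problems(tab)
    n_bad <- nrow(probs)
    attr(tab, "problems") <- NULL
    attr(tab, "spec") <- NULL
  }
  if (n_bad > 0 && !quiet) {
    message(n_bad, " unparseable cell(s) set to missing")
  }
  validate_cohort(tab, manifest)
}

cohort_col_types <- function(manifest) {
  cols <- list(
    stay_id = readr::col_character(),
    time_bin = readr::col_integer(),
    vt_set_ml = readr::col_double(),
    peep_cmh2o = readr::col_double(),
    fio2_pct = readr::col_double(),
    height_cm = readr::col_double(),
    sex = readr::col_character(),
    age_years = readr::col_double(),
    extubation = readr::col_logical(),
    niv_start = readr::col_logical(),
    suppl_o2 = readr::col_logical(),
    withdrawal = readr::col_logical(),
    outcome = readr::col_character()
  )
  for (f in manifest$feature) cols[[f]] <- readr::col_double()
  do.call(readr::cols, c(cols, .default = readr::col_double()))
}

#' Validate a trajectory table
#'
#' @param table Trajectory data frame.
#' @param manifest Feature manifest.
#' @return The table, ordered by `stay_id` and `time_bin`, invisibly valid.
#' @export
validate_cohort <- function(table, manifest = default_manifest()) {
  validate_manifest(manifest)
  table <- tibble::as_tibble(table)
  mandatory <- c(fixed_columns(), manifest$feature)
  missing_cols <- setdiff(mandatory, names(table))
  if (length(missing_cols) > 0) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  key <- paste(table$stay_id, table$time_bin, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("integrity error: duplicate (stay_id, time_bin): ",
         gsub("\r", ", ", dup), call. = FALSE)
  }
  bad_settings <- c(
    vt = any(table$vt_set_ml < 0, na.rm = TRUE),
    peep = any(table$peep_cmh2o < 0, na.rm = TRUE),
    fio2 = any(table$fio2_pct < 0, na.rm = TRUE)
  )
  if (any(bad_settings)) {
    stop("integrity error: negative ventilator setting(s) in column(s): ",
         paste(names(bad_settings)[bad_settings], collapse = ", "),
         call. = FALSE)
  }
  per_stay_outcomes <- tapply(table$outcome, table$stay_id,
                              function(x) length(unique(x[!is.na(x)])))
  if (any(per_stay_outcomes > 1)) {
    stop("integrity error: a stay has more than one distinct outcome",
         call. = FALSE)
  }
  dplyr::arrange(table, .data$stay_id, .data$time_bin)
}

#' Write a trajectory cohort
#'
#' Inverse of [read_cohort()]; dialect chosen from the file extension
#' (`.csv` or `.parquet`). Missing cells are written as `NA`.
#'
#' @param table Trajectory tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("writing parquet requires the arrow package", call. = FALSE)
    }
    arrow::write_parquet(table, path)
  } else {
    readr::write_csv(table, path, na = "NA", progress = FALSE)
  }
  invisible(path)
}

#' Resolve a run configuration
#'
#' Reads a YAML key-value file of run settings; unset keys take the documented
#' defaults. With `path = NULL` the full default configuration is returned.
#' Keys and defaults:
#'
#' * `gamma` (0.99): discount factor in (0, 1].
#' * `n_states` (650): number of k-means patient states (terminal
#'   survival/death states are two additional absorbing states).
#' * `n_models` (500): ensemble size for model selection.
#' * `split` (0.6, 0.2, 0.2): train/validation/test stay fractions, sum 1.
#' * `bootstrap_b` (1000): bootstrap resamples for WIS confidence bounds.
#' * `conf_levels` (0.90, 0.95): confidence levels for lower/upper bounds.
#' * `select_level` (0.95): lower-bound level maximized during selection.
#' * `epsilon` (0.05): softening mass spread over non-greedy eligible actions.
#' * `min_count` (5): minimum visits for an action to be eligible in a state.
#' * `hold_fallback` (2): sample-and-hold limit (bins) for features whose
#'   typical measurement interval cannot be estimated.
#' * `impute_method` ("knn"), `knn_k` (3), `svd_rank` (NULL = automatic),
#'   `discard_threshold` (0.5), `tukey_k` (1.5): imputation and outlier
#'   settings.
#' * `seed` (1): master seed.
#'
#' @param path Optional YAML file.
#' @param ... Named overrides applied after the file.
#' @param quiet Suppress the resolved-configuration message.
#' @return A named list with class `run_config`.
#' @export
load_config <- function(path = NULL, ..., quiet = TRUE) {
  defaults <- list(
    gamma = 0.99,
    n_states = 650L,
    n_models = 500L,
    split = c(train = 0.6, validation = 0.2, test = 0.2),
    bootstrap_b = 1000L,
    conf_levels = c(0.90, 0.95),
    select_level = 0.95,
    epsilon = 0.05,
    min_count = 5L,
    hold_fallback = 2L,
    impute_method = "knn",
    knn_k = 3L,
    svd_rank = NULL,
    discard_threshold = 0.5,
    tukey_k = 1.5,
    seed = 1L
  )
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown) > 0) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(user)] <- user
  }
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg <- validate_config(cfg)
  if (!quiet) {
    message("resolved configuration:\n",
            paste(utils::capture.output(utils::str(cfg)), collapse = "\n"))
  }
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$gamma) || cfg$gamma <= 0 || cfg$gamma > 1) {
    stop("validation error: gamma must lie in (0, 1]", call. = FALSE)
  }
  cfg$n_states <- as.integer(cfg$n_states)
  cfg$n_models <- as.integer(cfg$n_models)
  cfg$bootstrap_b <- as.integer(cfg$bootstrap_b)
  cfg$min_count <- as.integer(cfg$min_count)
  cfg$knn_k <- as.integer(cfg$knn_k)
  cfg$hold_fallback <- as.integer(cfg$hold_fallback)
  cfg$seed <- as.integer(cfg$seed)
  if (cfg$n_states < 1) stop("validation error: n_states must be positive",
                             call. = FALSE)
  if (cfg$n_models < 1) stop("validation error: n_models must be positive",
                             call. = FALSE)
  cfg$split <- unlist(cfg$split)
  if (length(cfg$split) != 3 || abs(sum(cfg$split) - 1) > 1e-8 ||
      any(cfg$split <= 0)) {
    stop("validation error: split must be three positive fractions summing to 1",
         call. = FALSE)
  }
  names(cfg$split) <- c("train", "validation", "test")
  cfg$conf_levels <- sort(unlist(cfg$conf_levels))
  if (any(cfg$conf_levels <= 0) || any(cfg$conf_levels >= 1)) {
    stop("validation error: conf_levels must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$select_level <= 0 || cfg$select_level >= 1) {
    stop("validation error: select_level must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$epsilon < 0 || cfg$epsilon >= 1) {
    stop("validation error: epsilon must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$discard_threshold < 0 || cfg$discard_threshold > 1) {
    stop("validation error: discard_threshold must lie in [0, 1]",
         call. = FALSE)
  }
  if (!cfg$impute_method %in% c("knn", "svd", "mean")) {
    stop("validation error: impute_method must be knn, svd or mean",
         call. = FALSE)
  }
  cfg
}

#' Write run artifacts to a report directory
#'
#' Serializes a named list of result objects: data frames go to delimited
#' text (`.csv`), everything else to JSON. A `run_log.txt` with the artifact
#' inventory is always written. Numeric payloads are written in full
#' precision, so a rerun with the same seed is byte-identical.
#'
#' @param results Named list of artifacts (data frames, OPE results, lists).
#' @param out_dir Output directory; created if needed.
#' @return Tibble manifest of written files (name, path).
#' @export
write_report <- function(results, out_dir) {
  stopifnot(is.list(results), !is.null(names(results)), all(names(results) != ""))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("I/O error: cannot create directory ", out_dir, call. = FALSE)
  }
  if (file.access(out_dir, 2) != 0) {
    stop("I/O error: directory not writable: ", out_dir, call. = FALSE)
  }
  paths <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (inherits(x, "ope_result")) x <- unclass_ope(x)
    if (is.data.frame(x)) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      readr::write_csv(tibble::as_tibble(x), p, progress = FALSE)
    } else {
      p <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, null = "null",
                           force = TRUE)
    }
    paths[nm] <- p
  }
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c("ventrl run report", paste0("artifact: ", names(paths))),
             log_path)
  tibble::tibble(name = names(paths), path = unname(paths))
}

# Strip heavyweight members of an OPE result for serialization.
unclass_ope <- function(x) {
  list(
    estimate = x$estimate,
    estimator = x$estimator,
    n_trajectories = x$n_trajectories,
    ess = x$ess,
    n_zero_weight = x$n_zero_weight,
    bounds = if (!is.null(x$bounds)) as.list(x$bounds) else NULL
  )
}
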