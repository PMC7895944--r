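#' Default patient data-fingerprint manifest
#'
#' The state space is built from a per-time-bin "data fingerprint" of 44
#' clinical features: demographics-adjacent measures, vitals, laboratory
#' values, fluid inputs/outputs and the Glasgow Coma Scale. The exact feature
#' list used on the original credentialed ICU databases is not public, so this
#' manifest is a documented stand-in with the same size and composition; every
#' function that consumes a manifest accepts a user-supplied replacement.
#'
#' Each feature carries a value kind (`continuous`, `binary`, `ordinal`) and
#' the aggregation used when collapsing raw charting into 4-hour bins:
#' `mean` for vitals and labs, `sum` for fluid volumes, `last` for ordinal
#' scores and set-once values.
#'
#' @return A tibble with columns `feature`, `kind`, `aggregation`, `unit`;
#'   44 rows for the default manifest.
#' @examples
#' nrow(default_manifest())
#' @export
default_manifest <- function() {
  vitals <- c(
    heart_rate = "bpm", sbp = "mmHg", dbp = "mmHg", map = "mmHg",
    resp_rate = "breaths/min", spo2 = "%", temp_c = "degC", cvp = "mmHg"
  )
  labs <- c(
    ph_arterial = "pH", pao2 = "mmHg", paco2 = "mmHg", base_excess = "mmol/L",
    lactate = "mmol/L", sodium = "mmol/L", potassium = "mmol/L",
    chloride = "mmol/L", bicarbonate = "mmol/L", glucose = "mg/dL",
    bun = "mg/dL", creatinine = "mg/dL", magnesium = "mg/dL",
    calcium = "mg/dL", phosphate = "mg/dL", albumin = "g/dL",
    total_bili = "mg/dL", alt = "U/L", ast = "U/L", inr = "ratio",
    pt = "s", ptt = "s", wbc = "10^9/L", hemoglobin = "g/dL",
    hematocrit = "%", platelets = "10^9/L"
  )
  derived <- c(pao2_fio2_ratio = "mmHg", mean_airway_pressure = "cmH2O",
               minute_volume = "L/min")
  fluids <- c(fluid_in_ml = "mL", fluid_out_ml = "mL", urine_out_ml = "mL")
  scores <- c(gcs = "points", sofa = "points")
  other <- c(weight_kg = "kg")
  binary <- c(vasopressor_use = "flag")

  tibble::tibble(
    feature = c(names(vitals), names(labs), names(derived), names(fluids),
                names(scores), names(other), names(binary)),
    kind = c(rep("continuous", length(vitals) + length(labs) + length(derived) +
                   length(fluids)),
             rep("ordinal", length(scores)), "continuous", "binary"),
    aggregation = c(rep("mean", length(vitals) + length(labs) + length(derived)),
                    rep("sum", length(fluids)),
                    rep("last", length(scores) + length(other) + length(binary))),
    unit = unname(c(vitals, labs, derived, fluids, scores, other, binary))
  )
}

#' Build a reduced synthetic feature manifest
#'
#' Convenience constructor for simulation studies that do not need the full
#' 44-feature fingerprint: `d` continuous features aggregated by mean.
#'
#' @param d Number of features.
#' @return A manifest tibble with `d` rows.
#' @export
synthetic_manifest <- function(d) {
  stopifnot(d >= 1)
  tibble::tibble(
    feature = sprintf("feat_%02d", seq_len(d)),
    kind = "continuous",
    aggregation = "mean",
    unit = "arb"
  )
}

validate_manifest <- function(manifest) {
  req <- c("feature", "kind", "aggregation", "unit")
  if (!all(req %in% names(manifest))) {
    stop("manifest must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(manifest) == 0) stop("manifest is empty", call. = FALSE)
  if (anyDuplicated(manifest$feature)) {
    stop("manifest feature names must be unique", call. = FALSE)
  }
  if (!all(manifest$kind %in% c("continuous", "binary", "ordinal"))) {
    stop("manifest kind must be continuous, binary or ordinal", call. = FALSE)
  }
  if (!all(manifest$aggregation %in% c("mean", "sum", "last"))) {
    stop("manifest aggregation must be mean, sum or last", call. = FALSE)
  }
  invisible(manifest)
}

#' Feature names of a manifest
#' @param manifest A manifest tibble (see [default_manifest()]).
#' @return Character vector of feature names.
#' @export
feature_names <- function(manifest) {
  validate_manifest(manifest)
  manifest$feature
}

# Fixed (non-manifest) trajectory-table columns, in canonical order.
fixed_columns <- function() {
  c("stay_id", "time_bin", "vt_set_ml", "peep_cmh2o", "fio2_pct",
    "height_cm", "sex", "age_years",
    "extubation", "niv_start", "suppl_o2", "withdrawal", "outcome")
}
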