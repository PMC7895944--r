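# Small hand-built fixtures shared across test files.

tiny_manifest <- function(d = 3) synthetic_manifest(d)

# A minimal valid trajectory table: `settings` rows are recycled per stay.
make_stay <- function(stay_id, bins, vt = NA_real_, peep = NA_real_,
                      fio2 = NA_real_, feats = NULL, outcome = "survived",
                      age = 60, height = 170, sex = "male",
                      extubation = FALSE, niv = FALSE, suppl = FALSE,
                      withdrawal = FALSE, d = 3) {
  n <- length(bins)
  tab <- tibble::tibble(
    stay_id = stay_id, time_bin = as.integer(bins),
    vt_set_ml = rep_len(vt, n), peep_cmh2o = rep_len(peep, n),
    fio2_pct = rep_len(fio2, n),
    height_cm = height, sex = sex, age_years = age,
    extubation = rep_len(extubation, n), niv_start = rep_len(niv, n),
    suppl_o2 = rep_len(suppl, n), withdrawal = rep_len(withdrawal, n),
    outcome = outcome
  )
  if (is.null(feats)) {
    feats <- matrix(stats::rnorm(n * d), n, d)
  }
  colnames(feats) <- tiny_manifest(d)$feature
  dplyr::bind_cols(tab, tibble::as_tibble(feats))
}

# A qualifying 3-stay cohort (>= 6 post-onset bins each).
make_tiny_cohort <- function(seed = 42, d = 3) {
  withr::with_seed(seed, dplyr::bind_rows(
    make_stay("s1", 0:8, vt = 420, peep = 6, fio2 = 40, d = d),
    make_stay("s2", 0:9, vt = 380, peep = 8, fio2 = 50, outcome = "died",
              sex = "female", height = 160, d = d),
    make_stay("s3", 0:7, vt = 500, peep = 5, fio2 = 35, d = d)
  ))
}
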