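test_that("ideal body weight matches the sex-specific prediction formula", {
  expect_equal(ideal_body_weight("male", 152.4), 50)
  expect_equal(ideal_body_weight("female", 152.4), 45.5)
  expect_equal(ideal_body_weight("male", 172.4), 68.2)
  expect_equal(ideal_body_weight(c("male", "female"), c(152.4, 152.4)),
               c(50, 45.5))
  expect_error(ideal_body_weight("male", 0), "height")
  expect_error(ideal_body_weight("other", 170), "sex")
})

test_that("event definition applies the onset/continuation/termination rules", {
  man <- tiny_manifest()
  # Vt at bin 1, PEEP at bins 2-8, extubation at bin 9 -> 8 post-onset bins
  s <- make_stay("a", 0:9, vt = c(NA, 420, rep(NA, 8)),
                 peep = c(NA, NA, rep(6, 7), NA),
                 extubation = c(rep(FALSE, 9), TRUE))
  ev <- define_ventilation_events(s, man)
  expect_equal(max(ev$rel_bin), 8)
  expect_equal(sum(ev$rel_bin >= 1), 8)
  expect_equal(unique(ev$onset_bin), 1)
  # pre-onset bin retained with rel_bin 0
  expect_true(0 %in% ev$rel_bin)

  # event of 5 post-onset bins (20 h) -> too short, dropped
  short <- make_stay("b", 0:4, vt = 420, peep = 6, fio2 = 40)
  ev2 <- define_ventilation_events(short, man)
  expect_equal(nrow(ev2), 0)
  expect_true("too_short" %in% attr(ev2, "drop_log")$reason)

  # two separated events: only the first qualifying one is kept
  two <- make_stay("c", 0:20,
                   vt = c(rep(420, 7), rep(NA, 6), rep(380, 8)))
  ev3 <- define_ventilation_events(two, man)
  expect_equal(unique(ev3$onset_bin), 0)
  expect_equal(max(ev3$time_bin), 6)

  # settings gap beyond 8 h terminates the event at the gap
  gap <- make_stay("d", 0:19,
                   vt = c(rep(420, 7), rep(NA, 10), rep(380, 3)))
  ev4 <- define_ventilation_events(gap, man)
  expect_equal(max(ev4$time_bin[ev4$stay_id == "d"]), 6)
})

test_that("inclusion filters drop under-age, withdrawn and undocumented stays", {
  man <- tiny_manifest()
  base <- function(id, ...) make_stay(id, 0:8, vt = 420, peep = 6,
                                      fio2 = 40, ...)
  tab <- dplyr::bind_rows(
    base("ok"),
    base("minor", age = 17),
    base("withdrawn", withdrawal = c(rep(FALSE, 5), TRUE, rep(FALSE, 3))),
    dplyr::mutate(base("no_outcome"), outcome = NA_character_)
  )
  ev <- define_ventilation_events(tab, man)
  expect_identical(unique(ev$stay_id), "ok")
  log <- attr(ev, "drop_log")
  expect_setequal(
    log$reason,
    c("age_18_or_under", "treatment_withdrawal", "outcome_undocumented")
  )
})

test_that("events are clipped to the 72-h observation window", {
  man <- tiny_manifest()
  long <- make_stay("w", 0:30, vt = 420, peep = 6, fio2 = 40)
  ev <- define_ventilation_events(long, man)
  expect_equal(max(ev$rel_bin), 18)
})

test_that("event definition is idempotent on its own output", {
  man <- tiny_manifest()
  tab <- make_tiny_cohort()
  ev1 <- define_ventilation_events(tab, man)
  again <- dplyr::select(ev1, -"rel_bin", -"onset_bin", -"ibw_kg")
  again$extubation <- FALSE
  again$niv_start <- FALSE
  again$suppl_o2 <- FALSE
  again$withdrawal <- FALSE
  ev2 <- define_ventilation_events(again, man)
  expect_equal(ev2$time_bin, ev1$time_bin)
  expect_equal(ev2$vt_set_ml, ev1$vt_set_ml)
  expect_equal(ev2$onset_bin, ev1$onset_bin)
})

test_that("hold limits equal the median inter-measurement gap", {
  man <- tiny_manifest(1)
  every_bin <- make_stay("a", 0:9, vt = 420,
                         feats = matrix(1, 10, 1), d = 1)
  expect_identical(unname(estimate_hold_limits(every_bin, man)), 1L)

  sparse3 <- make_stay("b", 0:9, vt = 420,
                       feats = matrix(c(1, NA, NA, 1, NA, NA, 1, NA, NA, 1),
                                      10, 1), d = 1)
  expect_identical(unname(estimate_hold_limits(sparse3, man)), 3L)

  # gap multiset {1, 1, 5}: median 1
  mixed <- make_stay("c", 0:7,
                     feats = matrix(c(1, 1, 1, NA, NA, NA, NA, 1), 8, 1),
                     vt = 420, d = 1)
  expect_identical(unname(estimate_hold_limits(mixed, man)), 1L)

  # unobservable feature falls back
  none <- make_stay("d", 0:5, vt = 420, feats = matrix(NA_real_, 6, 1), d = 1)
  expect_identical(unname(estimate_hold_limits(none, man, fallback = 2L)), 2L)
  expect_error(estimate_hold_limits(none[0, ], man), "empty")
})

test_that("sample-and-hold honours the hold limit", {
  expect_equal(sample_and_hold(c(7, NA, NA, NA), 2), c(7, 7, 7, NA))
  expect_equal(sample_and_hold(c(1, 2, 3), 2), c(1, 2, 3))
  expect_equal(sample_and_hold(c(NA, 3, NA), 1), c(NA, 3, 3))
  # property: every filled cell has an observation within `limit` bins before
  withr::with_seed(11, {
    for (rep_i in 1:20) {
      x <- ifelse(runif(30) < 0.5, NA, rnorm(30))
      limit <- sample(1:4, 1)
      y <- sample_and_hold(x, limit)
      for (t in which(is.na(x) & !is.na(y))) {
        window <- x[max(1, t - limit):t]
        expect_true(any(!is.na(window)))
        last_obs <- max(which(!is.na(x[1:t])))
        expect_identical(y[t], x[last_obs])
      }
      expect_identical(y[!is.na(x)], x[!is.na(x)])
    }
  })
})

test_that("cohort-level sample-and-hold never leaks across stays", {
  man <- tiny_manifest(1)
  tab <- dplyr::bind_rows(
    make_stay("a", 0:3, vt = 420, feats = matrix(c(5, NA, NA, NA), 4, 1),
              d = 1),
    make_stay("b", 0:3, vt = 420, feats = matrix(c(NA, 9, NA, NA), 4, 1),
              d = 1)
  )
  held <- apply_sample_and_hold(tab, man, limits = c(feat_01 = 2L))
  a <- held$feat_01[held$stay_id == "a"]
  b <- held$feat_01[held$stay_id == "b"]
  expect_equal(a, c(5, 5, 5, NA))
  expect_equal(b, c(NA, 9, 9, 9))
})

test_that("Tukey fences flag exactly the hand-computed outliers", {
  x <- c(1:9, 100)
  # quartiles (type 7): Q1 = 3.25, Q3 = 7.75, IQR = 4.5 -> fences [-3.5, 14.5]
  expect_identical(which(tukey_outlier_filter(x)), 10L)
  expect_false(any(tukey_outlier_filter(1:9)))
  expect_false(any(tukey_outlier_filter(rep(5, 10))))
  expect_warning(tukey_outlier_filter(c(NA, NA, NA)), "missing")
  expect_warning(tukey_outlier_filter(c(1, 2, 3)), "fewer than 4")
  # frequency mode also trims the empirical 5% tails
  y <- as.numeric(1:100)
  expect_false(any(tukey_outlier_filter(y)))
  # 90% interval (type-7 quantiles) is [5.95, 95.05] -> 1..5 and 96..100
  expect_identical(sum(tukey_outlier_filter(y, frequency_interval = TRUE)),
                   10L)
})

test_that("events over the 50% missing threshold are discarded, others kept", {
  man <- tiny_manifest(2)
  feats_bad <- matrix(NA_real_, 9, 2)
  feats_bad[1:3, 1] <- 1  # 3 of 18 cells observed -> 83% missing
  feats_ok <- matrix(1, 9, 2)
  feats_ok[1:4, 1] <- NA  # 4 of 18 missing -> 22%
  tab <- dplyr::bind_rows(
    make_stay("bad", 0:8, vt = 420, feats = feats_bad, d = 2),
    make_stay("ok", 0:8, vt = 420, feats = feats_ok, d = 2)
  )
  ev <- define_ventilation_events(tab, man)
  res <- impute_events(ev, man, method = "mean")
  expect_identical(res$n_discarded, 1L)
  expect_identical(res$discarded_stays, "bad")
  expect_false(anyNA(res$events[, man$feature]))

  # exactly at the threshold: event survives (discard iff fraction > 0.5)
  feats_half <- matrix(c(rep(1, 9), rep(NA_real_, 9)), 9, 2)
  tab2 <- make_stay("half", 0:8, vt = 420, feats = feats_half, d = 2)
  ev2 <- define_ventilation_events(tab2, man)
  res2 <- suppressWarnings(impute_events(ev2, man, method = "mean"))
  expect_identical(res2$n_discarded, 0L)
})

test_that("kNN imputation recovers a twin row's value with k = 1", {
  man <- tiny_manifest(4)
  feats <- matrix(rnorm(36), 9, 4)
  feats[5, ] <- feats[4, ]   # identical twin rows
  feats[5, 3] <- NA          # one missing cell
  tab <- make_stay("t", 0:8, vt = 420, feats = feats, d = 4)
  ev <- define_ventilation_events(tab, man)
  res <- impute_events(ev, man, method = "knn", k = 1)
  i <- which(res$events$time_bin == 4)
  expect_equal(res$events$feat_03[i], feats[4, 3])
  # observed cells are untouched
  obs <- !is.na(feats)
  expect_equal(as.matrix(res$events[, man$feature])[obs], feats[obs])
})

test_that("SVD completion recovers a deleted entry of a rank-1 matrix", {
  u <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  v <- c(2, -1, 0.5, 3)
  X <- outer(u, v)
  X_del <- X
  X_del[3, 2] <- NA
  rec <- ventrl:::impute_svd(X_del, rank = 1, max_iter = 200, tol = 1e-10)
  expect_lt(abs(rec[3, 2] - X[3, 2]) / abs(X[3, 2]), 1e-6)
  expect_equal(rec[!is.na(X_del)], X[!is.na(X_del)])
})

test_that("imputation output is complete for all three methods", {
  man <- tiny_manifest(4)
  withr::with_seed(5, {
    feats <- matrix(rnorm(40 * 4), 40, 4)
    feats[runif(160) < 0.2] <- NA
  })
  tab <- dplyr::bind_rows(
    make_stay("a", 0:19, vt = 420, feats = feats[1:20, ], d = 4),
    make_stay("b", 0:19, vt = 420, feats = feats[21:40, ], d = 4)
  )
  ev <- define_ventilation_events(tab, man)
  for (m in c("knn", "svd", "mean")) {
    res <- impute_events(ev, man, method = m)
    expect_false(anyNA(res$events[, man$feature]))
    obs <- !is.na(ev[, man$feature])
    expect_equal(as.matrix(res$events[, man$feature])[obs],
                 as.matrix(ev[, man$feature])[obs])
    expect_true(all(res$diagnostics$imputed_fraction >= 0))
  }
})

test_that("missingness diagnostic separates MCAR from a constructed MAR", {
  man <- tiny_manifest(4)
  withr::with_seed(21, {
    n <- 1000
    X <- matrix(rnorm(n * 4), n, 4)
    # MCAR on all features
    X_mcar <- X
    X_mcar[matrix(runif(n * 4) < 0.15, n, 4)] <- NA
    tab <- tibble::tibble(stay_id = sprintf("s%04d", seq_len(n)),
                          time_bin = 0L)
    tab <- dplyr::bind_cols(tab, tibble::as_tibble(as.data.frame(X_mcar)) |>
                              rlang::set_names(man$feature))
    diag_mcar <- missingness_diagnostic(tab, man)
    expect_true(all(diag_mcar$status == "tested"))
    expect_lt(mean(diag_mcar$p_value < 0.05), 0.10 + 1e-9)

    # MAR: feature 2 goes missing exactly when feature 1 exceeds its median
    X_mar <- X
    X_mar[X[, 1] > stats::median(X[, 1]), 2] <- NA
    tab2 <- tibble::tibble(stay_id = sprintf("s%04d", seq_len(n)),
                           time_bin = 0L)
    tab2 <- dplyr::bind_cols(tab2, tibble::as_tibble(as.data.frame(X_mar)) |>
                               rlang::set_names(man$feature))
    diag_mar <- missingness_diagnostic(tab2, man)
    expect_lt(diag_mar$p_value[diag_mar$feature == "feat_02"], 1e-3)
    expect_identical(diag_mar$covariate[diag_mar$feature == "feat_02"],
                     "feat_01")
    # fully observed features are marked not applicable
    expect_true(all(diag_mar$status[diag_mar$feature != "feat_02"] ==
                      "not_applicable"))
  })
})
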