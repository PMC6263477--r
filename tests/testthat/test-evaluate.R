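test_that("event matching handles the canonical small cases", {
  cc <- match_events(c(100, 500), c(102, 700), tolerance = 3, n_windows = 100)
  expect_equal(cc$tp, 1L)
  expect_equal(cc$fn, 1L)
  expect_equal(cc$fp, 1L)
  expect_equal(cc$delta_t, 2)

  same <- match_events(c(10, 200, 900), c(10, 200, 900), n_windows = 50)
  expect_equal(same$tp, 3L)
  expect_equal(same$fn + same$fp, 0L)
  expect_true(all(same$delta_t == 0))

  expect_error(match_events(1, 1, tolerance = -1, n_windows = 10),
               "non-negative")
})

test_that("matching is maximum-cardinality against a brute-force oracle", {
  set.seed(55)
  for (rep in 1:200) {
    n_t <- sample(0:5, 1)
    n_d <- sample(0:5, 1)
    truth <- sort(sample(1:60, n_t))
    dets <- sort(sample(1:60, n_d))
    tol <- sample(0:4, 1)
    cc <- match_events(truth, dets, tolerance = tol, n_windows = 10)
    expect_equal(cc$tp, brute_force_match_count(truth, dets, tol))
    # conservation laws
    expect_equal(cc$tp + cc$fn, length(truth))
    expect_equal(cc$tp + cc$fp, length(dets))
    expect_true(all(abs(cc$delta_t) <= tol))
  }
})

test_that("performance indices follow the TP/FN/FP/TN definitions", {
  mk <- function(tp, fn, fp, tn, dt = numeric(0)) {
    structure(list(tp = tp, fn = fn, fp = fp, tn = tn, delta_t = dt),
              class = "confusion_counts")
  }
  pm <- performance_metrics(mk(9, 1, 1, 989, dt = rep(2, 9)))
  expect_equal(pm$acc, 100 * 9 / 11, tolerance = 1e-12)
  expect_equal(pm$sen, 90)
  expect_equal(pm$spe, 100 * 989 / 990, tolerance = 1e-12)
  expect_equal(pm$mean_abs_dt_ms, 0.2)
  expect_equal(pm$median_abs_dt_samples, 2)

  perfect <- performance_metrics(mk(5, 0, 0, 100))
  expect_equal(c(perfect$acc, perfect$sen, perfect$spe), c(100, 100, 100))

  worst <- performance_metrics(mk(0, 10, 0, 100))
  expect_equal(c(worst$acc, worst$sen, worst$spe), c(0, 0, 100))

  undef <- performance_metrics(mk(0, 0, 0, 0))
  expect_true(is.na(undef$acc) && is.na(undef$sen) && is.na(undef$spe))

  # scale-free in the counts
  a <- performance_metrics(mk(4, 2, 1, 50))
  b <- performance_metrics(mk(40, 20, 10, 500))
  expect_equal(c(a$acc, a$sen, a$spe), c(b$acc, b$sen, b$spe))
})

test_that("pooled counts equal the sum of per-recording counts", {
  cc1 <- match_events(c(100, 300), c(100, 305), n_windows = 20)
  cc2 <- match_events(c(50), c(50, 800), n_windows = 30)
  pooled <- pool_counts(cc1, cc2)
  expect_equal(pooled$tp, cc1$tp + cc2$tp)
  expect_equal(pooled$fp, cc1$fp + cc2$fp)
  expect_equal(pooled$tn, cc1$tn + cc2$tn)
  expect_equal(pooled$n_windows, 50)
})

test_that("threshold sweep is ROC-monotone on a seeded scenario set", {
  scenarios <- lapply(64:65, function(s) simulate_scenario(1, 3.5, seed = s))
  grid <- c(0.015, 0.020, 0.024, 0.030, 0.040)
  sw <- threshold_sweep(scenarios, grid = grid)
  expect_s3_class(sw, "threshold_sweep")
  expect_equal(nrow(sw), length(grid))
  expect_true(all(diff(sw$sen) <= 0))
  expect_true(all(diff(sw$spe) >= 0))

  # a one-point grid reduces to a single detect + match + metrics pass
  one <- threshold_sweep(scenarios[1], grid = 0.024)
  det <- detect_crackles(scenarios[[1]]$recording, threshold = 0.024)
  cc <- match_events(scenarios[[1]], det)
  pm <- performance_metrics(cc)
  expect_equal(one$sen, pm$sen)
  expect_equal(one$spe, pm$spe)
  expect_equal(one$tp, cc$tp)
})

test_that("threshold selection implements corner distance and accuracy max", {
  sweep <- data.frame(
    threshold = seq(0.010, 0.060, by = 0.001)
  )
  # synthetic curves: Sen decays, Spe saturates, Acc peaks at 0.029
  sweep$sen <- 100 - 60 * pmax(sweep$threshold - 0.019, 0) / 0.041 -
    200 * pmax(0.019 - sweep$threshold, 0)
  sweep$spe <- 100 - 800 * pmax(0.019 - sweep$threshold, 0)
  sweep$acc <- 90 - 4000 * (sweep$threshold - 0.029)^2
  sel <- select_threshold(sweep)
  expect_equal(sel$thr_lower, 0.019)
  expect_equal(sel$thr_upper, 0.029)
  expect_equal(sel$thr_mid, 0.024)

  # brute-force corner-distance scan agrees on random sweeps
  set.seed(77)
  for (rep in 1:20) {
    rnd <- data.frame(threshold = seq(0.01, 0.06, length.out = 11),
                      sen = stats::runif(11, 50, 100),
                      spe = stats::runif(11, 50, 100),
                      acc = stats::runif(11, 50, 100))
    sel <- select_threshold(rnd)
    d <- sqrt((100 - rnd$sen)^2 + (100 - rnd$spe)^2)
    expect_equal(sel$thr_lower, rnd$threshold[which.min(d)])
    expect_equal(sel$thr_upper, rnd$threshold[which.max(rnd$acc)])
    expect_equal(sel$thr_mid, (sel$thr_lower + sel$thr_upper) / 2)
  }

  # dominance: a threshold best in both Sen and Spe is the lower limit
  dom <- data.frame(threshold = c(0.01, 0.02, 0.03),
                    sen = c(80, 95, 90), spe = c(90, 99, 98),
                    acc = c(70, 85, 80))
  expect_equal(select_threshold(dom)$thr_lower, 0.02)

  flat <- data.frame(threshold = c(0.01, 0.02, 0.03),
                     sen = c(90, 90, 90), spe = c(99, 99, 99),
                     acc = c(80, 80, 80))
  expect_warning(sel <- select_threshold(flat), "degenerate")
  expect_equal(sel$thr_mid, 0.02)

  expect_error(select_threshold(flat[1:2, ]), "at least 3")
})

test_that("report CSV export has the Acc/Sen/Spe/|dt| shape", {
  rows <- list(list(scenario = 1, gain = 3.5,
                    report = performance_metrics(
                      match_events(c(100), c(101), n_windows = 50))))
  p <- withr::local_tempfile(fileext = ".csv")
  write_report_csv(rows, p)
  df <- utils::read.csv(p)
  expect_equal(names(df),
               c("scenario", "gain", "acc", "sen", "spe", "mean_abs_dt_ms"))
  expect_equal(df$sen, 100)
})
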