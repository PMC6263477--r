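test_that("coefficient derivatives difference correctly", {
  A <- matrix(1.5, nrow = 50, ncol = 4)
  expect_true(all(coefficient_derivatives(A) == 0))

  B <- matrix(0, nrow = 50, ncol = 4)
  B[20:50, 1] <- 1  # unit step in a1 at row 20
  D <- coefficient_derivatives(B)
  expect_equal(which(D[, 1] != 0), 19L)
  expect_equal(D[19, 1], 1)

  set.seed(4)
  C <- matrix(stats::rnorm(200), ncol = 4)
  D <- coefficient_derivatives(C)
  expect_equal(colSums(D), C[50, ] - C[1, ])  # telescoping

  expect_error(coefficient_derivatives(matrix(1, 1, 4)), "two rows")
})

test_that("phase assignment follows the guided maneuver timing", {
  m <- maneuver_template()
  expect_equal(duration(m), 20)
  ph <- assign_phase(c(1.0, 2.5, 4.0, 19.5), m)
  expect_equal(ph$phase, c("apnea", "inspiration", "expiration", "apnea"))
  expect_equal(ph$cycle, c(NA, 1L, 1L, NA))
  # boundary: inspiration spans [2 + 4c, 2 + 4c + 1.6)
  expect_equal(assign_phase(2 + 4 * 2 + 1.6, m)$phase, "expiration")
  expect_equal(assign_phase(2 + 4 * 3, m)$cycle, 4L)
  expect_error(assign_phase(25, m), "outside")
})

test_that("per-phase count tables conserve totals and ignore order", {
  m <- maneuver_template()
  empty <- summarize_counts(data.frame(phase = character(0),
                                       cycle = integer(0)), m)
  expect_true(all(empty$count == 0))

  ev <- data.frame(phase = c(rep("inspiration", 3), rep("expiration", 2)),
                   cycle = c(2L, 2L, 2L, 3L, 3L))
  tab <- summarize_counts(ev, m)
  expect_equal(sum(tab$count), 5L)
  expect_equal(tab$count[tab$cycle == 2 & tab$phase == "inspiration"], 3L)
  expect_equal(tab$count[tab$cycle == 3 & tab$phase == "expiration"], 2L)

  perm <- ev[sample(nrow(ev)), ]
  expect_identical(summarize_counts(perm, m), tab)
})

test_that("crackle-free stationary background yields no detections at the grid top", {
  x <- ar4_background(n = 30000, seed = 31)
  det <- detect_crackles(x, fs = 1e4, threshold = 0.060)
  expect_equal(nrow(det$events), 0L)
})

test_that("a single inserted gain-3.5 fine crackle is localized within 3 samples", {
  basal <- basal_surrogate(seed = 41)
  on <- 30000  # mid-inspiration of cycle 1
  x <- insert_one_crackle(basal$samples, on, "fine", 3.5)
  det <- detect_crackles(x, fs = 1e4)
  hits <- det$events$onset_sample[abs(det$events$onset_sample - on) <= 3]
  # the crackle spans two analysis windows, so it may fire in both
  expect_gte(length(hits), 1L)
  expect_lte(length(hits), 2L)
})

test_that("detections are threshold-monotone and reproducible", {
  sc <- simulate_scenario(1, gain = 3.5, seed = 51)
  d1 <- detect_crackles(sc$recording, threshold = 0.020)
  d2 <- detect_crackles(sc$recording, threshold = 0.030)
  expect_true(all(d2$events$onset_sample %in% d1$events$onset_sample))
  expect_gte(nrow(d1$events), nrow(d2$events))

  d1b <- detect_crackles(sc$recording, threshold = 0.020)
  expect_identical(d1$events, d1b$events)

  # events are strictly increasing and inside the recording
  expect_true(all(diff(d1$events$onset_sample) > 0))
  expect_true(all(d1$events$onset_sample >= 1 &
                    d1$events$onset_sample <= length(sc$recording$samples)))
})

test_that("every emitted event satisfies the six-step rule recomputed by hand", {
  sc <- simulate_scenario(1, gain = 3.5, seed = 61)
  thr <- 0.024
  det <- detect_crackles(sc$recording, threshold = thr)
  expect_gt(nrow(det$events), 10)

  fit <- tvar_rls(sc$recording$samples)
  D <- diff(fit$coeffs)
  sum_abs <- rowSums(abs(D))
  for (g in det$events$onset_sample) {
    w <- ceiling(g / 40)             # non-overlapping 40-sample windows
    lo <- (w - 1) * 40 + 1
    hi <- min(lo + 39, nrow(D))
    sds <- apply(D[lo:hi, ], 2, stats::sd)
    expect_true(all(sds > thr))
    expect_equal(g, lo + which.max(sum_abs[lo:hi]) - 1L)  # in-window argmax
    expect_gt(sum_abs[g] - sum_abs[g - 1], 0)             # rising before
    expect_lt(sum_abs[g + 1] - sum_abs[g], 0)             # falling after
  }
})

test_that("detection rate increases weakly with insertion gain", {
  hits <- sapply(c(1.5, 2.5, 3.5), function(g) {
    n_hit <- 0L
    for (seed in 1:8) {
      x <- ar4_background(n = 12000, seed = 70 + seed)
      on <- 6000 + 37 * seed
      y <- insert_one_crackle(x, on, "fine", g)
      det <- detect_crackles(y, fs = 1e4)
      if (any(abs(det$events$onset_sample - on) <= 3)) n_hit <- n_hit + 1L
    }
    n_hit
  })
  expect_true(all(diff(hits) >= 0))
})

test_that("detector enforces its input contracts", {
  expect_error(detect_crackles(ar4_background(1000) * 3, fs = 1e4),
               "\\[-1, 1\\]")
  raw <- sound_recording(stats::rnorm(1000), fs = 1e4, stage = "raw")
  expect_error(detect_crackles(raw), "preprocess")
  expect_error(detect_crackles(ar4_background(10), fs = 1e4),
               "window")
  expect_error(detect_crackles(ar4_background(1000), fs = 1e4,
                               threshold = -1), "positive")
})

test_that("detection text export is parseable, one event per line", {
  sc <- simulate_scenario(1, gain = 3.5, seed = 81)
  det <- detect_crackles(sc$recording, maneuver = maneuver_template())
  p <- withr::local_tempfile(fileext = ".txt")
  write_detections(det, p)
  lines <- readLines(p)
  expect_equal(length(lines), nrow(det$events))
  parts <- strsplit(lines[1], "\t")[[1]]
  expect_length(parts, 4)
  expect_false(is.na(as.integer(parts[1])))
  expect_false(is.na(as.numeric(parts[2])))
  expect_true(parts[3] %in% c("inspiration", "expiration", "apnea", "unknown"))
})
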