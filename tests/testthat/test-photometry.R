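make_session <- function(n = 4000, rate = 40, f0 = 20, events = NULL) {
  t <- (seq_len(n) - 1) / rate
  if (is.null(events))
    events <- data.frame(label = "investigation", start_s = 130,
                         stop_s = 132)
  photometry_session(t, rep(100, n) + f0, rep(100, n), rate,
                     c(0, 120), events)
}

test_that("session construction validates its invariants", {
  expect_error(make_session(events = data.frame(label = "x", start_s = 1)),
               "label, start_s, stop_s")
  t <- (0:99) / 40
  expect_error(photometry_session(t, rnorm(100), rnorm(100), 50,
                                  c(0, 1), data.frame(label = character(),
                                                      start_s = numeric(),
                                                      stop_s = numeric())),
               "inconsistent")
  expect_warning(photometry_session(t, rnorm(100), rnorm(100), 40,
                                    c(0, 2),
                                    data.frame(label = "a", start_s = 1,
                                               stop_s = 1.5)),
                 "baseline window")
})

test_that("preprocessing follows the dF/F and z-score algebra exactly", {
  # constant corrected trace: dF/F identically zero, z-score undefined
  expect_error(preprocess(make_session()), "zero variance")
  # 10% step at t0: dF/F steps from 0 to 0.1 exactly
  n <- 8000; rate <- 40
  t <- (seq_len(n) - 1) / rate
  f0 <- 50
  corrected <- f0 * (1 + 0.1 * (t >= 150))
  s <- photometry_session(t, corrected + 100, rep(100, n), rate, c(0, 120),
                          data.frame(label = "investigation",
                                     start_s = 150, stop_s = 152))
  tr <- preprocess(s)
  expect_equal(tr$f0, f0)
  expect_equal(unique(round(tr$dff[t < 150], 12)), 0)
  expect_equal(unique(round(tr$dff[t >= 150], 12)), 0.1)
  expect_equal(mean(tr$z), 0, tolerance = 1e-10)
  expect_equal(stats::sd(tr$z), 1, tolerance = 1e-10)
  # F0 <= 0 is an explicit contract violation
  s2 <- photometry_session(t, rep(100, n), rep(100, n) + 1, rate, c(0, 120),
                           s$events)
  expect_error(preprocess(s2), "not positive")
})

test_that("preprocessing is invariant to affine rescaling of raw units", {
  cfg <- photom_sim_config(duration_s = 300, event_times_s = c(150, 200),
                           noise_sd = 0.3, seed = 31)
  s <- simulate_photometry(cfg)
  z1 <- preprocess(s)$z
  s2 <- s
  s2$signal <- 2.5 * s$signal
  s2$control <- 2.5 * s$control
  z2 <- preprocess(s2)$z
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("bout classification applies the gap rule", {
  ev <- data.frame(
    label = c("investigation", "attack", "investigation", "investigation",
              "attack"),
    start_s = c(10, 13, 30, 50, 62),
    stop_s = c(12, 15, 32, 52, 64))
  cl <- classify_bouts(ev, gap_s = 2)
  expect_equal(cl$bout_class,
               c("investigation_preceding_attack",
                 "attack_with_prior_investigation",
                 "investigation_isolated",
                 "investigation_isolated",
                 "attack_without_prior_investigation"))
  expect_equal(attr(cl, "session_class"), "attack_day")
  no_atk <- classify_bouts(ev[ev$label == "investigation", ])
  expect_true(all(no_atk$bout_class == "investigation_isolated"))
  expect_equal(attr(no_atk, "session_class"), "no_attack_day")
  bad <- data.frame(label = "attack", start_s = c(1, 2), stop_s = c(3, 4))
  expect_error(classify_bouts(bad), "overlapping")
})

test_that("classification agrees with a brute-force interval scan", {
  set.seed(12)
  for (i in 1:25) {
    n_inv <- sample(1:6, 1); n_atk <- sample(0:4, 1)
    inv <- sort(sample(seq(0, 480, by = 6), n_inv))
    atk <- if (n_atk) sort(sample(seq(3, 483, by = 6), n_atk)) else numeric()
    ev <- rbind(
      data.frame(label = "investigation", start_s = inv, stop_s = inv + 2),
      if (n_atk) data.frame(label = "attack", start_s = atk,
                            stop_s = atk + 2))
    gap <- sample(c(1, 2, 5), 1)
    cl <- classify_bouts(ev, gap_s = gap)
    for (r in which(cl$label == "investigation")) {
      expected <- any(atk >= cl$stop_s[r] & atk <= cl$stop_s[r] + gap)
      expect_equal(cl$bout_class[r] == "investigation_preceding_attack",
                   expected)
    }
  }
})

test_that("peri-event extraction aligns, excludes and duplicates correctly", {
  cfg <- photom_sim_config(duration_s = 300, event_times_s = 150,
                           noise_sd = 0, seed = 1)
  s <- simulate_photometry(cfg)
  # one event too close to the recording start is excluded and counted;
  # two events at the same onset give identical rows
  ev <- data.frame(label = "investigation", start_s = c(2, 150, 150),
                   stop_s = c(3, 151, 151))
  tr <- preprocess(s)
  sets <- peri_event(tr, ev, window_s = c(4, 4))
  set <- sets$investigation
  expect_equal(set$n_excluded, 1)
  expect_equal(nrow(set$matrix), 2)
  expect_equal(ncol(set$matrix), 8 * s$rate_hz)
  expect_identical(set$matrix[1, ], set$matrix[2, ])
  # the planted transient peaks after the alignment index
  expect_gt(which.max(set$matrix[1, ]), set$alignment)
  expect_lte(abs(which.max(diff(set$matrix[1, ]) > 0.5) - set$alignment), 2)
})

test_that("pre/post summaries and class contrasts behave", {
  flat <- structure(list(matrix = matrix(0, 3, 8), window_s = c(0.1, 0.1),
                         event_class = "x", alignment = 5L,
                         onsets_s = 1:3, n_excluded = 0L),
                    class = "peri_event_set")
  st <- pre_post_stats(flat)
  expect_equal(st$per_trial$pre_mean, rep(0, 3))
  expect_equal(st$per_trial$post_mean, rep(0, 3))
  expect_true(is.na(st$p))
  # transients at every event: post > pre on every trial
  s <- two_class_session(77, n_per_class = 10, noise_sd = 0)
  tr <- preprocess(s)
  sets <- peri_event(tr, classify_bouts(s$events), window_s = c(4, 4))
  stp <- pre_post_stats(sets$investigation_preceding_attack)
  expect_true(all(stp$per_trial$diff > 0))
  expect_lt(stp$p, 0.01)
  # empty class yields an explicit empty set downstream
  empty <- sets$investigation_preceding_attack
  empty$matrix <- empty$matrix[0, , drop = FALSE]
  expect_equal(pre_post_stats(empty)$n_trials, 0)
})
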