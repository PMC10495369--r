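test_that("runoff extraction follows the 10 percent rule on the worked trace", {
  sig <- c(50, 48, 45, 40, 30, 20, 10, 4, 3, 2)
  r <- extract_runoff_time(sig, dt = 10, t_drug = 0)
  expect_equal(r$runoff_time_s, 70)        # first persistent sub-5 frame is 7
  expect_equal(r$exclusion, "none")
  expect_false(r$censored)
})

test_that("exclusion and censoring rules behave as documented", {
  # low initial signal: mean of first four frames below 10% of max
  low <- c(2, 3, 1, 2, 50, 40, 20, 3, 2, 1)
  expect_equal(extract_runoff_time(low, 10, 0)$exclusion, "low_initial")
  # never below threshold within 30 min: censored at 1800 s
  flat <- rep(50, 181)
  r <- extract_runoff_time(flat, 10, 0)
  expect_true(r$censored)
  expect_equal(r$censor_time_s, 1800)
  # RNA track vanishing with the protein signal: co-disappearance
  sig <- c(50, 48, 45, 40, 30, 20, 10, 4, 3, 2)
  r2 <- extract_runoff_time(sig, 10, 0, rna_end_frame = 8L,
                            movie_end_frame = 30L)
  expect_equal(r2$exclusion, "co_disappear")
  # all-zero trace is not translating; short traces are dropped
  expect_equal(extract_runoff_time(rep(0, 10), 10, 0)$exclusion,
               "not_translating")
  expect_equal(extract_runoff_time(c(9, 9, 9, 9, 9), 10, 0)$exclusion,
               "short_track")
  expect_error(extract_runoff_time(sig, 10, t_drug = 500), "input error")
  # a noise dip shorter than the persistence guard does not end the trace
  dip <- c(50, 48, 45, 2, 40, 38, 30, 2, 1, 1)
  expect_equal(extract_runoff_time(dip, 10, 0)$runoff_time_s, 70)
})

test_that("KM equals the empirical survival function without censoring", {
  rec <- record_df(c(2, 4, 6) * 60)
  sc <- km_survival(rec)
  expect_equal(sc$curve$survival, c(1, 2 / 3, 1 / 3, 0))
  expect_equal(sc$median_s, 240)   # first time S <= 0.5
  # property: random event times, KM = empirical at every event time
  set.seed(1)
  for (i in 1:5) {
    tt <- round(rexp(40, 1 / 300), 1)
    sc2 <- km_survival(record_df(tt))
    emp <- vapply(sc2$curve$time_s, function(t0) mean(tt > t0), numeric(1))
    expect_equal(sc2$curve$survival, emp)
  }
  expect_error(km_survival(within(rec, exclusion <- "low_initial")),
               "empty-set")
})

test_that("Greenwood CI matches the hand-computed example", {
  # n = 4: event at 1, censored at 2, event at 3, censored at 4
  rec <- record_df(c(1, 2, 3, 4), censored = c(FALSE, TRUE, FALSE, TRUE))
  sc <- km_survival(rec)
  i <- which(sc$curve$time_s == 1)
  expect_equal(sc$curve$survival[i], 0.75)
  se <- 0.75 * sqrt(1 / 12)                       # Greenwood at t = 1
  expect_equal(sc$curve$ci_low[i], 0.75 - qnorm(0.975) * se, tolerance = 1e-6)
  expect_equal(sc$curve$ci_high[i], 1)            # clipped at 1
})

test_that("per-cell averaged survival behaves like the pooled curve", {
  # one cell: identical to its empirical survival
  rec1 <- record_df(c(100, 200, 300))
  pc1 <- per_cell_survival(rec1)
  expect_equal(pc1$curve$survival, c(1, 2 / 3, 1 / 3, 0))
  # two cells with survival 1 and 0 at t: mean 0.5
  rec2 <- rbind(record_df(1000, cell = 1L), record_df(10, cell = 2L))
  pc2 <- per_cell_survival(rec2, times = 500)
  expect_equal(pc2$curve$survival, 0.5)
  # homogeneous simulated cells: per-cell mean tracks pooled KM
  sc <- run_runoff_cohort(build_reporter("elongation_NLuc"), 3.5,
                          seed = 301, n = 60, n_cells = 6)
  rec <- runoff_records(simulate_traces(build_reporter("elongation_NLuc"),
                                        runoff_params(), 60, seed = 301,
                                        n_cells = 6)$traces, t_drug = 0)
  pc <- per_cell_survival(rec, times = sc$curve$time_s)
  se <- (pc$curve$ci_high - pc$curve$ci_low) / (2 * qnorm(0.975))
  expect_true(all(abs(pc$curve$survival - sc$curve$survival) <=
                    2 * pmax(se, 0.02)))
  expect_true(all(diff(pc$curve$survival) <= 1e-9))
  expect_true(all(pc$curve$survival >= 0 & pc$curve$survival <= 1))
})

test_that("log-rank test matches the hand-computed example and the null", {
  a <- record_df(c(1, 2, 3)); b <- record_df(c(4, 5, 6))
  lr <- logrank_test(a, b)
  expect_equal(lr$chi_square, 5.0517, tolerance = 0.01)
  expect_equal(lr$p, 0.0246, tolerance = 0.01)
  # identical samples: chi ~ 0, p ~ 1
  lr0 <- logrank_test(a, a)
  expect_lt(lr0$chi_square, 1e-9)
  expect_equal(lr0$p, 1, tolerance = 1e-6)
  expect_error(logrank_test(a, record_df(5, censored = TRUE)),
               "zero events")
  # administrative censoring horizon converts late events to censorings
  lrh <- logrank_test(a, b, horizon = 5.5)
  expect_lte(lrh$chi_square, lr$chi_square + 1e-9)
})

test_that("elongation inversion: v0, fold decomposition and identities", {
  expect_equal(estimate_v0(100, 100), 1.0)
  v0 <- estimate_v0(294, 863 + 171)        # NLuc-backbone control
  expect_equal(v0, 3.517, tolerance = 1e-3)
  expect_error(estimate_v0(-1, 100), "parameter error")

  # uniform-speed identity: fold exactly 1
  e1 <- elongation_fold((140 + 863) / v0, v0, 140, 863)
  expect_equal(e1$speed_fold, 1.0)
  # Eq. decomposition holds to machine precision
  e2 <- elongation_fold(672, v0, 140, 863)
  expect_equal(e2$t_I + e2$t_0, e2$t_target)
  expect_equal(e2$speed_fold, 10.7, tolerance = 0.01)
  e3 <- elongation_fold(810, v0, 140, 863)
  expect_equal(e3$speed_fold, 14.2, tolerance = 0.01)
  expect_equal(e3$per_aa_time_fold, e3$speed_fold)
  expect_error(elongation_fold(200, v0, 140, 863), "degenerate")

  expect_equal(fold_runoff_time(11.2, 4.9), 2.3)
  expect_equal(fold_runoff_time(13.5, 4.9), 2.8)
  expect_equal(fold_runoff_time(4.9, 4.9), 1.0)
  expect_error(fold_runoff_time(1, 0), "parameter error")
})

test_that("FRAP summary: immediate recovery, no recovery, speed ordering", {
  # instantaneous full recovery at the first post-bleach frame
  sig <- c(10, 10, 10, 10, 10, 10, 10, 10)
  fr <- frap_recovery(sig, dt = 5, t_bleach = 16)
  expect_lte(fr$half_time_s, 5)
  expect_equal(fr$plateau, 1, tolerance = 1e-9)
  # no recovery: plateau near zero
  sig0 <- c(10, 10, 10, rep(0, 20))
  fr0 <- frap_recovery(sig0, dt = 5, t_bleach = 14)
  expect_lt(fr0$plateau, 0.05)
  expect_error(frap_recovery(c(1, 2), dt = 5, t_bleach = 100), "input error")
  # slower insert speed gives slower recovery of the simulated site
  d <- build_reporter("elongation_GGGGCC70")
  half <- vapply(c(3.5, 0.35, 0.23), function(vi) {
    p <- kinetic_params(k_init = 0.1, exclusion = FALSE, v_insert = vi,
                        dt = 5, duration = 600, t_bleach = 30, noise_sd = 10)
    sim <- simulate_traces(d, p, n_rna = 25, seed = 55)
    m <- tapply(sim$traces$ch1_signal - p$background, sim$traces$frame, mean)
    frap_recovery(as.numeric(m), dt = 5, t_bleach = 30)$half_time_s
  }, numeric(1))
  expect_true(all(diff(half) > 0))
})
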