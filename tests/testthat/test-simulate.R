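test_that("deterministic stepping gives the exact transit time L/v", {
  d <- build_reporter("elongation_GGGGCC70")
  p <- kinetic_params(v_insert = 3.5)
  tt <- ribosome_transit_times(d, p, n = 3, seed = 1, stepping = "deterministic")
  expect_equal(tt, rep(1003 / 3.5, 3))   # 286.57 s
  # stochastic transits center on the same value
  ts <- ribosome_transit_times(d, p, n = 400, seed = 2)
  expect_equal(mean(ts), 1003 / 3.5, tolerance = 0.02)
})

test_that("no initiation means identically zero protein signal", {
  d <- short_design()
  p <- kinetic_params(k_init = 0, noise_sd = 0, background = 0, duration = 300)
  sim <- simulate_traces(d, p, n_rna = 3, seed = 1)
  expect_true(all(sim$traces$ch1_signal == 0))
  expect_equal(nrow(sim$truth$ribosomes), 0L)
})

test_that("the seed is mandatory and fully determines the output", {
  d <- short_design()
  p <- kinetic_params(duration = 300)
  expect_error(simulate_traces(d, p, n_rna = 1), "seed")
  a <- simulate_traces(d, p, n_rna = 4, seed = 7, n_cells = 2)
  b <- simulate_traces(d, p, n_rna = 4, seed = 7, n_cells = 2)
  expect_identical(a$traces, b$traces)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_traces(d, p, n_rna = 4, seed = 8, n_cells = 2)
  expect_false(identical(a$traces, c2$traces))
})

test_that("noiseless signals are integer multiples of unit_intensity (conservation)", {
  d <- short_design()
  p <- kinetic_params(noise_sd = 0, background = 0, duration = 600)
  sim <- simulate_traces(d, p, n_rna = 5, seed = 3)
  units <- sim$traces$ch1_signal / p$unit_intensity
  expect_equal(units, round(units))
  expect_equal(unname(as.vector(t(sim$truth$counts1))), units)
})

test_that("after harringtonine the signal decays to zero within the transit time", {
  d <- short_design()
  p <- kinetic_params(noise_sd = 0, background = 0, duration = 600,
                      t_drug = 100, dt = 10)
  sim <- simulate_traces(d, p, n_rna = 6, seed = 4,
                         stepping = "deterministic")
  clear_frame <- ceiling((100 + d$total_length / p$v_flank) / p$dt)  # drug + L/v
  for (r in 1:6) {
    s <- sim$traces$ch1_signal[sim$traces$rna_id == r]
    expect_true(all(s[(clear_frame + 2):length(s)] == 0))
    # nonincreasing once the cassette has cleared
    tail_from <- ceiling((100 + 192 / p$v_flank) / p$dt) + 2
    expect_true(all(diff(s[tail_from:length(s)]) <= 0))
  }
  # ground-truth clearance agrees
  cl <- sim$truth$rna_states$clearance_s
  expect_true(all(is.na(cl) | cl <= d$total_length / p$v_flank + 1e-9))
})

test_that("steric exclusion caps concurrent ribosome load", {
  d <- build_reporter("explicit", name = "tiny",
                      regions = data.frame(label = c("tag", "tail"),
                                           start = c(1L, 97L),
                                           end = c(96L, 100L),
                                           role = c("epitope_cassette", "flank")),
                      epitope_positions_ch1 = 8L * (1:12),
                      ch1_stop = 100L, total_length = 100L)
  p <- kinetic_params(k_init = 5, k_off = 0, footprint = 10L, duration = 400)
  sim <- simulate_traces(d, p, n_rna = 3, seed = 5)
  rib <- sim$truth$ribosomes
  for (r in unique(rib$rna_id)) {
    rr <- rib[rib$rna_id == r, ]
    ends <- ifelse(is.na(rr$end_time_s), Inf, rr$end_time_s)
    conc <- vapply(rr$init_time_s, function(t0)
      sum(rr$init_time_s <= t0 & ends > t0), integer(1))
    expect_lte(max(conc), floor(99 / 10) + 1L)
  }
})

test_that("telegraph duty cycle converges to k_on/(k_on+k_off)", {
  d <- short_design()
  p <- kinetic_params(k_on = 0.02, k_off = 0.005, duration = 1800)
  sim <- simulate_traces(d, p, n_rna = 100, seed = 6)
  duty <- mean(sim$truth$rna_states$on_time_s) / p$duration
  expect_equal(duty, 0.8, tolerance = 0.04)
})

test_that("frameshift flags converge to the per-traversal probability", {
  d <- build_reporter("elongation_GGGGCC70")
  p <- kinetic_params(p_fs_traversal = 0.05, duration = 1800, k_off = 0,
                      k_init = 0.06)
  sim <- simulate_traces(d, p, n_rna = 120, seed = 7)
  rib <- sim$truth$ribosomes
  done <- rib[!is.na(rib$end_time_s) & !rib$ran_flag, ]   # completed traversals
  expect_gt(nrow(done), 1e4)
  phat <- mean(done$fs_flag)
  ci <- 1.96 * sqrt(0.05 * 0.95 / nrow(done))
  expect_lt(abs(phat - 0.05), ci + 0.003)
  expect_true(all(done$fs_codon[done$fs_flag] >= 529 &
                  done$fs_codon[done$fs_flag] <= 668))
})

test_that("steady-state epitope load matches the Little's-law closed form", {
  d <- build_reporter("elongation_GGGGCC70")
  p <- kinetic_params(k_off = 0, k_init = 0.02, exclusion = FALSE,
                      noise_sd = 0, background = 0, duration = 3600,
                      v_insert = 3.5)
  sim <- simulate_traces(d, p, n_rna = 300, seed = 8)
  expected <- p$k_init * sum((1003 - d$epitope_positions_ch1) / 3.5)
  got <- mean(sim$traces$ch1_signal) / p$unit_intensity
  expect_equal(got, expected, tolerance = 0.05)
})

test_that("ON/OFF ground-truth intervals are disjoint and cover the movie", {
  d <- short_design()
  p <- kinetic_params(duration = 900)
  sim <- simulate_traces(d, p, n_rna = 20, seed = 9)
  st <- sim$truth$rna_states
  expect_true(all(st$on_time_s >= 0 & st$on_time_s <= p$duration + 1e-9))
  for (iv in st$on_intervals[st$on_intervals != ""]) {
    m <- do.call(rbind, lapply(strsplit(strsplit(iv, ";")[[1]], "-"),
                               as.numeric))
    expect_true(all(m[, 2] > m[, 1]))
    if (nrow(m) > 1) expect_true(all(m[-1, 1] >= m[-nrow(m), 2]))
  }
})

test_that("mature-protein samples honor the stated median and CV", {
  p <- kinetic_params(unit_intensity = 100, mature_cv = 0)
  expect_equal(sample_mature_proteins(p, 10, seed = 1), rep(2400, 10))
  p2 <- kinetic_params(mature_median = 1000, mature_cv = 0.3)
  x <- sample_mature_proteins(p2, 1e5, seed = 2)
  expect_equal(median(x), 1000, tolerance = 0.02)
  expect_equal(sd(x) / mean(x), 0.3, tolerance = 0.05)
  expect_error(sample_mature_proteins(kinetic_params(mature_cv = -1), 10, 1),
               "parameter error")
})

test_that("smFISH snapshot: silent RNAs sit at background, loaded sites are bright", {
  d <- short_design()
  p0 <- kinetic_params(k_on = 0, k_off = 1, noise_sd = 5)
  snap <- simulate_smfish_snapshot(d, p0, n_cells = 3, rnas_per_cell = 10, seed = 1)
  expect_true(all(!snap$rna$translating_true))
  expect_equal(mean(snap$rna$tls_intensity), p0$background, tolerance = 0.5)
  # a fully loaded RNA far outshines a single mature protein
  p1 <- kinetic_params(k_init = 5, k_off = 0, noise_sd = 5)
  snap1 <- simulate_smfish_snapshot(d, p1, n_cells = 2, rnas_per_cell = 10, seed = 2)
  expect_gt(mean(snap1$rna$tls_intensity), 3 * median(snap1$mature$intensity))
})
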