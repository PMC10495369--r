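test_that("nascent_units arithmetic and guards", {
  expect_equal(nascent_units(7200, 1000), 7.2)
  expect_equal(nascent_units(0, 1000), 0)
  expect_equal(nascent_units(c(500, 1500), 1000, background = 500), c(0, 1))
  expect_error(nascent_units(100, 0), "parameter error")
})

test_that("percent_translating aggregates cells within replicates", {
  rec <- data.frame(cell_id = rep(1:2, c(10, 4)),
                    replicate = 1L,
                    nascent_units = c(rep(5, 2), rep(0, 8), rep(5, 1), rep(0, 3)))
  pt <- percent_translating(rec, min_units = 2)
  expect_equal(sort(pt$per_cell$percent), c(20, 25))  # 2/10 and 1/4
  expect_equal(pt$mean, 22.5)
  # invariance to global intensity rescaling (normalizer scales identically)
  rec2 <- rec; rec2$nascent_units <- rec$nascent_units  # units are ratios
  expect_equal(percent_translating(rec2, 2)$mean, pt$mean)
  # replicate means, not cells, are the statistical unit
  rec3 <- rbind(cbind(rec, grp = 1), cbind(rec, grp = 1))
  rec3$replicate <- rep(1:2, each = nrow(rec))
  pt3 <- percent_translating(rec3[, -5], min_units = 2)
  expect_equal(nrow(pt3$per_replicate), 2L)
  expect_equal(pt3$sd, 0)
  # permuting row order never changes the result
  set.seed(3); perm <- sample(nrow(rec))
  expect_equal(percent_translating(rec[perm, ], 2)$mean, pt$mean)
})

test_that("snapshot quantification recovers true loads and translating fractions", {
  d <- short_design()
  p <- kinetic_params(k_on = 0.003, k_off = 0.017, k_init = 0.1,
                      noise_sd = 10)                      # ON fraction 0.15
  snap <- simulate_smfish_snapshot(d, p, n_cells = 25, rnas_per_cell = 10,
                                   seed = 21)
  med <- median(snap$mature$intensity)
  units <- nascent_units(snap$rna$tls_intensity, med,
                         background = p$background)
  # mean nascent units track the true attached-epitope count / 24
  expect_equal(mean(units), mean(snap$rna$true_units) / 24, tolerance = 0.1)
  # recovered percent translating within binomial CI of the ground truth
  truth_frac <- mean(snap$rna$true_units >= 24)
  rec <- data.frame(cell_id = snap$rna$cell_id, nascent_units = units)
  pt <- percent_translating(rec, min_units = 1)
  n <- nrow(snap$rna)
  ci <- 1.96 * sqrt(truth_frac * (1 - truth_frac) / n)
  expect_lt(abs(mean(rec$nascent_units >= 1) - truth_frac), ci + 0.02)
  expect_lt(abs(pt$mean / 100 - truth_frac), ci + 0.05)
})

test_that("ON-fraction sweep is ordered and in the expected regimes", {
  d <- short_design()
  duties <- c(0.02, 0.15, 0.8)
  got <- vapply(seq_along(duties), function(i) {
    du <- duties[i]
    p <- kinetic_params(k_on = 0.02 * du, k_off = 0.02 * (1 - du),
                        k_init = 0.1, noise_sd = 10)
    snap <- simulate_smfish_snapshot(d, p, n_cells = 15, rnas_per_cell = 10,
                                     seed = 30 + i)
    mean(snap$rna$true_units >= 24)
  }, numeric(1))
  expect_true(all(diff(got) > 0))
  expect_lt(got[1], 0.10)
  expect_gt(got[3], 0.5)
})

test_that("fraction of time translating: trivial traces and guards", {
  on <- c(rep(100, 135), rep(0, 45))
  expect_equal(fraction_time_translating(on, on_threshold = 50), 0.75)
  expect_equal(fraction_time_translating(rep(100, 50), on_threshold = 50), 1)
  expect_equal(fraction_time_translating(rep(0, 50), on_threshold = 50), 0)
  expect_error(fraction_time_translating(rep(100, 5), on_threshold = 50),
               "excluded")
})

test_that("pooled-variance t test matches the hand example and conventions", {
  g <- compare_groups(c(1, 2, 3), c(2, 3, 4))
  expect_equal(g$t, -1.2247, tolerance = 1e-4)
  expect_equal(g$df, 4)
  expect_equal(g$p, 0.2879, tolerance = 1e-3)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
  same <- suppressMessages(compare_groups(c(2, 2), c(2, 2)))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  ident <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
})
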