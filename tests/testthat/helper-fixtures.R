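# Shared fixtures and independent oracles for the test suite.

# short one-color design: 24 epitopes completing every 8 codons, no insert
short_design <- function(total = 200L) {
  build_reporter("explicit", name = "short",
                 regions = data.frame(
                   label = c("tag", "tail"),
                   start = c(1L, 193L), end = c(192L, total),
                   role = c("epitope_cassette", "flank")),
                 epitope_positions_ch1 = 8L * (1:24),
                 ch1_stop = total, total_length = total)
}

# build a runoff-record table directly (for survival-machinery tests)
record_df <- function(time, censored = FALSE, cell = 1L) {
  censored <- rep_len(censored, length(time))
  data.frame(cell_id = rep_len(cell, length(time)),
             rna_id = seq_along(time),
             runoff_time_s = ifelse(censored, NA_real_, time),
             censored = censored,
             censor_time_s = ifelse(censored, time, NA_real_),
             exclusion = "none", stringsAsFactors = FALSE)
}

# independent log-rank statistic (hand-rolled product of O-E sums; oracle
# for logrank_test, which goes through survival::survdiff)
logrank_chi_oracle <- function(time, event, group) {
  g <- unique(group)
  stopifnot(length(g) == 2L)
  ev_times <- sort(unique(time[event == 1L]))
  o_minus_e <- 0; v <- 0
  for (t0 in ev_times) {
    at_risk <- time >= t0
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g[1])
    d <- sum(time == t0 & event == 1L)
    d1 <- sum(time == t0 & event == 1L & group == g[1])
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

# standard cohort conditions for runoff experiments: constitutive high-load
# initiation, independent ribosomes (see the methods vignette)
runoff_params <- function(v_insert = 3.5, dt = 10, duration = 1800) {
  kinetic_params(k_init = 0.1, exclusion = FALSE, v_insert = v_insert,
                 t_drug = 0, dt = dt, duration = duration)
}

run_runoff_cohort <- function(design, v_insert, seed, n = 100L, n_cells = 5L) {
  sim <- simulate_traces(design, runoff_params(v_insert), n_rna = n,
                         seed = seed, n_cells = n_cells)
  km_survival(runoff_records(sim$traces, t_drug = 0))
}
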