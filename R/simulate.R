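#' Simulate single-mRNA translation-site traces
#'
#' Event-driven (Gillespie) simulation of translation on `n_rna` independent
#' mRNAs.  Initiation is a Poisson process gated by the telegraph ON/OFF state;
#' each ribosome advances codon by codon with exponential dwell time
#' `1/v(region)` (or exactly `1/v` in deterministic-stepping mode), blocked
#' whenever the next position would come within `footprint` codons of the
#' ribosome ahead.  Inside the insert a ribosome shifts frame with per-codon
#' hazard `1 - (1 - p_fs_traversal)^(1/L_I)`.  The recorded channel signal at
#' each frame is `unit_intensity` times the number of epitopes completed and
#' still attached, plus background and Gaussian noise.  At `t_drug` initiation
#' stops (harringtonine); at `t_bleach` all accumulated fluorescence is zeroed
#' while subsequently completed epitopes fluoresce.  Terminated nascent chains
#' leave the site.
#'
#' The process is started `burnin` seconds before frame 0 so that frame 0
#' samples the stationary regime; by default the burn-in is twice the full
#' ORF traversal time plus three telegraph correlation times.
#'
#' Reproducibility: `seed` is mandatory; every RNA runs on its own substream
#' derived deterministically from `(seed, cell_id, rna_id)`, so identical
#' `(design, params, n_rna, seed)` give byte-identical output regardless of
#' evaluation order.
#'
#' @param design A [build_reporter()] design.
#' @param params A [kinetic_params()] object.
#' @param n_rna Number of mRNAs to simulate.
#' @param seed Integer master seed (required).
#' @param n_cells Number of cells the RNAs are distributed over (round-robin).
#' @param stepping `"gillespie"` (exponential dwells) or `"deterministic"`
#'   (fixed dwells, for analytic checks).
#' @param positions If `TRUE`, attach tethered-diffusion x/y positions (px).
#' @param field_px Field of view side, px (positions mode).
#' @param step_sd_px Per-frame diffusion step sd, px (positions mode).
#' @param burnin Burn-in time, s (`NULL` for the automatic choice).
#'
#' @return A list of class `ribotrace_sim` with elements
#'   \describe{
#'     \item{`traces`}{data frame: `cell_id`, `rna_id`, `frame` (0-based),
#'       `time_s`, `rna_signal`, `ch1_signal`, and for two-color designs
#'       `ch2_signal`; plus `x_px`/`y_px` in positions mode.}
#'     \item{`truth`}{list with `ribosomes` (one row per ribosome:
#'       `cell_id`, `rna_id`, `init_time_s`, `fs_flag`, `fs_codon`, `ran_flag`,
#'       `end_time_s`), `rna_states` (per RNA: true `class`, `on_intervals`,
#'       `on_time_s`, `clearance_s`), and noiseless per-frame epitope counts
#'       `counts1`/`counts2` (matrices, RNAs x frames).}
#'   }
#' @examples
#' d <- build_reporter("elongation_NLuc")
#' p <- kinetic_params(duration = 600, noise_sd = 0)
#' sim <- simulate_traces(d, p, n_rna = 2, seed = 1)
#' head(sim$traces)
#' @export
simulate_traces <- function(design, params, n_rna, seed,
                            n_cells = 1L,
                            stepping = c("gillespie", "deterministic"),
                            positions = FALSE,
                            field_px = 128L, step_sd_px = 0.3,
                            burnin = NULL) {
  stopifnot(inherits(design, "reporter_design"), inherits(params, "kinetic_params"))
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("seed missing: simulate_traces requires an explicit seed")
  if (n_rna < 1L) stop("n_rna must be >= 1")
  stepping <- match.arg(stepping)
  validate_params(params)

  L <- design$total_length
  rate <- step_rates(design, params)
  if (any(rate <= 0)) stop("parameter error: zero elongation rate in an occupied region")
  haz <- fs_hazards(design, params)
  is_ep1 <- seq_len(L) %in% design$epitope_positions_ch1
  is_ep2 <- seq_len(L) %in% design$epitope_positions_ch2
  two_color <- length(design$epitope_positions_ch2) > 0L
  ins <- insert_region(design)
  ran_start <- if (is.null(ins)) L else ins$start

  if (is.null(burnin)) {
    burnin <- 2 * sum(1 / rate) +
      if (params$k_on + params$k_off > 0) 3 / (params$k_on + params$k_off) else 0
  }
  dt <- params$dt
  nf <- floor(params$duration / dt) + 1L
  tf <- (seq_len(nf) - 1L) * dt
  t_drug <- if (is.na(params$t_drug)) Inf else params$t_drug
  fp <- if (params$exclusion) params$footprint else 0L

  cell_of <- rep_len(seq_len(n_cells), n_rna)
  trace_list <- vector("list", n_rna)
  rib_list <- vector("list", n_rna)
  state_list <- vector("list", n_rna)
  counts1 <- matrix(0L, n_rna, nf)
  counts2 <- matrix(0L, n_rna, nf)

  for (r in seq_len(n_rna)) {
    cid <- cell_of[r]
    set.seed(substream_seed(seed, cid, r))
    sim <- sim_rna_cpp(L, rate, haz, is_ep1, is_ep2,
                       design$ch1_stop, ran_start,
                       params$k_on, params$k_off, params$k_init, params$p_ran,
                       fp, -burnin, params$duration, t_drug,
                       stepping == "deterministic")
    cc <- frame_counts(sim, nf, dt, params$t_bleach)
    counts1[r, ] <- cc$c1
    counts2[r, ] <- cc$c2

    noise <- function() if (params$noise_sd > 0) rnorm(nf, 0, params$noise_sd) else 0
    tr <- data.frame(
      cell_id = cid, rna_id = r, frame = seq_len(nf) - 1L, time_s = tf,
      rna_signal = params$rna_intensity + params$background + noise(),
      ch1_signal = params$unit_intensity * cc$c1 + params$background + noise())
    if (two_color)
      tr$ch2_signal <- params$unit_intensity * cc$c2 + params$background + noise()
    if (positions) {
      x0 <- runif(1, 8, field_px - 8)
      y0 <- runif(1, 8, field_px - 8)
      tr$x_px <- reflect_walk(x0, nf, step_sd_px, field_px)
      tr$y_px <- reflect_walk(y0, nf, step_sd_px, field_px)
    }
    trace_list[[r]] <- tr

    n_rib <- length(sim$init_time)
    rib_list[[r]] <- data.frame(
      cell_id = rep(cid, n_rib), rna_id = rep(r, n_rib),
      init_time_s = sim$init_time,
      fs_flag = as.logical(sim$fs), fs_codon = sim$fs_codon,
      ran_flag = as.logical(sim$ran), end_time_s = sim$end_time)
    state_list[[r]] <- rna_state_row(sim, cc, cid, r, params, burnin, t_drug)
  }

  traces <- do.call(rbind, trace_list)
  truth <- list(ribosomes = do.call(rbind, rib_list),
                rna_states = do.call(rbind, state_list),
                counts1 = counts1,
                counts2 = counts2)
  out <- list(traces = traces, truth = truth)
  attr(out, "meta") <- list(design = design$name, dt = dt,
                            duration = params$duration, seed = seed,
                            stepping = stepping, burnin = burnin,
                            params = unclass(params))
  class(out) <- "ribotrace_sim"
  out
}

substream_seed <- function(seed, cell_id, rna_id) {
  as.integer((as.numeric(seed) + 1000003 * cell_id + 7919 * rna_id) %% 2147483629)
}

reflect_walk <- function(x0, n, sd, field) {
  x <- cumsum(c(x0, rnorm(n - 1L, 0, sd)))
  lo <- 2; hi <- field - 2
  # reflect into [lo, hi]
  w <- 2 * (hi - lo)
  y <- (x - lo) %% w
  lo + pmin(y, w - y)
}

# per-frame attached-epitope counts from a single-RNA simulation record
frame_counts <- function(sim, nf, dt, t_bleach) {
  ct <- sim$comp_time
  if (!length(ct)) {
    z <- integer(nf)
    return(list(c1 = z, c2 = z, vis = logical(0)))
  }
  endt <- sim$end_time[sim$comp_rib + 1L]
  endt[is.na(endt)] <- Inf
  i0 <- pmax(0, ceiling(ct / dt))
  i1 <- pmin(nf - 1, ceiling(endt / dt) - 1)
  if (!is.na(t_bleach)) {
    ib <- ceiling(t_bleach / dt) - 1
    pre <- ct <= t_bleach
    i1[pre] <- pmin(i1[pre], ib)
  }
  vis <- i0 <= i1
  count_ch <- function(sel) {
    if (!any(sel)) return(integer(nf))
    add <- tabulate(i0[sel] + 1L, nbins = nf + 1L)
    sub <- tabulate(i1[sel] + 2L, nbins = nf + 1L)
    cumsum(add - sub)[seq_len(nf)]
  }
  list(c1 = count_ch(vis & sim$comp_ch == 1L),
       c2 = count_ch(vis & sim$comp_ch == 2L),
       vis = vis)
}

rna_state_row <- function(sim, cc, cid, r, params, burnin, t_drug) {
  # ON intervals clipped to [0, duration]
  dur <- params$duration
  times <- c(-burnin, sim$toggle_times, dur)
  states <- rep(c(sim$init_state_on, !sim$init_state_on), length.out = length(times) - 1L)
  s0 <- pmax(times[-length(times)], 0)
  s1 <- pmin(times[-1L], dur)
  keep <- states & s1 > s0
  ivs <- if (any(keep)) paste(sprintf("%.3f-%.3f", s0[keep], s1[keep]), collapse = ";") else ""
  on_time <- sum(pmax(s1[keep] - s0[keep], 0))

  vis <- cc$vis
  ch <- sim$comp_ch
  rib <- sim$comp_rib + 1L
  ch1_any <- any(vis & ch == 1L)
  ch2_any <- any(vis & ch == 2L)
  fs_vis <- any(vis & ch == 2L & sim$fs[rib] == 1L)
  cls <- if (ch1_any && ch2_any) "frameshift"
         else if (ch2_any) "ran_only"
         else if (ch1_any) "normal" else "silent"
  if (cls == "frameshift" && !fs_vis && !any(vis & ch == 2L & sim$ran[rib] == 1L))
    cls <- "normal"  # unreachable guard

  clearance <- NA_real_
  if (is.finite(t_drug)) {
    ends <- sim$end_time
    if (length(sim$alive_idx)) clearance <- NA_real_
    else if (!length(ends) || !any(ends > t_drug)) clearance <- 0
    else clearance <- max(ends[ends > t_drug]) - t_drug
  }
  data.frame(cell_id = cid, rna_id = r, class = cls,
             on_intervals = ivs, on_time_s = on_time,
             clearance_s = clearance, stringsAsFactors = FALSE)
}

#' Single-ribosome transit times
#'
#' Simulates `n` independent, unobstructed ribosome transits through the full
#' ORF and returns their termination times; the deterministic mode returns the
#' exact sum of per-codon dwells `1/v`.  Useful as a closed-form anchor for
#' the runoff analysis.
#'
#' @inheritParams simulate_traces
#' @param n Number of transits.
#' @return Numeric vector of transit times, s.
#' @examples
#' d <- build_reporter("elongation_GGGGCC70")
#' p <- kinetic_params()
#' ribosome_transit_times(d, p, n = 1, seed = 1, stepping = "deterministic")
#' @export
ribosome_transit_times <- function(design, params, n, seed,
                                   stepping = c("gillespie", "deterministic")) {
  stopifnot(inherits(design, "reporter_design"), inherits(params, "kinetic_params"))
  if (missing(seed)) stop("seed missing")
  stepping <- match.arg(stepping)
  rate <- step_rates(design, params)[seq_len(design$ch1_stop)]
  if (stepping == "deterministic") return(rep(sum(1 / rate), n))
  set.seed(seed)
  vapply(seq_len(n), function(i) sum(rexp(length(rate), rate)), numeric(1))
}

#' Sample mature single-protein intensities
#'
#' Draws `n` mature-protein spot intensities from a right-skewed Gamma
#' distribution with the median and coefficient of variation given by
#' `params$mature_median` / `params$mature_cv`; a noiseless mature protein
#' carries all 24 epitopes, so when `mature_median` is `NA` the median
#' defaults to `24 * unit_intensity`.  The median of these values is the
#' normalizer used by [nascent_units()].
#'
#' @inheritParams simulate_traces
#' @param n Number of draws.
#' @return Numeric vector of intensities (a.u.).
#' @export
sample_mature_proteins <- function(params, n, seed) {
  stopifnot(inherits(params, "kinetic_params"))
  if (missing(seed)) stop("seed missing")
  if (n < 1L) stop("n must be >= 1")
  if (params$mature_cv < 0) stop("parameter error: mature_cv must be >= 0")
  med <- if (is.na(params$mature_median)) 24 * params$unit_intensity else params$mature_median
  if (params$mature_cv == 0) return(rep(med, n))
  set.seed(seed)
  shape <- 1 / params$mature_cv^2
  scale <- med / qgamma(0.5, shape = shape, scale = 1)
  rgamma(n, shape = shape, scale = scale)
}

#' Simulate an smFISH-IF style snapshot
#'
#' Draws each RNA's instantaneous ribosome load from the stationary regime of
#' [simulate_traces()] and reports one integrated translation-site intensity
#' per RNA, together with a mature single-protein intensity population per
#' cell (for normalization) and the ground-truth translating flag.
#'
#' @inheritParams simulate_traces
#' @param n_cells Number of cells.
#' @param rnas_per_cell RNAs per cell.
#' @return List with `rna` (per-RNA records: `cell_id`, `rna_id`,
#'   `rna_intensity`, `tls_intensity`, `true_units`, `translating_true`) and
#'   `mature` (per-cell mature-protein intensities).
#' @export
simulate_smfish_snapshot <- function(design, params, n_cells, rnas_per_cell, seed) {
  if (missing(seed)) stop("seed missing")
  if (n_cells < 1L || rnas_per_cell < 1L) stop("counts must be >= 1")
  p1 <- update_params(params, duration = params$dt)
  sim <- simulate_traces(design, p1, n_rna = n_cells * rnas_per_cell,
                         seed = seed, n_cells = n_cells)
  fr0 <- sim$traces[sim$traces$frame == 0L, ]
  true_units <- sim$truth$counts1[, 1L]
  rna <- data.frame(cell_id = fr0$cell_id, rna_id = fr0$rna_id,
                    rna_intensity = fr0$rna_signal,
                    tls_intensity = fr0$ch1_signal,
                    true_units = true_units,
                    translating_true = true_units > 0L)
  mats <- lapply(seq_len(n_cells), function(cid) {
    data.frame(cell_id = cid,
               intensity = sample_mature_proteins(
                 params, n = 200L, seed = substream_seed(seed, cid, 0L)))
  })
  list(rna = rna, mature = do.call(rbind, mats))
}
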