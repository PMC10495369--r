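# Ribosome-runoff survival analysis and elongation-speed inversion.

#' Extract the runoff time from one translation-site trace
#'
#' Applies the runoff rules to the protein-channel signal of a single linked
#' trace.  Let `M` be the maximum of the (raw, unsmoothed) signal over the
#' whole trace and `thr = threshold_frac * M`:
#' \itemize{
#'   \item if the mean of the first `init_frames` frames is below `thr` the
#'     RNA was not visibly translating at drug addition — exclusion
#'     `low_initial`;
#'   \item otherwise the runoff time is the time of the first frame at or
#'     after `t_drug` at which the signal falls below `thr` and stays below
#'     for at least `persistence` consecutive frames, minus `t_drug`;
#'   \item if the RNA track ends before the movie does and its end lies
#'     within 2 frames of that final fall, RNA and translation site
#'     disappeared together — exclusion `co_disappear`;
#'   \item if no persistent sub-threshold run occurs the trace is
#'     right-censored at its end.
#' }
#'
#' @param signal Numeric protein-channel signal, one value per frame (frame 0
#'   at time 0).
#' @param dt Frame interval, s.
#' @param t_drug Drug-addition time, s (on the trace's time base).
#' @param threshold_frac Threshold as a fraction of the trace maximum.
#' @param init_frames Number of leading frames for the low-initial-signal rule.
#' @param persistence Consecutive sub-threshold frames required to call
#'   runoff.
#' @param smooth If `TRUE`, apply a centered moving average (window 3) before
#'   thresholding (off by default).
#' @param rna_end_frame Last frame (0-based) at which the RNA track exists,
#'   if known.
#' @param movie_end_frame Last frame of the movie, if the trace may end early.
#' @return One-row data frame: `runoff_time_s`, `censored`, `censor_time_s`,
#'   `exclusion` (`"none"`, `"low_initial"`, `"co_disappear"`,
#'   `"short_track"`, `"not_translating"`).
#' @examples
#' sig <- c(50, 48, 45, 40, 30, 20, 10, 4, 3, 2)
#' extract_runoff_time(sig, dt = 10, t_drug = 0)  # runoff at 70 s
#' @export
extract_runoff_time <- function(signal, dt, t_drug = 0,
                                threshold_frac = 0.10, init_frames = 4L,
                                persistence = 3L, smooth = FALSE,
                                rna_end_frame = NULL, movie_end_frame = NULL) {
  n <- length(signal)
  rec <- function(runoff = NA_real_, censored = FALSE, censor = NA_real_,
                  exclusion = "none") {
    data.frame(runoff_time_s = runoff, censored = censored,
               censor_time_s = censor, exclusion = exclusion,
               stringsAsFactors = FALSE)
  }
  if (n <= 5L) return(rec(exclusion = "short_track"))
  tmax <- (n - 1L) * dt
  if (t_drug > tmax) stop("input error: t_drug after trace end")
  s <- signal
  if (smooth && n >= 3L) {
    s <- stats::filter(signal, rep(1 / 3, 3), sides = 2)
    s[1] <- signal[1]; s[n] <- signal[n]
    s <- as.numeric(s)
  }
  M <- max(signal)          # raw-trace maximum by convention
  if (!is.finite(M) || M <= 0) return(rec(exclusion = "not_translating"))
  thr <- threshold_frac * M
  if (mean(s[seq_len(min(init_frames, n))]) < thr)
    return(rec(exclusion = "low_initial"))

  below <- s < thr
  drug_frame <- ceiling(t_drug / dt)      # first frame with time >= t_drug
  run_frame <- NA_integer_
  f <- drug_frame
  while (f <= n - persistence) {          # 0-based frame f -> index f+1
    if (all(below[(f + 1L):(f + persistence)])) { run_frame <- f; break }
    f <- f + 1L
  }
  if (is.na(run_frame))
    return(rec(censored = TRUE, censor = tmax - t_drug))
  if (!is.null(rna_end_frame) && !is.null(movie_end_frame) &&
      rna_end_frame < movie_end_frame &&
      abs(rna_end_frame - run_frame) <= 2L)
    return(rec(exclusion = "co_disappear"))
  rec(runoff = run_frame * dt - t_drug)
}

#' Extract runoff records for a whole trace table
#'
#' @param traces Trace data frame (`cell_id`, `rna_id`, `frame`, `time_s` and
#'   a protein signal column).
#' @param channel Signal column to use.
#' @inheritParams extract_runoff_time
#' @param ... Passed on to [extract_runoff_time()].
#' @return Data frame of runoff records with `cell_id` and `rna_id`.
#' @export
runoff_records <- function(traces, t_drug = 0, channel = "ch1_signal", ...) {
  stopifnot(channel %in% names(traces))
  keys <- unique(traces[c("cell_id", "rna_id")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    tr <- traces[traces$cell_id == keys$cell_id[i] &
                 traces$rna_id == keys$rna_id[i], , drop = FALSE]
    tr <- tr[order(tr$frame), ]
    r <- extract_runoff_time(tr[[channel]], dt = diff(tr$time_s[1:2]),
                             t_drug = t_drug, ...)
    cbind(keys[i, , drop = FALSE], r)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pooled Kaplan-Meier survival of translation sites
#'
#' Product-limit estimator over runoff times with right censoring; pointwise
#' 95 percent confidence bounds from Greenwood's variance formula
#' (`S +/- z * SE`, clipped to `[0, 1]`).  The median is the first time at
#' which survival drops to 0.5 or below (undefined, `NA`, if it never does).
#'
#' @param records Runoff records (see [runoff_records()]); excluded records
#'   are dropped.
#' @param alpha Two-sided confidence level is `1 - alpha`.
#' @return Object of class `survival_curve`: data frame `curve` (`time_s`,
#'   `survival`, `ci_low`, `ci_high`, `n_at_risk`), plus `median_s`, `mode`,
#'   `n_used`, `n_excluded`.
#' @export
km_survival <- function(records, alpha = 0.05) {
  use <- records[records$exclusion == "none", , drop = FALSE]
  if (!nrow(use)) stop("empty-set error: all records excluded")
  time <- ifelse(use$censored, use$censor_time_s, use$runoff_time_s)
  event <- as.integer(!use$censored)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "plain", conf.int = 1 - alpha)
  curve <- data.frame(time_s = c(0, fit$time),
                      survival = c(1, fit$surv),
                      ci_low = pmax(0, c(1, ifelse(is.na(fit$lower), fit$surv, fit$lower))),
                      ci_high = pmin(1, c(1, ifelse(is.na(fit$upper), fit$surv, fit$upper))),
                      n_at_risk = c(fit$n, fit$n.risk))
  structure(list(curve = curve,
                 median_s = curve_median(curve$time_s, curve$survival),
                 mode = "pooled_km",
                 n_used = nrow(use),
                 n_excluded = sum(records$exclusion != "none")),
            class = "survival_curve")
}

curve_median <- function(times, surv) {
  i <- which(surv <= 0.5)
  if (!length(i)) NA_real_ else times[min(i)]
}

#' Median of a survival curve
#'
#' By convention the Kaplan-Meier median is the first time at which survival
#' drops to 0.5 or below.  With event times quantized to the frame grid this
#' step convention carries up to one frame interval of bias, so for reading a
#' 50 percent crossing off a curve (as one does off a per-cell averaged
#' curve) `interpolate = TRUE` returns the linear interpolation between the
#' bracketing grid points instead.
#'
#' @param sc A `survival_curve`.
#' @param interpolate Linearly interpolate the 50 percent crossing.
#' @return Median time, s (`NA` if survival never reaches 0.5).
#' @export
survival_median <- function(sc, interpolate = FALSE) {
  stopifnot(inherits(sc, "survival_curve"))
  if (!interpolate) return(sc$median_s)
  tt <- sc$curve$time_s; ss <- sc$curve$survival
  i <- which(ss <= 0.5)
  if (!length(i)) return(NA_real_)
  i <- min(i)
  if (i == 1L || ss[i] == 0.5) return(tt[i])
  j <- i - 1L
  tt[j] + (ss[j] - 0.5) / (ss[j] - ss[i]) * (tt[i] - tt[j])
}

#' Per-cell averaged survival
#'
#' For each cell, the fraction of its eligible translating RNAs still above
#' the runoff threshold at each time; the reported curve is the unweighted
#' mean across cells with a normal-approximation CI from the across-cell
#' standard error.  Censored traces count as surviving through their
#' censoring time.
#'
#' @inheritParams km_survival
#' @param times Time grid, s (default: all distinct event times).
#' @return A `survival_curve` with mode `"per_cell_mean"` and an extra
#'   `n_cells` field.
#' @export
per_cell_survival <- function(records, times = NULL, alpha = 0.05) {
  use <- records[records$exclusion == "none", , drop = FALSE]
  if (!nrow(use)) stop("empty-set error: all records excluded")
  if (is.null(times)) {
    ev <- use$runoff_time_s[!use$censored]
    times <- sort(unique(c(0, ev)))
  }
  cells <- split(use, use$cell_id)
  skipped <- vapply(cells, function(cc) nrow(cc) == 0L, logical(1))
  if (any(skipped)) warning(sum(skipped), " cell(s) with zero eligible records skipped")
  cells <- cells[!skipped]
  surv_cell <- vapply(cells, function(cc) {
    vapply(times, function(t0) {
      mean(ifelse(cc$censored, TRUE, cc$runoff_time_s > t0))
    }, numeric(1))
  }, numeric(length(times)))
  surv_cell <- matrix(surv_cell, nrow = length(times))
  m <- rowMeans(surv_cell)
  se <- apply(surv_cell, 1, sd) / sqrt(ncol(surv_cell))
  z <- qnorm(1 - alpha / 2)
  curve <- data.frame(time_s = times, survival = m,
                      ci_low = pmax(0, m - z * se),
                      ci_high = pmin(1, m + z * se),
                      n_at_risk = NA_integer_)
  structure(list(curve = curve, median_s = curve_median(times, m),
                 mode = "per_cell_mean", n_used = nrow(use),
                 n_excluded = sum(records$exclusion != "none"),
                 n_cells = ncol(surv_cell)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("<survival_curve> mode ", x$mode, ", n = ", x$n_used,
      " (", x$n_excluded, " excluded), median = ",
      ifelse(is.na(x$median_s), "undefined", paste0(x$median_s, " s")), "\n",
      sep = "")
  invisible(x)
}

#' @export
plot.survival_curve <- function(x, col = "steelblue", add = FALSE, ...) {
  cv <- x$curve
  stepx <- rep(cv$time_s, each = 2)[-1]
  stepy <- rep(cv$survival, each = 2)[-2 * nrow(cv)]
  if (!add) {
    plot(stepx, stepy, type = "n", xlab = "time after drug (s)",
         ylab = "fraction still translating", ylim = c(0, 1), ...)
    lo <- rep(cv$ci_low, each = 2)[-2 * nrow(cv)]
    hi <- rep(cv$ci_high, each = 2)[-2 * nrow(cv)]
    polygon(c(stepx, rev(stepx)), c(lo, rev(hi)),
            col = grDevices::adjustcolor(col, 0.2), border = NA)
  }
  lines(stepx, stepy, col = col, lwd = 2)
  invisible(x)
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' @param records_a,records_b Runoff record tables for the two groups.
#' @param horizon Optional administrative censoring horizon, s: events after
#'   the horizon are treated as censored at the horizon before testing.
#' @return List with `chi_square`, `df` (1) and `p`.
#' @export
logrank_test <- function(records_a, records_b, horizon = NULL) {
  prep <- function(rr, g) {
    rr <- rr[rr$exclusion == "none", , drop = FALSE]
    if (!nrow(rr)) stop("statistic undefined: empty group")
    time <- ifelse(rr$censored, rr$censor_time_s, rr$runoff_time_s)
    event <- as.integer(!rr$censored)
    if (!is.null(horizon)) {
      event[time > horizon] <- 0L
      time <- pmin(time, horizon)
    }
    data.frame(time = time, event = event, group = g)
  }
  d <- rbind(prep(records_a, "A"), prep(records_b, "B"))
  if (sum(d$event[d$group == "A"]) == 0L || sum(d$event[d$group == "B"]) == 0L)
    stop("statistic undefined: a group has zero events")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  list(chi_square = unname(sd_$chisq), df = 1L,
       p = pchisq(unname(sd_$chisq), df = 1L, lower.tail = FALSE))
}

#' Elongation speed from a uniform-speed (control) runoff median
#'
#' With a single elongation speed across the ORF, the median runoff time `t`
#' satisfies `t = L / v0`, so `v0 = L / t`.
#'
#' @param t_control_median Median runoff time of the control reporter, s.
#' @param L_total_control Control ORF length, codons.
#' @return `v0` in codons/s.
#' @examples
#' estimate_v0(294, 1034)  # about 3.52 codons/s
#' @export
estimate_v0 <- function(t_control_median, L_total_control) {
  if (!is.finite(t_control_median) || t_control_median <= 0 ||
      !is.finite(L_total_control) || L_total_control <= 0)
    stop("parameter error: inputs must be > 0")
  L_total_control / t_control_median
}

#' Invert a runoff median to the insert elongation-speed fold
#'
#' Decomposes the target reporter's median runoff time into flank and insert
#' parts, `t = t_I + t_0` with `t_0 = L_0 / v0`, and reports the speed ratio
#' `v0 / v_I = t_I / (L_I / v0)` — equivalently the fold-change in ribosome
#' residence time per amino acid inside the insert relative to a regular
#' sequence.
#'
#' @param t_target_median Median runoff time of the target reporter, s.
#' @param v0 Regular elongation speed, codons/s (see [estimate_v0()]).
#' @param L_I Insert length, codons.
#' @param L_0 Non-insert (flank) length, codons.
#' @return Object of class `elongation_estimate`: `v0`, `t_target`, `t_0`,
#'   `t_I`, `L_I`, `L_0`, `v_insert`, `speed_fold`, `per_aa_time_fold`.
#' @examples
#' elongation_fold(672, v0 = 3.52, L_I = 140, L_0 = 863)  # about 10.7
#' @export
elongation_fold <- function(t_target_median, v0, L_I, L_0) {
  if (L_I <= 0 || L_0 <= 0) stop("parameter error: lengths must be > 0")
  if (v0 <= 0) stop("parameter error: v0 must be > 0")
  t0 <- L_0 / v0
  tI <- t_target_median - t0
  if (tI <= 0)
    stop("degenerate error: t_target <= L_0/v0 leaves no time in the insert")
  fold <- tI / (L_I / v0)
  structure(list(v0 = v0, t_target = tI + t0, t_0 = t0, t_I = tI,
                 L_I = L_I, L_0 = L_0, v_insert = v0 / fold,
                 speed_fold = fold, per_aa_time_fold = fold),
            class = "elongation_estimate")
}

#' @export
print.elongation_estimate <- function(x, ...) {
  cat(sprintf(
    "<elongation_estimate> v0 %.3g codons/s; t = %.1f s = t_I %.1f + t_0 %.1f; v0/vI = %.2f\n",
    x$v0, x$t_target, x$t_I, x$t_0, x$speed_fold))
  invisible(x)
}

#' Fold change between two runoff medians
#'
#' @param t_target_median,t_control_median Median runoff times (same units).
#' @return The plain ratio, rounded to one decimal as conventionally reported.
#' @examples
#' fold_runoff_time(11.2, 4.9)  # 2.3
#' @export
fold_runoff_time <- function(t_target_median, t_control_median) {
  if (t_control_median <= 0) stop("parameter error: control median must be > 0")
  round(t_target_median / t_control_median, 1)
}

#' Summarize a FRAP trace
#'
#' Normalizes the post-bleach signal to the mean pre-bleach signal; the
#' recovery plateau is the mean of the final 10 percent of frames and the
#' half-time is the first post-bleach time at which the normalized signal
#' reaches half the plateau.
#'
#' @param signal Protein-channel signal, one value per frame (frame 0 at
#'   time 0).
#' @param dt Frame interval, s.
#' @param t_bleach Bleach time, s; at least 3 pre-bleach frames are required.
#' @return List with `curve` (`time_s`, `normalized`), `half_time_s`,
#'   `plateau`.
#' @export
frap_recovery <- function(signal, dt, t_bleach) {
  n <- length(signal)
  times <- (seq_len(n) - 1L) * dt
  pre <- times < t_bleach
  if (sum(pre) < 3L) stop("input error: need at least 3 pre-bleach frames")
  base <- mean(signal[pre])
  if (base <= 0) stop("input error: non-positive pre-bleach signal")
  post <- which(!pre)
  norm <- signal[post] / base
  n_tail <- max(1L, ceiling(0.1 * length(post)))
  plateau <- mean(norm[(length(post) - n_tail + 1L):length(post)])
  half <- NA_real_
  hit <- which(norm >= plateau / 2)
  if (length(hit) && plateau > 0) half <- times[post[min(hit)]] - t_bleach
  list(curve = data.frame(time_s = times[post], normalized = norm),
       half_time_s = half, plateau = plateau)
}
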