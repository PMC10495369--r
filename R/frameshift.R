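# Two-color frameshift classification: burst calling, per-trace class,
# population summary.

#' Robust noise statistics of a trace
#'
#' Baseline is the 5th percentile of the signal; the noise sd is the MAD of
#' successive differences divided by sqrt(2) (insensitive to slow bursts).
#'
#' @param signal Numeric trace.
#' @return List with `baseline` and `noise_sd`.
#' @export
trace_noise_stats <- function(signal) {
  list(baseline = unname(quantile(signal, 0.05, names = FALSE)),
       noise_sd = mad(diff(signal)) / sqrt(2))
}

#' Call ON bursts in a single channel
#'
#' Hysteresis thresholding: an ON interval starts once `min_on_frames`
#' consecutive frames exceed `on_threshold` and ends after `min_off_frames`
#' consecutive frames below it; ON intervals separated by fewer than
#' `min_off_frames` OFF frames are merged.
#'
#' @param signal Numeric trace.
#' @param on_threshold Threshold in the same units as `signal`; the default
#'   is `baseline + k_sd * noise_sd` estimated from the trace itself.
#' @param min_on_frames Minimum consecutive above-threshold frames to open a
#'   burst.
#' @param min_off_frames Consecutive below-threshold frames that close a
#'   burst.
#' @param k_sd Threshold in noise-sd units used when `on_threshold` is `NULL`.
#' @return Data frame of bursts (`start_frame`, `end_frame`, 0-based,
#'   inclusive); zero rows when the channel never fires.
#' @examples
#' call_bursts(c(0, 0, 9, 9, 9, 9, 0, 0), on_threshold = 5)
#' @export
call_bursts <- function(signal, on_threshold = NULL, min_on_frames = 3L,
                        min_off_frames = 2L, k_sd = 4) {
  if (is.null(on_threshold)) {
    ns <- trace_noise_stats(signal)
    on_threshold <- ns$baseline + k_sd * ns$noise_sd
  }
  if (on_threshold <= 0) stop("threshold must be > 0")
  above <- signal > on_threshold
  empty <- data.frame(start_frame = integer(0), end_frame = integer(0))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge ON runs separated by short OFF gaps
  if (nrow(iv) > 1L) {
    keep_start <- iv$start[1]
    merged <- list()
    for (k in 2:nrow(iv)) {
      gap <- iv$start[k] - iv$end[k - 1L] - 1L
      if (gap >= min_off_frames) {
        merged[[length(merged) + 1L]] <- c(keep_start, iv$end[k - 1L])
        keep_start <- iv$start[k]
      }
    }
    merged[[length(merged) + 1L]] <- c(keep_start, iv$end[nrow(iv)])
    iv <- as.data.frame(do.call(rbind, merged))
    names(iv) <- c("start", "end")
  }
  # a burst needs min_on_frames consecutive above frames somewhere inside
  ok <- vapply(seq_len(nrow(iv)), function(k) {
    seg <- above[iv$start[k]:iv$end[k]]
    rs <- rle(seg)
    any(rs$values & rs$lengths >= min_on_frames)
  }, logical(1))
  iv <- iv[ok, , drop = FALSE]
  if (!nrow(iv)) return(empty)
  data.frame(start_frame = iv$start - 1L, end_frame = iv$end - 1L)
}

#' Classify one two-color trace
#'
#' `frameshift` when both channels burst at least once within the
#' observation window (temporal overlap of the bursts is not required),
#' `normal` for channel 1 only, `ran_only` for channel 2 only, `silent`
#' otherwise.
#'
#' @param bursts_ch1,bursts_ch2 Burst tables from [call_bursts()] for the two
#'   channels of the same linked trace.
#' @return One of `"normal"`, `"frameshift"`, `"ran_only"`, `"silent"`.
#' @export
classify_trace <- function(bursts_ch1, bursts_ch2) {
  b1 <- nrow(bursts_ch1) > 0L
  b2 <- nrow(bursts_ch2) > 0L
  if (b1 && b2) "frameshift" else if (b1) "normal" else if (b2) "ran_only" else "silent"
}

#' Classify every trace of a two-color trace table
#'
#' Calls bursts in both protein channels of each (cell, RNA) trace and
#' records the per-trace class plus per-frame ON-state tallies used for the
#' time-in-state summary.  When `on_threshold_ch1`/`ch2` are `NULL` the
#' threshold is `baseline + k_sd * noise_sd` estimated per trace, which makes
#' classification invariant to uniform intensity rescaling.
#'
#' @param traces Trace table with `cell_id`, `rna_id`, `ch1_signal`,
#'   `ch2_signal`.
#' @param on_threshold_ch1,on_threshold_ch2 Absolute thresholds (a.u.), or
#'   `NULL` for per-trace noise-based thresholds.
#' @inheritParams call_bursts
#' @return Data frame: `cell_id`, `rna_id`, `class`, `ch1_burst_frames`,
#'   `ch2_burst_frames`, `frames_ch1_only`, `frames_both`, `frames_ch2_only`,
#'   `n_frames`.
#' @export
classify_traces <- function(traces, on_threshold_ch1 = NULL,
                            on_threshold_ch2 = NULL,
                            min_on_frames = 3L, min_off_frames = 2L,
                            k_sd = 4) {
  stopifnot(all(c("ch1_signal", "ch2_signal") %in% names(traces)))
  keys <- unique(traces[c("cell_id", "rna_id")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    tr <- traces[traces$cell_id == keys$cell_id[i] &
                 traces$rna_id == keys$rna_id[i], , drop = FALSE]
    tr <- tr[order(tr$frame), ]
    b1 <- call_bursts(tr$ch1_signal, on_threshold_ch1, min_on_frames,
                      min_off_frames, k_sd)
    b2 <- call_bursts(tr$ch2_signal, on_threshold_ch2, min_on_frames,
                      min_off_frames, k_sd)
    on1 <- frames_on(b1, nrow(tr))
    on2 <- frames_on(b2, nrow(tr))
    data.frame(cell_id = keys$cell_id[i], rna_id = keys$rna_id[i],
               class = classify_trace(b1, b2),
               ch1_burst_frames = sum(on1), ch2_burst_frames = sum(on2),
               frames_ch1_only = sum(on1 & !on2),
               frames_both = sum(on1 & on2),
               frames_ch2_only = sum(!on1 & on2),
               n_frames = nrow(tr), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

frames_on <- function(bursts, n) {
  on <- logical(n)
  for (k in seq_len(nrow(bursts)))
    on[(bursts$start_frame[k] + 1L):(bursts$end_frame[k] + 1L)] <- TRUE
  on
}

#' Population frameshift summary
#'
#' Class percentages over the chosen denominator (translating traces —
#' anything not silent — or all traces) and time-in-state fractions over all
#' frames in which at least one channel is ON.
#'
#' @param calls Output of [classify_traces()].
#' @param denominator `"translating"` or `"all"`.
#' @return Object of class `frameshift_summary`: `counts`, `percent`
#'   (named normal/frameshift/ran_only and, with denominator `"all"`,
#'   silent), `time_fractions` (ch1_only/both/ch2_only), `n_traces`,
#'   `n_translating`, `denominator`, `undefined` flag.
#' @export
summarize_population <- function(calls, denominator = c("translating", "all")) {
  denominator <- match.arg(denominator)
  if (!nrow(calls)) stop("no traces to summarize")
  counts <- table(factor(calls$class,
                         levels = c("normal", "frameshift", "ran_only", "silent")))
  n_translating <- sum(counts[c("normal", "frameshift", "ran_only")])
  denom <- if (denominator == "translating") n_translating else nrow(calls)
  undefined <- denom == 0L
  lev <- if (denominator == "translating")
    c("normal", "frameshift", "ran_only") else names(counts)
  percent <- if (undefined) setNames(rep(NA_real_, length(lev)), lev)
             else 100 * as.numeric(counts[lev]) / denom
  names(percent) <- lev
  tot_on <- sum(calls$frames_ch1_only + calls$frames_both + calls$frames_ch2_only)
  time_fractions <- if (tot_on == 0L)
    c(ch1_only = NA_real_, both = NA_real_, ch2_only = NA_real_)
  else c(ch1_only = sum(calls$frames_ch1_only) / tot_on,
         both = sum(calls$frames_both) / tot_on,
         ch2_only = sum(calls$frames_ch2_only) / tot_on)
  structure(list(counts = counts, percent = percent,
                 time_fractions = time_fractions,
                 n_traces = nrow(calls), n_translating = n_translating,
                 n_cells = length(unique(calls$cell_id)),
                 denominator = denominator, undefined = undefined),
            class = "frameshift_summary")
}

#' @export
print.frameshift_summary <- function(x, ...) {
  cat("<frameshift_summary> ", x$n_traces, " traces (", x$n_translating,
      " translating) over ", x$n_cells, " cell(s)\n", sep = "")
  if (x$undefined) {
    cat("  percentages undefined: no translating traces\n")
  } else {
    cat("  ", paste(sprintf("%s %.1f%%", names(x$percent), x$percent),
                    collapse = ", "), "\n", sep = "")
  }
  if (!any(is.na(x$time_fractions)))
    cat(sprintf("  time in state: ch1-only %.2f, both %.2f, ch2-only %.2f\n",
                x$time_fractions[1], x$time_fractions[2], x$time_fractions[3]))
  invisible(x)
}
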