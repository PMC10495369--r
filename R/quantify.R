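# Steady-state translation quantification.

#' Nascent-protein equivalents of a translation site
#'
#' Ratio of the background-subtracted translation-site intensity to the
#' median mature single-protein intensity, i.e. how many full-length
#' proteins' worth of fluorescence sit on the mRNA.
#'
#' @param tls_intensity Integrated translation-site intensity, a.u.
#' @param median_single_protein Median of the mature single-protein
#'   intensity population, a.u.
#' @param background Background to subtract, a.u.
#' @return Nascent units (>= 0).
#' @examples
#' nascent_units(7200, 1000)  # 7.2
#' @export
nascent_units <- function(tls_intensity, median_single_protein, background = 0) {
  if (!is.finite(median_single_protein) || median_single_protein <= 0)
    stop("parameter error: median_single_protein must be > 0")
  pmax(0, (tls_intensity - background) / median_single_protein)
}

#' Percentage of translating RNAs with replicate-level aggregation
#'
#' An RNA counts as translating when its nascent units reach `min_units`
#' (default 2 mature-protein equivalents: at least two nascent chains
#' distinguishes a translation site from a single mature protein diffusing at
#' the RNA).  Percentages are computed per cell, averaged within each
#' replicate, and summarized as mean and SD over replicate means — the
#' replicate, not the cell, is the statistical unit.
#'
#' @param records Data frame with `cell_id`, `nascent_units` (or a logical
#'   `translating` column) and optionally `replicate` (defaults to one
#'   replicate).
#' @param min_units Nascent-unit cutoff defining "translating".
#' @return List: `per_cell` (cell, replicate, n RNAs, percent), `per_replicate`
#'   (replicate means), `mean`, `sd`, `min_units`.
#' @export
percent_translating <- function(records, min_units = 2) {
  if (!"replicate" %in% names(records)) records$replicate <- 1L
  if (!"translating" %in% names(records)) {
    if (!"nascent_units" %in% names(records))
      stop("records need a nascent_units or translating column")
    records$translating <- records$nascent_units >= min_units
  }
  keys <- unique(records[c("replicate", "cell_id")])
  per_cell <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    rr <- records[records$replicate == keys$replicate[i] &
                  records$cell_id == keys$cell_id[i], ]
    if (!nrow(rr) || all(is.na(rr$translating))) {
      warning("cell ", keys$cell_id[i], " has no RNAs and was skipped")
      return(NULL)
    }
    data.frame(replicate = keys$replicate[i], cell_id = keys$cell_id[i],
               n_rna = nrow(rr), percent = 100 * mean(rr$translating))
  }))
  per_replicate <- aggregate(percent ~ replicate, per_cell, mean)
  names(per_replicate)[2] <- "mean_percent"
  list(per_cell = per_cell, per_replicate = per_replicate,
       mean = mean(per_replicate$mean_percent),
       sd = if (nrow(per_replicate) > 1) sd(per_replicate$mean_percent) else NA_real_,
       min_units = min_units)
}

#' Fraction of time an RNA spends translating
#'
#' Fraction of the trace's frames whose protein signal is inside an ON burst
#' (see [call_bursts()]).  Traces of 5 frames or fewer are rejected,
#' consistent with the track-length filter.
#'
#' @param signal Protein-channel trace.
#' @inheritParams call_bursts
#' @return Fraction in `[0, 1]`.
#' @export
fraction_time_translating <- function(signal, on_threshold = NULL,
                                      min_on_frames = 3L, min_off_frames = 2L,
                                      k_sd = 4) {
  if (length(signal) < 6L)
    stop("trace shorter than 6 frames is excluded from analysis")
  b <- call_bursts(signal, on_threshold, min_on_frames, min_off_frames, k_sd)
  mean(frames_on(b, length(signal)))
}

#' Two-sample equal-variance t test on replicate means
#'
#' Pooled-variance two-sample t statistic with a two-tailed p value, applied
#' to replicate means (each group needs at least 2 replicates).  Zero pooled
#' variance with equal means returns `t = 0, p = 1` by convention.
#'
#' @param replicate_means_a,replicate_means_b Numeric vectors of replicate
#'   means.
#' @return List: `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @examples
#' compare_groups(c(1, 2, 3), c(2, 3, 4))
#' @export
compare_groups <- function(replicate_means_a, replicate_means_b) {
  a <- replicate_means_a; b <- replicate_means_b
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 replicates")
  df <- length(a) + length(b) - 2L
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      message("zero pooled variance with equal means: p = 1 by convention")
      return(list(t = 0, df = df, p = 1, mean_a = mean(a), mean_b = mean(b)))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = df, p = 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}
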