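# Table readers/writers and the end-to-end pipeline.

TRACE_COLUMNS <- c("cell_id", "rna_id", "frame", "time_s", "rna_signal", "ch1_signal")

#' Read and write trace tables
#'
#' The traces file is a plain CSV with a mandatory header and columns
#' `cell_id`, `rna_id`, `frame` (0-based), `time_s`, `rna_signal`,
#' `ch1_signal`; `ch2_signal`, `x_px`, `y_px` are optional (a missing
#' `ch2_signal` means a one-color experiment).  Unknown extra columns are
#' preserved; the round trip is lossless.
#'
#' @param path File path.
#' @return [read_traces()]: the trace data frame.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(TRACE_COLUMNS, names(tr))
  if (length(miss))
    stop("schema error: missing mandatory column(s): ", paste(miss, collapse = ", "))
  for (col in intersect(c("frame", "time_s", "rna_signal", "ch1_signal",
                          "ch2_signal", "x_px", "y_px"), names(tr))) {
    v <- suppressWarnings(as.numeric(tr[[col]]))
    bad <- which(is.na(v) & !is.na(tr[[col]]))
    if (length(bad))
      stop("schema error: non-numeric value in column '", col,
           "' at data row ", bad[1])
    if (any(is.na(v)))
      stop("schema error: missing value in column '", col,
           "' at data row ", which(is.na(v))[1])
    tr[[col]] <- v
  }
  tr$frame <- as.integer(tr$frame)
  tr
}

#' @rdname read_traces
#' @param traces Trace data frame (or a `ribotrace_sim` object, whose
#'   `traces` element is written).
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "ribotrace_sim")) traces <- traces$traces
  miss <- setdiff(TRACE_COLUMNS, names(traces))
  if (length(miss))
    stop("schema error: missing mandatory column(s): ", paste(miss, collapse = ", "))
  write.csv(traces, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write ground-truth sidecars next to a traces file
#'
#' Writes `<stem>.ribosomes.csv` (per-ribosome records) and
#' `<stem>.rna_states.csv` (per-RNA class and ON intervals).
#'
#' @param sim A [simulate_traces()] result.
#' @param stem Path stem (without extension).
#' @return The two paths, invisibly.
#' @export
write_ground_truth <- function(sim, stem) {
  stopifnot(inherits(sim, "ribotrace_sim"))
  p1 <- paste0(stem, ".ribosomes.csv")
  p2 <- paste0(stem, ".rna_states.csv")
  write.csv(sim$truth$ribosomes, p1, row.names = FALSE, quote = FALSE)
  write.csv(sim$truth$rna_states, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Assemble a pipeline configuration
#'
#' Bundles the reporter design, kinetic parameters, analysis thresholds and
#' seed into one validated list; all thresholds default to the documented
#' conventions (10 percent runoff rule over 4 initial frames with a 3-frame
#' persistence guard, 5-frame minimum temporal overlap, track length > 5
#' frames, burst threshold 4 noise sd with 3 ON / 2 OFF frames, translating
#' cutoff 2 nascent units).
#'
#' @param design Preset name or `reporter_design`.
#' @param params A `kinetic_params` (defaults to `kinetic_params()`).
#' @param n_rna,n_cells Simulation size.
#' @param seed Master seed.
#' @param threshold_frac,init_frames,persistence Runoff rules.
#' @param min_overlap Minimum RNA/protein temporal overlap, frames.
#' @param min_track_len Tracks must be longer than this many frames.
#' @param min_units Translating cutoff, nascent units.
#' @param k_sd,min_on_frames,min_off_frames Burst calling.
#' @param survival_mode `"pooled_km"` or `"per_cell_mean"`.
#' @param control_median_s,L_I,L_0 Optional inputs for the elongation
#'   inversion stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(design = "elongation_NLuc", params = kinetic_params(),
                       n_rna = 50L, n_cells = 5L, seed = 1L,
                       threshold_frac = 0.10, init_frames = 4L, persistence = 3L,
                       min_overlap = 5L, min_track_len = 5L, min_units = 2,
                       k_sd = 4, min_on_frames = 3L, min_off_frames = 2L,
                       survival_mode = c("pooled_km", "per_cell_mean"),
                       control_median_s = NULL, L_I = NULL, L_0 = NULL) {
  if (is.character(design)) design <- build_reporter(design)
  stopifnot(inherits(design, "reporter_design"), inherits(params, "kinetic_params"))
  stopifnot(threshold_frac > 0, threshold_frac < 1, init_frames >= 1,
            persistence >= 1, min_overlap >= 1, min_units >= 0)
  structure(list(design = design, params = params, n_rna = n_rna,
                 n_cells = n_cells, seed = seed,
                 threshold_frac = threshold_frac, init_frames = init_frames,
                 persistence = persistence, min_overlap = min_overlap,
                 min_track_len = min_track_len, min_units = min_units,
                 k_sd = k_sd, min_on_frames = min_on_frames,
                 min_off_frames = min_off_frames,
                 survival_mode = match.arg(survival_mode),
                 control_median_s = control_median_s, L_I = L_I, L_0 = L_0),
            class = "run_config")
}

#' Run the simulation/analysis pipeline
#'
#' Executes the requested stages in order, writing every interface file into
#' `out_dir` plus a `manifest.json` recording the full configuration and
#' thresholds.  Stages: `simulate` (traces.csv + ground-truth sidecars),
#' `runoff` (runoff_records.csv, survival.csv and, when control inputs are
#' configured, elongation.json), `frameshift` (frameshift_calls.csv,
#' frameshift_summary.json; two-color designs only), `quantify`
#' (quantify.csv, group_summary.json), `report` (summary.json and a survival
#' figure).  Later stages read the earlier stages' files, so re-running a
#' downstream stage alone works against an existing directory and a missing
#' upstream artifact raises a dependency error naming the absent file.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Character subset of
#'   `c("simulate", "runoff", "frameshift", "quantify", "report")`.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "runoff", "report")) {
  stopifnot(inherits(config, "run_config"))
  known <- c("simulate", "runoff", "frameshift", "quantify", "report")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tr_path <- file.path(out_dir, "traces.csv")
  need_traces <- function() {
    if (!file.exists(tr_path))
      stop("dependency error: missing upstream artifact ", tr_path,
           " (run the simulate stage first)")
    read_traces(tr_path)
  }
  summary <- list()

  if ("simulate" %in% stages) {
    sim <- simulate_traces(config$design, config$params, n_rna = config$n_rna,
                           seed = config$seed, n_cells = config$n_cells)
    write_traces(sim, tr_path)
    write_ground_truth(sim, file.path(out_dir, "traces"))
  }

  if ("runoff" %in% stages) {
    traces <- need_traces()
    t_drug <- config$params$t_drug
    if (is.na(t_drug)) t_drug <- 0
    rec <- runoff_records(traces, t_drug = t_drug,
                          threshold_frac = config$threshold_frac,
                          init_frames = config$init_frames,
                          persistence = config$persistence)
    write.csv(rec, file.path(out_dir, "runoff_records.csv"), row.names = FALSE)
    sc <- if (config$survival_mode == "pooled_km") km_survival(rec)
          else per_cell_survival(rec)
    sv <- cbind(sc$curve, mode = sc$mode)
    names(sv)[1:5] <- c("time_s", "survival", "ci_low", "ci_high", "n_at_risk")
    write.csv(sv, file.path(out_dir, "survival.csv"), row.names = FALSE)
    summary$median_runoff_s <- sc$median_s
    summary$n_excluded <- sc$n_excluded
    if (!is.null(config$control_median_s) && !is.null(config$L_I) &&
        !is.null(config$L_0) && !is.na(sc$median_s)) {
      v0 <- estimate_v0(config$control_median_s, config$L_I + config$L_0)
      est <- elongation_fold(sc$median_s, v0, config$L_I, config$L_0)
      jsonlite::write_json(unclass(est), file.path(out_dir, "elongation.json"),
                           auto_unbox = TRUE, digits = NA)
      summary$speed_fold <- est$speed_fold
    }
  }

  if ("frameshift" %in% stages) {
    traces <- need_traces()
    if (!"ch2_signal" %in% names(traces))
      stop("dependency error: frameshift stage needs two-color traces (ch2_signal)")
    calls <- classify_traces(traces, k_sd = config$k_sd,
                             min_on_frames = config$min_on_frames,
                             min_off_frames = config$min_off_frames)
    write.csv(calls, file.path(out_dir, "frameshift_calls.csv"), row.names = FALSE)
    fsum <- summarize_population(calls)
    jsonlite::write_json(
      list(percent = as.list(fsum$percent),
           time_fractions = as.list(fsum$time_fractions),
           n_traces = fsum$n_traces, n_translating = fsum$n_translating,
           thresholds = list(k_sd = config$k_sd,
                             min_on_frames = config$min_on_frames,
                             min_off_frames = config$min_off_frames)),
      file.path(out_dir, "frameshift_summary.json"), auto_unbox = TRUE, digits = NA)
    summary$percent_frameshift <- unname(fsum$percent["frameshift"])
  }

  if ("quantify" %in% stages) {
    traces <- need_traces()
    keys <- unique(traces[c("cell_id", "rna_id")])
    fr <- vapply(seq_len(nrow(keys)), function(i) {
      s <- traces$ch1_signal[traces$cell_id == keys$cell_id[i] &
                             traces$rna_id == keys$rna_id[i]]
      if (length(s) < 6L) return(NA_real_)
      fraction_time_translating(s, k_sd = config$k_sd,
                                min_on_frames = config$min_on_frames,
                                min_off_frames = config$min_off_frames)
    }, numeric(1))
    qt <- cbind(keys, fraction_translating = fr)
    write.csv(qt, file.path(out_dir, "quantify.csv"), row.names = FALSE)
    summary$mean_fraction_time_translating <- mean(fr, na.rm = TRUE)
  }

  if ("report" %in% stages) {
    sv_path <- file.path(out_dir, "survival.csv")
    if (!file.exists(sv_path) && !file.exists(tr_path))
      stop("dependency error: missing upstream artifact ", tr_path)
    if (file.exists(sv_path)) {
      sv <- read.csv(sv_path)
      grDevices::pdf(file.path(out_dir, "survival.pdf"), width = 5, height = 4)
      sc <- structure(list(curve = sv,
                           median_s = curve_median(sv$time_s, sv$survival),
                           mode = sv$mode[1], n_used = NA, n_excluded = NA),
                      class = "survival_curve")
      plot(sc, main = "translation-site survival")
      grDevices::dev.off()
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package = "ribotrace",
    version = as.character(utils::packageVersion("ribotrace")),
    seed = config$seed,
    design = config$design$name,
    stages = stages,
    params = unclass(config$params),
    thresholds = config[setdiff(names(config), c("design", "params"))])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
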