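#' Kinetic and measurement parameters for the trace simulator
#'
#' Collects every rate, speed and noise term of the mechanistic model.
#' Initiation is a two-state (telegraph) process: the mRNA switches ON with
#' rate `k_on` and OFF with rate `k_off` (1/s), and while ON ribosomes initiate
#' as a Poisson process with rate `k_init` (1/s), subject to steric exclusion
#' at the start codon.  Ribosomes step codon by codon at `v_flank` codons/s
#' outside the insert and `v_insert` codons/s inside it.  `p_fs_traversal` is
#' the total probability that a ribosome shifts into the channel-2 frame while
#' traversing the insert (converted internally to a per-codon hazard);
#' `p_ran` is a per-RNA-per-second hazard of cap-independent channel-2-only
#' initiation at the insert.
#'
#' Measurement: each completed epitope contributes `unit_intensity` (a.u.) of
#' fluorescence; integrated spot read-outs get additive Gaussian noise of sd
#' `noise_sd` on top of `background` (negative read-outs are not clipped).
#' Frames are taken every `dt` seconds for `duration` seconds; defaults match
#' the imaging regimes emulated here (10 s for 30 min in runoff mode; FRAP
#' uses 5 s for 10 min).  `t_drug` (s, `NA` for none) stops all initiation
#' (harringtonine); `t_bleach` (s, `NA` for none) zeroes all accumulated
#' fluorescence at that instant while later-completed epitopes fluoresce.
#' `mature_median`/`mature_cv` describe the mature single-protein intensity
#' population used for normalization (`NA` median means "24 epitopes worth",
#' i.e. `24 * unit_intensity`).
#'
#' @param k_on,k_off Telegraph switching rates, 1/s.
#' @param k_init Initiation rate while ON, 1/s.
#' @param v_flank Elongation speed outside the insert (the `v0` of the runoff
#'   inversion), codons/s.
#' @param v_insert Elongation speed inside the insert (`vI`), codons/s.
#' @param footprint Steric exclusion size, codons (>= 1).
#' @param p_fs_traversal Per-traversal frameshift probability, in `[0, 1]`.
#' @param p_ran Hazard of RAN (channel-2-only) initiation, 1/s.
#' @param unit_intensity Fluorescence per completed epitope, a.u.
#' @param noise_sd Additive Gaussian measurement noise, a.u.
#' @param background Additive background, a.u.
#' @param rna_intensity Mean RNA-channel spot intensity, a.u.
#' @param dt Frame interval, s.
#' @param duration Movie length, s.
#' @param t_drug Initiation shut-off time, s (`NA` = none).
#' @param t_bleach Photobleach time, s (`NA` = none).
#' @param mature_median,mature_cv Mature-protein intensity median (a.u.) and
#'   coefficient of variation.
#' @param exclusion Logical; enforce the steric-exclusion footprint (set
#'   `FALSE` to let ribosomes pass freely, e.g. for closed-form checks).
#'
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(k_on = 0.02, k_off = 0.005, k_init = 0.02,
                           v_flank = 3.5, v_insert = 3.5,
                           footprint = 10L,
                           p_fs_traversal = 0, p_ran = 0,
                           unit_intensity = 100, noise_sd = 30,
                           background = 50, rna_intensity = 1000,
                           dt = 10, duration = 1800,
                           t_drug = NA_real_, t_bleach = NA_real_,
                           mature_median = NA_real_, mature_cv = 0.3,
                           exclusion = TRUE) {
  p <- structure(list(
    k_on = k_on, k_off = k_off, k_init = k_init,
    v_flank = v_flank, v_insert = v_insert,
    footprint = as.integer(footprint),
    p_fs_traversal = p_fs_traversal, p_ran = p_ran,
    unit_intensity = unit_intensity, noise_sd = noise_sd,
    background = background, rna_intensity = rna_intensity,
    dt = dt, duration = duration,
    t_drug = t_drug, t_bleach = t_bleach,
    mature_median = mature_median, mature_cv = mature_cv,
    exclusion = isTRUE(exclusion)
  ), class = "kinetic_params")
  validate_params(p)
}

validate_params <- function(p) {
  num <- unlist(p[c("k_on", "k_off", "k_init", "v_flank", "v_insert",
                    "p_fs_traversal", "p_ran", "unit_intensity", "noise_sd",
                    "background", "rna_intensity", "dt", "duration",
                    "mature_cv")])
  if (any(!is.finite(num))) stop("parameter error: non-finite parameter value")
  if (any(num < 0)) stop("parameter error: rates, speeds and noise terms must be >= 0")
  if (p$p_fs_traversal > 1) stop("parameter error: p_fs_traversal must be <= 1")
  if (p$v_flank <= 0) stop("parameter error: v_flank must be > 0")
  if (p$footprint < 1L) stop("parameter error: footprint must be >= 1")
  if (p$dt <= 0) stop("parameter error: dt must be > 0")
  if (p$duration < p$dt) stop("parameter error: duration must be >= dt")
  for (tf in c("t_drug", "t_bleach")) {
    v <- p[[tf]]
    if (!is.na(v) && (!is.finite(v) || v < 0)) stop("parameter error: ", tf, " must be >= 0 or NA")
  }
  if (!is.na(p$mature_median) && p$mature_median <= 0)
    stop("parameter error: mature_median must be > 0")
  if (p$mature_cv < 0) stop("parameter error: mature_cv must be >= 0")
  p
}

#' Update fields of a parameter set
#'
#' Convenience wrapper that replaces named fields and re-validates.
#' @param params A `kinetic_params` object.
#' @param ... Fields to replace.
#' @return A `kinetic_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "kinetic_params"))
  new <- list(...)
  bad <- setdiff(names(new), names(unclass(params)))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  for (nm in names(new)) params[[nm]] <- new[[nm]]
  params$footprint <- as.integer(params$footprint)
  validate_params(params)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf("  initiation: k_on %.4g k_off %.4g k_init %.4g 1/s  (duty %.2f)\n",
              x$k_on, x$k_off, x$k_init,
              if (x$k_on + x$k_off > 0) x$k_on / (x$k_on + x$k_off) else 1))
  cat(sprintf("  elongation: v_flank %.3g v_insert %.3g codons/s, footprint %d\n",
              x$v_flank, x$v_insert, x$footprint))
  cat(sprintf("  frameshift p %.3g / traversal, RAN hazard %.3g 1/s\n",
              x$p_fs_traversal, x$p_ran))
  cat(sprintf("  imaging: dt %g s, duration %g s, drug %s s, bleach %s s\n",
              x$dt, x$duration, format(x$t_drug), format(x$t_bleach)))
  invisible(x)
}

# per-codon stepping rates: completing codon j uses the speed of j's region
step_rates <- function(design, params) {
  v <- rep(params$v_flank, design$total_length)
  ins <- insert_region(design)
  if (!is.null(ins)) v[ins$start:ins$end] <- params$v_insert
  v
}

# per-traversal probability p -> per-codon hazard h = 1 - (1-p)^(1/L_I)
fs_hazards <- function(design, params) {
  h <- rep(0, design$total_length)
  ins <- insert_region(design)
  li <- insert_length(design)
  if (params$p_fs_traversal > 0) {
    if (li == 0L)
      stop("parameter error: p_fs_traversal > 0 requires an insert region")
    h[ins$start:ins$end] <- 1 - (1 - params$p_fs_traversal)^(1 / li)
  }
  h
}
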