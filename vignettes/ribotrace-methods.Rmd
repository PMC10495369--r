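---
title: "ribotrace: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ribotrace: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ribotrace` simulates and analyzes single-molecule translation-site (TLS)
imaging experiments of the SunTag/MS2 kind: single mRNAs tethered to the
plasma membrane, their nascent peptides made visible by fluorescent
single-chain antibodies binding epitope arrays co-translationally. This
vignette documents the mechanistic model behind the simulator, the analysis
conventions, the numerical choices, and what the synthetic data can and
cannot tell you about real experiments.

## The mechanistic trace model

A reporter ORF (`build_reporter()`) is a codon-resolution layout: an epitope
cassette whose `epitope_positions` mark the codon at which each epitope
becomes antibody-bound (binding is taken as instantaneous on completion;
fluorophore maturation is neglected, the standard fast-binding assumption
for these probes), an optional insert region (the repeat or a control
sequence), and flanking ORF. Two-color frameshift reporters add a second,
downstream cassette reachable only by ribosomes that shift reading frame
inside the insert (or by cap-independent initiation), with the first frame's
stop codon immediately after the insert.

Translation on each mRNA is simulated event by event (Gillespie, in C++):

* **Initiation.** A telegraph process switches the mRNA ON with rate `k_on`
  and OFF with rate `k_off` (1/s); while ON, ribosomes initiate as a Poisson
  process with rate `k_init`, blocked while the first `footprint` codons are
  occupied. The long-run ON fraction is `k_on / (k_on + k_off)`.
* **Elongation.** Each ribosome advances codon by codon with exponential
  dwell of mean `1/v`, where `v` is `v_flank` outside the insert and
  `v_insert` inside it. A deterministic-stepping mode (dwell exactly `1/v`)
  exists for analytic checks, e.g. a single unobstructed ribosome on a
  1003-codon ORF at 3.5 codons/s terminates at exactly 286.6 s.
* **Exclusion.** Two ribosomes never come closer than `footprint` codons
  (default 10). Exclusion can be switched off entirely, which makes
  ribosomes fully independent (they may pass through each other); see the
  runoff section for when and why we use that mode.
* **Frameshift.** A per-traversal probability `p` is converted to the
  per-codon hazard `h = 1 - (1 - p)^(1/L_I)` applied at every insert codon;
  a shifted ribosome continues at `v_insert` to the insert end, then
  translates the downstream cassette at `v_flank` and terminates at the
  second frame's stop. `p_ran` adds an independent Poisson hazard of
  channel-2-only initiation at the insert (default 0).
* **Signal.** At each frame, each channel reads
  `unit_intensity × (epitopes completed and still attached) + background +
  Gaussian noise`. Terminated chains leave the site. Harringtonine
  (`t_drug`) zeroes the initiation rate from that instant; photobleaching
  (`t_bleach`) zeroes all accumulated fluorescence while letting
  subsequently completed epitopes fluoresce. Noise is additive Gaussian on
  the integrated spot intensity and negative read-outs are deliberately not
  clipped, so downstream thresholds see realistic fluctuations.

Each simulation starts at a negative time (burn-in of twice the full ORF
traversal time plus three telegraph correlation times) so that frame 0
samples the stationary regime. One master seed drives everything; each RNA
runs on a substream derived deterministically from `(seed, cell_id,
rna_id)`, making output byte-identical for identical inputs.

Ground truth records every ribosome (initiation, frameshift codon,
termination), the ON/OFF intervals, the noiseless per-frame epitope counts,
and a per-RNA class. The class is defined *observationally*: a trace is
`frameshift` when both channels carry visible signal in the observation
window, `ran_only` when only channel 2 does, which matches what any
classifier could in principle recover. (With `p_ran > 0` a RAN event on an
otherwise normally translating RNA is therefore labelled `frameshift`; at
the default `p_ran = 0` the distinction never arises.)

## Reporter geometries

The presets encode the construct family analyzed here. The one-color
elongation reporter is a 3009-nt (1003-codon) ORF: a 24-epitope SunTag
cassette, the 420-nt (140-codon) hexanucleotide-repeat insert, and the
degron tail; the control replaces the repeat with a 513-nt (171-codon)
NanoLuc insert. The published construct sizes fix the insert (140 codons)
and the non-insert total (863 codons) but not the internal split, so the
cassette is laid out as 24 epitopes completing every 22 codons (528 codons)
with a 335-codon tail — only epitope *positions* matter to any analysis
here, and only through the time each epitope remains attached. The
two-color preset places 24 channel-1 epitopes upstream and 24 channel-2
epitopes downstream of the insert. The per-epitope brightness of the two
channels is taken as equal (one `unit_intensity` each); nothing in the
analyses depends on the ratio because thresholds are per-channel.

## Kinetic defaults

Defaults describe a bursty, moderately loaded mRNA imaged in runoff mode:
`k_on = 0.02`, `k_off = 0.005` (ON fraction 0.8), `k_init = 0.02`/s while
ON, `v_flank = 3.5` codons/s, frame interval 10 s for 30 min (FRAP mode uses
5 s for 10 min). An initiation event every ~50 s keeps the instantaneous
flux below the carrying capacity `v_insert / footprint` of even a 15-fold
slowed insert, so hard exclusion and bursting can both stay on without the
insert jamming. `unit_intensity = 100` a.u. per epitope, `background = 50`,
`noise_sd = 30` (0.3 epitope equivalents) give realistic single-epitope
signal-to-noise; a mature protein carries 24 epitopes, and the mature-spot
population is Gamma with that median and CV 0.3 unless overridden.

## Runoff analysis

`extract_runoff_time()` implements the trace rules: the threshold is 10% of
the raw trace maximum (no smoothing by default; a window-3 moving average is
available but off, since the convention here scores the raw trace); traces
whose first four frames average below threshold were not visibly translating
at drug addition and are excluded (`low_initial`); the runoff time is the
first frame at or after `t_drug` that falls below threshold and stays there
for at least 3 consecutive frames — the persistence guard keeps single-frame
noise dips from ending a trace; traces still above threshold at movie end
are right-censored, never discarded; and an RNA track that terminates within
2 frames of the final signal loss is excluded as a co-disappearance (likely
loss of the tracked mRNA rather than runoff).

Survival curves come in two modes. `km_survival()` is the product-limit
estimator over pooled runoff times with pointwise Greenwood confidence
bounds (`S ± z·SE`, clipped to [0, 1]); `per_cell_survival()` computes each
cell's fraction of still-translating RNAs and averages across cells with an
across-cell standard error, treating censored traces as surviving. The
median is by convention the first time survival reaches 0.5; on a 10-s
frame grid that step convention quantizes, so `survival_median(...,
interpolate = TRUE)` reads the 50% crossing off the curve by linear
interpolation — the same thing one does graphically on a per-cell averaged
curve — and is what the cohort analyses below use. A median is reported as
undefined (`NA`) when the curve never reaches 0.5; it is never extrapolated.
Group comparison uses the log-rank (Mantel–Cox) test via the `survival`
package, with an optional administrative censoring horizon (default
suggestion 15 min) standing in for a time-restricted comparison; a full Cox
regression is out of scope.

### Elongation-speed inversion

The runoff time of the last ribosome decomposes over the regions it
traverses: `t = t_I + t_0 = L_I/v_I + L_0/v_0`. A uniform-speed control
gives `v_0 = L/t_control`; the insert speed fold then follows as
`v_0/v_I = (t_target − L_0/v_0) / (L_I/v_0)`, which equals the fold change
in per-amino-acid residence time inside the insert. The control ORF length
must be supplied explicitly (`estimate_v0(t, L)`) and is always reported
with the estimate, because the estimate is only as good as the length it is
anchored on.

### Cohort conditions for runoff simulations

Runoff cohorts (the parameter-recovery analyses and the acceptance script)
are simulated under `k_init = 0.1`/s with exclusion off, rather than the
bursty low-load defaults. The reason is measurement geometry, not
convenience: the 10%-of-maximum rule crosses while roughly a tenth of the
peak epitope load is still attached. Under sparse loading that crossing
collapses onto the exit of the single last ribosome, whose initiation time
is a full `1/k_init` before drug on average, biasing the apparent `v_0`
upward and the recovered folds with it; under continuous loading the
crossing sits a fixed, insert-dependent offset before the last exit and the
bias cancels almost exactly between control and target in the fold formula.
Continuous loading at `k_init = 0.1` would, however, exceed the carrying
capacity of a 10–15× slowed insert if hard exclusion were enforced, piling
up queues whose drainage would dominate the runoff time — a regime the
empirical survival curves this model emulates do not show (slowed-insert
medians sit near the free-runoff expectation, consistent with collided
ribosomes being cleared by quality-control pathways rather than
accumulating). Since ribosome-collision surveillance is explicitly not
modelled here, the cohorts use the independent-ribosome mode; the hard
footprint stays on by default everywhere else. With a 300-trace control and
100-trace targets, recovered folds carry a standard deviation of roughly
5% (about ±0.05–0.06 at fold 1), so single-cohort recoveries at factor 1
land within ±0.1 in most but not every realization.

## Two-color frameshift classification

`call_bursts()` applies hysteresis thresholding per channel: an ON interval
needs 3 consecutive frames above threshold to open, 2 consecutive below to
close, and intervals separated by shorter OFF gaps merge. The default
threshold is the trace baseline (5th percentile) plus 4 noise standard
deviations, with the noise estimated robustly from successive differences;
expressing the threshold in noise units makes classification invariant to
uniform intensity rescaling. At these settings the false-positive rate on
noise-only channels is far below the 1% budget (a single frame exceeds 4 sd
with probability ~3×10⁻⁵, three in a row essentially never). The
difference-based noise estimate assumes the signal moves slowly relative to
the frame interval; for traces with very fast dynamics pass an explicit
`on_threshold` built from the known noise model instead.

A trace is `frameshift` when both channels burst at least once anywhere in
the window — temporal overlap is deliberately not required, because a
shifted ribosome finishes the downstream cassette after upstream ribosomes
may have terminated; `ran_only` requires zero channel-1 bursts over the
whole track. Population summaries report class percentages over translating
(non-silent) traces by default and time-in-state fractions (ch1-only /
both / ch2-only) over frames with at least one channel ON.

## Quantification

`nascent_units()` divides background-subtracted TLS intensity by the median
mature single-protein intensity. The "actively translating" cutoff defaults
to 2 mature-protein equivalents — at least two nascent chains distinguishes
a translation site from a single mature protein diffusing at the RNA — and
the cutoff is a reported parameter, not a constant, since the underlying
convention is not standardized. Percent-translating aggregates per cell,
then per replicate, and summarizes as mean ± SD *over replicate means*: the
replicate is the statistical unit. Group comparison is the two-tailed,
equal-variance (pooled) t test. In trace mode, background for intensity
normalization uses the trace's 5th percentile; in image mode, the local fit
background.

## Image rendering, detection and linking

`render_frames()` draws each spot as a 2-D Gaussian (peak amplitude in
photons) on a uniform background with Poisson pixel noise; coordinates are
continuous with the origin at the center of pixel (0, 0), and pixel values
sample the model at pixel centers, so the Gaussian-fit estimates are exactly
unbiased on noiseless renders. `detect_spots()` band-passes (difference of
Gaussians at 1× and 3× the expected width), takes local maxima above
`snr_threshold` times the robust noise, and refines each candidate by
least-squares 2-D Gaussian fit in an 11×11 window, rejecting fits whose
width strays beyond a factor 2 of the expectation. `link_spots()` performs
greedy nearest-neighbour frame-to-frame assignment (cost = squared
displacement, moves capped at `max_disp` px/frame, gaps closed up to
`max_gap` frames) and flags merge/split collisions; tracks longer than 5
frames (i.e. ≥ 6, counting spanned frames including closed gaps) survive
`filter_tracks()`, and merge/split tracks are dropped. RNA–protein pairing
requires at least 5 co-existing frames and minimal time-averaged distance
within 3 px (the colocalization radius is a package convention — no
published threshold exists — and is carried in the linking output);
ties break deterministically toward the lower RNA track id.

Resolution limits are what a Gaussian-PSF model implies: two spots 6σ apart
are resolved, at 1σ at most one is found. No motion-model tracking, 3-D
localization, drift or chromatic correction is attempted.

## What the synthetic data does and does not emulate

The generator reproduces the statistical structure the analyses consume:
stationary bursty loading, region-dependent elongation, drug shutoff,
bleach-and-recover, rare frameshift and RAN events, mature-protein intensity
populations, tethered spot motion, and camera-level shot noise. It does not
model RNA secondary structure or codon-specific dwell variation,
ribosome-collision surveillance (RQC) and its clearance dynamics,
probe-binding kinetics or photobleaching of the antibody pool, 3-D optics or
camera register artifacts. Passing the recovery analyses therefore shows the
*analysis chain* is correct and unbiased under the stated model; it does not
certify any biological claim about real traces whose noise or kinetics
depart from that model.

## Problem sizes and runtimes

The bundled analyses use cohorts of 100 runoff traces (300 for the control
anchor), 500 two-color traces per frameshift condition, 200 traces for
duty-cycle recovery, 500 replicates for confidence-bound coverage, 10⁴ null
draws for test size, and 100 rendered frames for localization statistics —
sizes at which every recovery lands well inside its tolerance while the full
test suite and the acceptance script each run in a couple of minutes on one
CPU.
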