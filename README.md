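# ribotrace

Simulation and analysis of single-molecule translation-site imaging, built
around the harringtonine ribosome-runoff assay for measuring elongation
speed through difficult coding sequences (expanded GGGGCC repeats and the
dipeptide-repeat frames they encode), two-color detection of ribosomal
frameshifting on single mRNAs, and steady-state quantification of
translating mRNA fractions.

It is written for people analyzing SunTag/MS2-style live-cell data — traces
of RNA-channel and nascent-protein-channel intensity per tracked mRNA — and
for people who want a mechanistic, fully seeded simulator of such data with
ground truth, so that every analysis step can be validated end to end
without any external dataset.

## What it computes

**Runoff survival and elongation speed.** After harringtonine blocks
initiation, loaded ribosomes run off; the time until a translation site's
signal falls persistently below 10% of its trace maximum is its runoff time
*t*. Pooled Kaplan–Meier or per-cell-averaged survival curves (Greenwood
95% bounds, log-rank comparison) summarize cohorts, and the median runoff
time inverts to elongation speed through the insert via

    t = t_I + t_0 = L_I / v_I + L_0 / v_0,
    v_0 / v_I = (t − L_0/v_0) / (L_I/v_0)

with `v_0 = L / t_control` anchored on a uniform-speed control reporter.
`v_0/v_I` equals the fold change in ribosome residence time per amino acid
inside the insert.

**Frameshift classification.** Two-color traces (upstream epitope cassette
in frame 1, downstream cassette reachable only by frameshifting) are
burst-called per channel and classified normal / frameshift / RAN-only /
silent, with population percentages and time-in-state fractions.

**Quantification.** Translation-site intensities normalize to nascent-chain
counts by the median mature single-protein intensity; percent-translating
and fraction-of-time-translating aggregate per cell and per replicate with
the replicate as statistical unit (equal-variance two-tailed t test).

**Imaging front end.** A renderer (Gaussian PSF, Poisson noise), sub-pixel
spot detection, nearest-neighbour track linking with gap closing, track
filtering (length > 5 frames, merge/split discard) and RNA–protein pairing
(≥ 5 co-existing frames, ≤ 3 px mean distance).

**Simulator.** A Gillespie model per mRNA: telegraph-bursted initiation,
codon-wise stepping with region-specific speeds and steric exclusion,
per-traversal frameshift hazard, harringtonine shutoff, photobleaching,
measurement noise — with per-ribosome ground truth and deterministic
per-RNA seed substreams. See `vignette source in vignettes/` for the model
and every convention.

## Worked example

Simulate a runoff cohort on the repeat reporter with a true 10× slow-down
in the insert, and recover the slow-down from the traces alone:

```r
library(ribotrace)

design <- build_reporter("elongation_GGGGCC70")
design
#> <reporter_design> elongation_GGGGCC70: 1003 codons, insert 140 codons, 24 ch1 epitopes

params <- kinetic_params(k_init = 0.1, exclusion = FALSE,
                         v_insert = 0.35,      # 10x slow-down in the repeat
                         t_drug = 0)
sim <- simulate_traces(design, params, n_rna = 100, seed = 1, n_cells = 5)

rec <- runoff_records(sim$traces, t_drug = 0)
sc  <- km_survival(rec)
sc
#> <survival_curve> mode pooled_km, n = 100 (0 excluded), median = 580 s

# anchor v0 on a NanoLuc-insert control cohort
ctrl     <- build_reporter("elongation_NLuc")
ctrl_sim <- simulate_traces(ctrl, update_params(params, v_insert = 3.5),
                            n_rna = 300, seed = 2, n_cells = 5)
v0 <- estimate_v0(survival_median(km_survival(runoff_records(ctrl_sim$traces)),
                                  interpolate = TRUE),
                  ctrl$total_length)
round(v0, 2)
#> [1] 3.89

elongation_fold(survival_median(sc, interpolate = TRUE), v0,
                L_I = insert_length(design), L_0 = flank_length(design))
#> <elongation_estimate> v0 3.89 codons/s; t = 580.0 s = t_I 358.1 + t_0 221.9; v0/vI = 9.95
```

The decomposition says: of the 580 s median runoff, 222 s were spent in the
863 flanking codons and 358 s in the 140-codon insert, i.e. ribosomes moved
9.95-fold slower per amino acid through the insert — recovering the
simulated factor of 10.

The whole chain also runs as a pipeline writing the standard CSV/JSON
interface files:

```r
cfg <- run_config(design = "elongation_NLuc",
                  params = kinetic_params(k_init = 0.1, exclusion = FALSE,
                                          t_drug = 0),
                  n_rna = 50, n_cells = 5, seed = 1)
run_pipeline(cfg, "out", stages = c("simulate", "runoff", "report"))
```

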