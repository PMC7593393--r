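# erptopo

Topographic analysis of multichannel evoked potentials in R: preprocessing,
reference-independent randomization statistics, automated component marking,
and microstate segmentation for stimulus-locked EEG — built for sensory
evoked potentials (SEPs) such as those elicited by lower-urinary-tract or
pudendal stimulation, and applicable to any stimulus-locked multichannel
paradigm.

## Who this is for, and what it computes

Multichannel SEP studies ask two separable questions at every post-stimulus
time point: does a condition change the **strength** of the scalp field, and
does it change its **topography** (the configuration of active sources)?
`erptopo` implements the standard toolkit for both, for researchers who have
(or simulate) subject × condition evoked maps:

* **Global field power (GFP)** — the spatial standard deviation of an
  average-referenced map `u` over `K` channels,
  `GFP = sqrt( Σᵢ (uᵢ − ū)² / K )`, a reference-independent measure of map
  strength.
* **Randomization tests**, all built on the generalized dissimilarity
  effect size `Σ_ℓ GFP(m̄_ℓ − m̄)` (summed GFP distance of level mean maps
  from the grand mean) with `p = (#{null ≥ obs} + 1)/(n_perm + 1)`:
  * `tanova()` — topographic ANOVA on GFP-normalized maps (topography only),
    with within-subject, between-subject and interaction factors;
  * `gfp_test()` — the same permutation schemes on raw per-map GFP values
    (strength only);
  * `tct()` — topographic consistency test: is there any topography shared
    across subjects (null: channel shuffle within each subject's map);
  * `t_map()` — descriptive channel-wise paired/Welch t-maps.
* **Component marking** — windowed-extremum P1/N1/P2 detection on clinical
  derivations (Cz–Fz, Cz–AvgRef), split-half stability gating, responder
  rates, and component time windows from mean ± 2 SD latencies, GFP minima,
  or GFP inflection points.
* **Microstates** — atomize-and-agglomerate hierarchical clustering (AAHC)
  with polarity-sensitive or -ignorant correlation, split-half
  cross-validated selection of the class count, and permutation comparison
  of class parameters (duration, mean GFP, occurrence) across conditions.
* **Preprocessing & I/O** — BrainVision (.vhdr/.vmrk/.eeg, multiplexed
  int16/float32) reading, zero-phase Butterworth filtering, average
  reference, Perrin spherical-spline virtual channels (CzCPz, FzFCz),
  epoching, ±100 µV artifact rejection, baseline correction, split-half
  averages.
* **A synthetic SEP generator** (`simulate_sep()`) with programmed component
  patterns, frequency-dependent amplitude scaling, subject variability and
  smoothed noise — the seeded ground truth behind every validation.

Results come back as tibbles with broom-style `tidy()`/`glance()` and
ggplot2 `autoplot()` methods; `run_pipeline()` drives the whole workflow
from a YAML/list config and writes deterministic TSV/JSON outputs.

## Worked example

Simulate a small three-frequency study (12 subjects, 30 trials, 20-channel
montage), mark the components on the clinical Cz–Fz derivation, and test the
frequency effect on map strength:

```r
library(erptopo)

ds <- simulate_sep(
  generator_config(
    montage = standard_montage("10-20-20"),
    n_subjects = 12, frequencies = c("0.5 Hz", "1.1 Hz", "1.6 Hz"),
    trials = 30, sampling_rate = 250
  ),
  seed = 1
)

ga <- grand_average(ds, frequency = "0.5 Hz")
detect_markers(difference_channel(ga, "Cz", "Fz"), channel_pair = "Cz-Fz")
#> # A tibble: 3 × 4
#>   component latency_ms amplitude_uv polarity
#>   <chr>          <dbl>        <dbl> <chr>
#> 1 P1                60        0.306 positive
#> 2 N1               120       -3.35  negative
#> 3 P2               260        3.38  positive

stk <- evoked_stack(ds)
gfp_test(stk$maps, stk$design, n_perm = 999, seed = 1, time = stk$time) |>
  significant_intervals()
#> # A tibble: 3 × 3
#>   factor start_ms end_ms
#>   <chr>     <dbl>  <dbl>
#> 1 within      -88     52
#> 2 within       60    164
#> 3 within      192    312
```

The markers sit at the generator's programmed latencies (P1 60 ms, N1
115 ± 7 ms jitter, P2 255 ms); the GFP test finds the frequency effect on
map strength across the N1 and P2 periods — and in the pre-stimulus segment,
where the generator's anticipatory CNV ramp is strongest for slow pacing.
Component windows derived from the GFP curve of the pooled grand average:

```r
windows_from_gfp(gfp_curve(grand_average(ds)), mode = "minima")
#> # A tibble: 2 × 5
#>   component start_ms end_ms peak_ms method
#>   <chr>        <dbl>  <dbl>   <dbl> <chr>
#> 1 N1              72    176     120 gfp_minima
#> 2 P2             176    344     256 gfp_minima
```

`run_pipeline(demo_config(), out_dir = "sep_demo", seed = 1)` runs the whole
chain (markers, windows, TANOVA/GFP/TCT, microstates) on a bundled synthetic
demo and writes every table, summary and an optional topographic figure
series to disk; rerunning with the same seed reproduces every output byte
for byte. A thin command-line front-end with `simulate` / `run-all` / `plot`
subcommands ships in `inst/cli/erptopo.R`.

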