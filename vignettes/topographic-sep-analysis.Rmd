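---
title: "Topographic analysis of sensory evoked potentials with erptopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topographic analysis of sensory evoked potentials with erptopo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erptopo)
```

## The analysis problem

Sensory evoked potentials (SEPs) are the stimulus-locked average EEG response
to repeated stimulation. Classic clinical practice reads them off one or two
derivations (e.g. the vertex channel Cz against a frontal reference Fz), but a
multichannel montage carries more: at every time point the recording is a
*scalp map*, and questions about conditions ("does stimulation frequency
change the response?") split into two distinct ones --

* does the **map strength** change (how much synchronous activity there is)?
* does the **topography** change (which configuration of sources is active)?

`erptopo` implements the standard reference-independent toolkit for these
questions -- global field power (GFP), time-wise randomization tests (the GFP
condition test, the topographic analysis of variance TANOVA, the topographic
consistency test TCT, descriptive channel t-maps), data-driven component time
windows, automated component marking, and microstate segmentation -- together
with the preprocessing needed to get from a continuous multichannel recording
(or a synthetic simulation) to condition-wise evoked maps.

## Map strength and the randomization statistics

With $u_i$ the voltage at channel $i$ of an average-referenced map of $K$
channels and $\bar u$ the channel mean, the global field power is the spatial
standard deviation with population divisor,

$$\mathrm{GFP} = \sqrt{\tfrac1K \sum_{i=1}^K (u_i - \bar u)^2},$$

equal to the root mean square of the voltages once the map is average
referenced. It is invariant to the recording reference and to adding any
constant to all channels.

All three randomization tests share one effect-size convention, the
*generalized dissimilarity*: for a factor with levels $\ell$, the effect at a
time point is $\sum_\ell \mathrm{GFP}(\bar m_\ell - \bar m)$, the summed GFP
distance of the level mean maps from the grand mean map. The tests differ in
what the "map" is and what is permuted:

* **TANOVA** normalizes every subject-condition map to unit GFP first, so only
  topography can drive the effect. Within-subject factors permute the
  condition labels independently inside each subject; between-subject factors
  permute subjects across groups; the interaction first residualizes each map
  (subtracting the subject-mean and level-mean maps, adding back the grand
  mean) and then permutes within-subject labels. This residualization is a
  convention choice -- exact permutation tests for interactions do not exist --
  and is stated here because other implementations differ.
* The **GFP test** runs the same permutation schemes on the scalar per-map GFP
  values, deliberately *without* normalization: map strength is the tested
  quantity. We do not rescale per-subject overall amplitude before the
  comparison; whether to do so is a modelling choice on which the underlying
  methodology is silent, and leaving amplitudes untouched keeps the test
  interpretable in microvolts.
* The **TCT** asks whether subjects share a topography at all: the observed
  statistic is the GFP of the mean of the subjects' unit-GFP maps, and the
  null shuffles channel values independently within each subject's map.
  A channel shuffle (rather than, say, a polarity flip) is the variant
  implemented here, and is documented because the choice is tool-internal in
  most packages.

p values use the $+1/+1$ convention, $p = (\#\{\text{null} \ge
\text{observed}\} + 1)/(n_{\mathrm{perm}} + 1)$, so $p$ is never zero and its
minimum is $1/(n_{\mathrm{perm}}+1)$; with `exact = TRUE` small within-subject
designs are enumerated completely instead of sampled. Results are
reproducible bit for bit given `(seed, n_perm)`. Near-zero-GFP maps (below
$10^{-12}$ µV) cannot be normalized; they are left out of normalization-based
statistics with a logged count rather than producing infinities. No
multiplicity correction is applied across time points: significant *periods*
are reported as such, which mirrors standard practice for these tests and is
noted as an extension point.

## Preprocessing

The preprocessing chain is deliberately plain: zero-phase Butterworth
band-pass (default 0.5--70 Hz; the 24 dB/oct slope corresponds to an analog
order of 4) plus a 2nd-order 48--52 Hz notch, average reference, spherical
spline virtual channels, epoching (default -100 to +600 ms around the
stimulus), threshold artifact rejection (default ±100 µV, with explicit
keep/reject override lists standing in for the manual half of semiautomatic
rejection), baseline correction (default -53 to -3 ms) and trial averaging.

Numerical notes. The band-pass is realized as an order-4 high-pass followed
by an order-4 low-pass, each run forward-backward over a reflection-padded
signal (padding $3 \cdot \text{order} \cdot f_s / f_{low}$ samples, capped at
the signal length): a single transfer-function band-pass with a 0.5 Hz corner
at 5 kHz sampling is numerically fragile, the cascade is not. The
forward-backward pass doubles the effective attenuation and cancels the phase
shift, matching common analyzer behaviour. Filtering is applied to the
continuous recording before epoching (the conventional order; whether to
filter continuous or epoched data is left open in much of the literature, so
the choice is flagged here). Ocular correction is out of scope; a no-op hook
position in the chain is where one would insert it.

## Electrode geometry and spherical splines

Electrodes live on a unit sphere. The package's spherical convention --
stated prominently because EEG software genuinely disagrees -- is: polar
angle `theta` measured from the vertex (Cz at 0), azimuth `phi` with +90°
anterior, 0° right, -90° posterior; Cartesian $x = \sin\theta\cos\phi$,
$y = \sin\theta\sin\phi$, $z = \cos\theta$ (+z vertex, +y nose, +x right).
Under this convention the two midline virtual SEP channels sit at
CzCPz = (11, -90) and FzFCz = (34, 90).

The bundled 64-channel extended 10--20 montage is an idealized layout: row
and column percentages map onto a square grid which the elliptical
("squircular") mapping carries onto the projection disk; the disk radius is
read as polar angle. This reproduces the conventional anchor points (Fz at
$\theta = 45$, CPz at 22.5, T7 on the equator) and keeps all 64 positions
distinct and left-right symmetric. Any real cap's digitized coordinates can
be supplied instead via `montage()` or a three-column TSV.

Interpolation uses the Perrin-type spherical spline with kernel

$$g(\cos\gamma) = \frac{1}{4\pi}\sum_{n=1}^{N}
\frac{2n+1}{[n(n+1)]^m} P_n(\cos\gamma),$$

default order $m = 4$ and degree $N = 10$, solving the standard constrained
linear system. The default ridge $\lambda = 10^{-8}$ guards against
near-duplicate electrodes; $\lambda = 0$ gives the exact interpolant (used by
the exactness tests). Accuracy is only claimed inside the electrode-covered
cap: a degree-3 harmonic sampled at the 64 electrodes is recovered to about
0.3% RMS above the equator, while extrapolation below the head is
meaningless for any spline.

## Markers, stability, and component windows

`detect_markers()` automates what a clinical reader does: within a search
window per component (defaults P1 40--90, N1 80--170, P2 185--380 ms), the
positive components are marked at the maximum and negative ones at the
minimum, ties breaking toward the earlier sample. The marking is deliberately
definition-faithful -- an inverted-polarity trace will be marked "wrongly",
and it is the stability gate's job to catch such recordings.

The gate replaces the visual "overlapping odd/even waveforms" judgement with
the Pearson correlation of the split-half averages over the post-stimulus
window; `r >= 0.5` is the package default for "stable" and is explicitly a
proxy threshold to be tuned per lab. The responder rate is the percentage of
recordings that are stable with all components marked.

Component time windows come from three methods: the group
mean ± 2 SD of individual latencies (sample SD, widened outward to the
sample grid; a zero-width window widens to ±1 sample with a warning), the
local minima of the GFP curve bracketing each GFP peak, and the inflection
points (zero crossings of the second derivative) flanking each peak, which
give nested, narrower windows. The GFP curve is smoothed with a 5 ms moving
average before the minima/derivative search -- the second derivative of raw
GFP is noise-dominated -- and inflection positions are linearly interpolated
between samples. The first GFP peak after 50 ms is labelled N1 and the next
P2; no GFP window is assigned to P1, because a weak early component need not
produce a distinct GFP peak at all.

## Microstates

`aahc()` implements atomize-and-agglomerate hierarchical clustering: every
map starts as its own cluster; repeatedly the cluster contributing least to
the global explained variance,

$$\mathrm{GEV} = \frac{\sum_t \big(\mathrm{GFP}_t \cdot r(u_t,
p_{\ell(t)})\big)^2}{\sum_t \mathrm{GFP}_t^2},$$

is dissolved and its maps reassigned to the remaining cluster with the
highest spatial correlation, after which prototypes are recomputed. The
default polarity-*sensitive* mode treats anti-correlated maps as different
states (correct for evoked data, where the N1 negativity and P2 positivity
are distinct components); polarity-*ignorant* mode uses $|r|$ with
principal-direction prototypes for resting-style use. Because the procedure
is hierarchical, one run yields the model at every class count
(`aahc_path()`), which the cross-validation exploits.

**Choosing k.** `cross_validate_k()` repeatedly splits the subjects into two
equal halves (an odd count drops one random subject per repeat), fits AAHC to
each half's grand-average series for every candidate $k$, optimally matches
the two prototype sets one-to-one and records their mean correlation; the
chosen $k$ maximizes the repeat-mean curve, ties breaking toward the smaller
$k$. This *split-half reproducibility* criterion is the design decision that
required the most care: the superficially similar alternative -- assign the
test half's time points to the training half's prototypes and average the
best-fit correlation -- is non-decreasing in $k$ by construction (a larger
prototype set can only improve a maximum), so it cannot select a model at
all. We verified this empirically; the assignment curve is still computed
and returned for reference, but selection uses reproducibility, which
genuinely peaks: above the true class count the halves split states along
their own noise and the matched correlation drops.

`assign_and_compare()` labels each subject-condition series inside an
analysis window (default 20--600 ms) by best prototype correlation -- maps
with near-zero GFP stay unassigned rather than receiving arbitrary labels --
and derives per class and condition the onset, offset, duration, mean GFP
and GFP-weighted occurrence, testing condition differences in the scalar
parameters with the same permutation schemes as the map statistics.

## The synthetic generator

`simulate_sep()` produces the ground-truth substrate every validation runs
on. Each component is a fixed spatial pattern -- a sum of von-Mises-like
lobes $\exp(\kappa(\cos\gamma - 1))$ on the sphere, mean-centered so maps are
average-reference compatible -- modulated by a Gaussian temporal pulse
(width given as FWHM; FWHM $= 2.355\,\sigma$). The defaults emulate
lower-urinary-tract SEP morphology: a weak central P1 at 60 ms, the dominant
centro-parietal N1 negativity with frontal positive counterpart at 115 ms
(subject latency jitter SD 7 ms), a broad central P2 with surrounding
negativity at 255 ms, and a slow central pre-stimulus CNV ramp that decays
over the first 100 ms post-stimulus (the component that confounds P1 unless
baselines are corrected). Amplitude multipliers fall with stimulation
frequency (1/0.8/0.6 across 0.5/1.1/1.6 Hz; the CNV falls faster because
anticipation needs slow pacing). Subjects draw lognormal amplitude factors
(σ = 0.3) and component-wise latency offsets once, shared across their
conditions; trials add noise that is white Gaussian per channel and then
smoothed across channels (~60° FWHM spherical kernel) and across time (20 ms
kernel), with both smoothing matrices variance-normalized so the nominal
noise SD (default 1 µV) is preserved per sample.

The default study layout mirrors a three-frequency, five-location design
with group sizes 20/17/19/9/18. Two defaults are deliberately *desk-scale*
choices of this package rather than properties of any recording protocol:
250 Hz sampling and 60 trials per condition keep a full simulated study in
memory; clinical recordings at 5 kHz with hundreds of sweeps are emulated by
overriding `sampling_rate` and `trials`.

What the generator does **not** emulate -- and what passing tests therefore
do not show about real data: no realistic volume-conductor forward model
(lobes are not dipole fields), no artifacts (blinks, muscle), no
heteroscedastic or non-Gaussian noise, no drifting electrode impedances, no
latency variability *within* a subject across trials. The validation results
say the algorithms are correct under their stated assumptions, not that real
LUTSEP data satisfies those assumptions.

## Validation studies and their fixed conditions

The `sim_*` functions freeze the simulation studies that both the test suite
and `scripts/acceptance.R` run; their problem sizes are package choices made
once:

* `sim_type1_rates()`: 500 null datasets (10 subjects, 2 conditions, 4
  trials, 20 channels, 51 samples, white noise), each tested at one fixed
  latency with 999 permutations. Condition labels carry no signal for
  TANOVA/GFP calibration; the TCT null additionally removes the shared
  topography (pure noise), since a common signal is exactly what the TCT
  detects.
* `sim_frequency_effect()`: 50 replicates of the headline contrast --
  multipliers 1/0.8/0.6 applied *identically to every component* so the
  topographic null holds exactly while map strength differs; n = 20
  subjects, 30 trials, 1 µV noise. Both tests are evaluated at the peak-GFP
  latency inside the N1 window (a single, data-driven time point -- testing
  the whole window would inflate the false-positive check).
* `sim_marker_recovery()`: 200 single-subject recordings at the clinical
  averaging standard of 200 sweeps; recovery is measured against each
  subject's own jittered ground-truth latency on the Cz--Fz trace, and the
  per-run evoked SNR is reported so the SNR ≥ 5 regime can be conditioned
  on.
* `sim_k_recovery()`: 25 replicate datasets of 20 subjects visiting four
  template states (amplitude 3 a.u., noise SD 1.5, boundary jitter 2
  samples), cross-validated over k = 3..8 with 10 half-splits.

## Known limitations

* **Broad components resist single-sample localization.** The
  peak-localization error of a windowed extremum scales with the noise
  derivative over the component's curvature; for the realistic 80 ms-wide P2
  this error has SD ≈ 2.4 ms even at 200 sweeps, so P2 latency is recovered
  within one 4 ms sample in only ~91--95% of runs (the N1, half as wide, is
  recovered in ~100%). Raising SNR or the sampling rate does not close the
  gap -- a finer grid tightens the one-sample tolerance faster than averaging
  shrinks the noise. Window-mean amplitudes are the robust alternative for
  broad components, which is precisely why the window methods exist.
* Interaction inference relies on the residualization convention above;
  other choices (e.g. unrestricted permutation) give different nulls.
* The TCT channel-shuffle null assumes spatially exchangeable noise under
  H0; strongly correlated noise topographies can mis-calibrate it.
* The montage is idealized; analyses of real data should load digitized
  positions.
* No duration/cluster-based control over time-wise multiple testing.

## A minimal run

```{r, eval = FALSE}
ds <- simulate_sep(
  generator_config(
    montage = standard_montage("10-20-20"),
    n_subjects = 12, frequencies = c("0.5 Hz", "1.1 Hz", "1.6 Hz"),
    trials = 30, sampling_rate = 250
  ),
  seed = 1
)
stk <- evoked_stack(ds)
tanova(stk$maps, stk$design, n_perm = 999, seed = 1, time = stk$time) |>
  significant_intervals()
```

or, end to end with all tables and figures on disk:

```{r, eval = FALSE}
run_pipeline(demo_config(), out_dir = "sep_demo", seed = 1)
```
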