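---
title: "Models and methods: circadian gating of adult emergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: circadian gating of adult emergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eclosr)
```

# The scheduling model

Adult emergence (eclosion) of holometabolous insects under constant
darkness is restricted to recurring daily gates. `eclosr` formalizes the
final stretch of metamorphosis of each animal as four times, all in
decimal hours since the start of the DD recording:

* commitment `C` — the moment the animal *could* begin the final steps,
  drawn as `pupariation offset + Normal(commit_mean_h, commit_sd_h)`;
* onset `O` — when head roughening (resorption of the molting fluid)
  actually begins;
* completion — when the animal is developmentally able to emerge,
  `O + R` with the roughening duration
  `R ~ Normal(rough_mean_h, rough_sd_h)` truncated at zero;
* emergence `E`.

Circadian time is `ct(t) = (t + ct0_offset_h) mod tau_h` and the gate is
the half-open interval `[gate_open_ct, gate_open_ct + gate_width_h)`.
Three regimes connect the four times:

* **developmental** — the clock defers the onset: `O` is the smallest time
  `>= C` such that `O + R` falls inside a gate; `E = O + R`. Readiness and
  emergence coincide, so no animal ever waits.
* **permissive** — `O = C`; an animal completing outside a gate waits for
  the next opening: `E = completion` if in gate, else the next gate
  opening.
* **arrhythmic** — no clock; `O = C`, `E = C + R`.

The half-open gate makes the tie at gate close unambiguous: a completion
exactly at `gate_open + width` is deferred. The roughening-duration draw is
independent of which gate the animal uses, encoding the empirical finding
that the duration of the final steps is constant across gates and
genotypes; the independence is what the duration-constancy test checks,
and a gate-dependent duration can be emulated simply by simulating with a
different `rough_mean_h` per group when a falsification scenario is
wanted.

Both gated regimes produce *identical* emergence-time distributions when
the dispersion parameters shrink to zero; they differ in onset times (the
permissive onset equals commitment; the developmental onset is deferred by
up to `tau - width`) and in the "ready but unemerged" fraction that
`ready_fraction()` computes — the quantity an ETH (ecdysis-triggering
hormone) injection probes, since only animals that have completed
metamorphosis respond to ETH by emerging prematurely. Under the
developmental model that fraction is structurally zero; under the
permissive model it approaches one just before a gate opens.

## Presets

The package ships three presets. Their clock periods are the published
free-running periods of the corresponding genotypes (~24 h wild-type,
~20 h for the short-period mutant); every other number is a
reconstruction — the sources give only qualitative anchors (emergence
restricted to the subjective morning, roughening spanning roughly the
final half day) — chosen once and documented here:

| parameter | wild-type | short-period | clock-less | why |
|---|---|---|---|---|
| `tau_h` | 24 | 20 | (24, unused) | published free-running periods |
| `gate_open_ct` | 0 | 0 | — | gate opens at subjective dawn |
| `gate_width_h` | 10 | 8 | — | morning emergence; same fraction of cycle |
| `commit_mean_h` | 96 | 96 | 96 | ~4 days of metamorphosis at 20 °C |
| `commit_sd_h` | 2 | 2 | 2 | between-animal developmental spread |
| `rough_mean_h` | 13 | 13 | 13 | final steps span roughly half a day |
| `rough_sd_h` | 1 | 1 | 1 | duration much less variable than onset |
| `ct0_offset_h` | 12 | 10 | — | DD starts at (subjective) lights-off |

Randomness is controlled by one root seed; each fly draws from its own
substream derived arithmetically from the seed and the fly index, so
enlarging a cohort never reshuffles earlier flies.

## The population assay

`generate_event_record()` emulates an eclosion monitor: a population
develops, each animal emerges once, and counts are accumulated in 0.5-h
half-open bins over a 7-day window beginning when the earliest cohorts
complete development. By default pupariation times are drawn uniformly
over the loading span, matching a monitor loaded with unsynchronized pupae
from bottle cultures. This default matters: with only a few discrete
synchronized collections a clock-less population is a set of narrow bumps,
not the flat record the assay actually produces. The synchronized
ZT6/12/18 collection protocol used in single-animal imaging remains
available through `pupariation_zts`.

# The synthetic filming rig

`render_series()` renders 8-bit grayscale frames (default 200 x 200 px,
origin top-left) at the rig cadence of 0.2 h — the stage passes each
animal 5 times per hour, giving the 12-min sampling interval — with a
burst of images per pass, each independently jittered by an integer
translation of up to `jitter_px` per axis. The appearance model:

* a puparium body ellipse on a dark background;
* a head reflection that is one smooth, soft-edged bright ellipse before
  roughening onset; between onset and emergence it splits into
  `m(u) = round(1 + (K - 1) u)` patches (`u` the progress
  `(t - O)/(E - O)`, `K = frag_k = 12`), rendered as the Voronoi cells of
  per-animal seed points separated by dark cracks carved along the cell
  boundaries, with radial boundary wobble growing as `sqrt(u)`;
* a wing region whose mean intensity ramps linearly downward (darker
  wings, smaller values) over `wing_ramp_dur_h`;
* at emergence, an abrupt switch to the empty-puparium appearance: the
  wing region brightens, the head patchiness disappears;
* additive Gaussian pixel noise (`noise_sd = 2`), a slow 2% sinusoidal
  illumination drift, and the burst jitter above.

Two renderer choices deserve explanation. The seed points of the
fragmentation keep a minimum separation (scaled to the per-seed share of
the ellipse area and to the crack width); without it, two nearby seeds turn
the entire region between them into one wide dark swath, and the roughness
indices fluctuate non-monotonically as patches appear. And the crack
network gains edges monotonically because the seed list is nested — patch
`m+1` is carved out of existing cells. Together these give the generator
its contract: on noise-free renders both roughness indices rise
monotonically through fragmentation (Spearman rho > 0.9 on `[O, E)`), and
with default noise the full pipeline recovers onsets within ±1 h and
emergences within one cadence step for the large majority of animals.

What the generator does **not** emulate: optics (no point-spread function
or pixel scale — the geometry is nominal), occlusions or neighboring
animals, rotation or scale changes, non-translational deformation, and any
light-driven behavior (the rig films under far-red light precisely so
that the clock is blind to it). Passing the round-trip tests therefore
shows that the measurement chain is correct on data obeying the appearance
model, not that it is robust to everything real footage can contain.

# Imaging

Burst selection takes, per pass, the frame whose intensity-weighted
centroid of supra-Otsu pixels lies nearest the frame center (ties by
lowest burst index) — "most centered" is not defined more precisely by the
assay, and the centroid rule is parameter-free. Stabilization registers
each frame to its predecessor by the integer translation (within
`max_shift_px = 5`) maximizing normalized cross-correlation on the
overlap, preferring the smallest displacement on ties, accumulating shifts
so every frame is registered to the first, and flagging frames whose best
shift sits on the search bound. Subpixel registration is deliberately out
of scope: the emulated jitter is whole-pixel. Degenerate constant frames
(zero variance, correlation undefined) keep a zero shift.

# Markers

The head-roughness index has two readings of "the SD between each pixel
and those immediately surrounding it": the default takes, for every
interior ROI pixel, the population SD of the nine intensities of its 3x3
neighborhood (center included) — a standard local-texture operator with
sane degenerate behavior — and sums over pixels; `mode = "differences"`
instead takes the population SD of the eight signed neighbor-minus-center
differences. Both are invariant to adding a constant to all intensities
and scale linearly with intensity scaling.

The "Borders" index segments 8-connected components of pixels at or above
a threshold frozen per animal (Otsu on the head ROI of the first frame —
per-frame thresholds would confound fragmentation with illumination
drift) and sums crack-edge perimeters: the number of pixel edges adjoining
a sub-threshold or out-of-ROI pixel. Crack-edge counting (rather than
boundary-pixel counting) makes the perimeter additive under patch
splitting, which is the property that makes the index grow as the
reflection fragments.

## Onset detection

The onset detector high-pass filters the trace (value minus a centered
moving average over `window_h = 6` h, windows truncated at the record
ends), estimates baseline noise as the MAD over the first quarter of the
record (falling back to the global MAD when the baseline is exactly
constant), and looks for the first excursion of the filtered *magnitude*
above `k_mad = 4` MADs sustained for `min_run = 5` samples (1 h); the
onset is the first local extremum of the lightly smoothed magnitude inside
that excursion. The magnitude-and-extremum form, rather than a first
positive crossing, is forced by the filter's geometry: a centered-window
high-pass of a flat-then-rising trace is *negative* around the corner
(the window is pulled up by future values) and near zero on the rise
itself, so a positive-crossing rule misses or badly delays exactly the
feature being sought, whereas the magnitude peaks exactly at the corner —
on an ideal flat-then-ramp trace the detector returns the corner time to
within a sample. The defaults were tuned on rendered fixtures and are
exposed as arguments; samples after the detected emergence are excluded
before filtering, and a trace with no sustained excursion returns `NA`
rather than an error.

Emergence is the largest single-step difference of the channel's expected
sign (wing: positive; roughness: negative), accepted only if it exceeds
`k_jump = 6` robust SDs (MAD x 1.4826) of all step differences; a
numerically constant-slope ramp (MAD ~ 0) falls back to the median step
size so that steady trends never register as jumps.

Group comparisons use the standard fixed-effects one-way ANOVA
sum-of-squares decomposition with Tukey HSD pairwise comparisons at
alpha = 0.05 and a compact-letter display built from the pairwise
significance matrix.

# Population rhythm statistics

The autocorrelogram uses the biased, non-circular estimator
`r(l) = sum_t (x_t - xbar)(x_{t+l} - xbar) / sum_t (x_t - xbar)^2` — the
estimator whose decaying peak envelope the rhythmicity-index convention
assumes; an unbiased estimator would inflate long-lag coefficients. A
record with zero count variance is a hard error.

Peak finding smooths the correlogram over 3 lags, takes local maxima
excluding lag 0, requires a prominence of at least 0.02 measured against
the nearest strictly-higher points (narrow one-bin peaks otherwise erase
each other via their twin smoothed maxima), refines each peak to the raw
coefficient maximum within the smoothing window (a one-bin spike's
smoothed maximum can sit one lag off the spike), and requires the raw
coefficient at the peak to clear the white-noise 95% significance line
`1.96/sqrt(N)` — the line conventionally drawn on correlograms; without
it, noise bumps of |r| ~ 0.03 at N = 336 bins qualify as "first peak" and
corrupt both the period and the RI.

The period estimate is the lag of the first peak; the RI is the
coefficient at the second non-zero-lag peak (the "third peak" when lag 0
is counted first, per the convention of correlogram-based RI analysis;
`ri_peak` switches it). Classification is exactly the quoted rule:
RI > 0.3 rhythmic, 0.1 <= RI <= 0.3 weakly rhythmic, RI < 0.1 arrhythmic.
A record is flagged "obviously aperiodic" — and classified arrhythmic with
`ri = NA` — when fewer than two significant peaks exist or when the second
peak is not within ±25% of twice the first peak's lag: in a genuinely
periodic correlogram the peaks sit at period multiples, and without the
harmonic check a pair of unrelated noise bumps above the significance line
would earn a white-noise record a "weakly rhythmic" label.

The valley criterion serves records too short for correlogram analysis:
counts are smoothed with a 3-h moving average; valleys are maximal runs of
at least 6 h in which the smoothed counts stay at or below the 20th
percentile of the smoothed values between the first and last nonzero
bins; the criterion passes when at least two valley centers exist and the
median spacing of consecutive centers is within ±4 h of the expected
period. The duration floor and the median-spacing rule are both needed:
any record has bins below its own 20th percentile, so without them brief
noise dips in an arrhythmic record count as valleys and some pair of them
is always spaced about a day apart. The `<=` comparison keeps the long
empty stretches of a strongly gated record — where well over a fifth of
the span is exactly zero — counting as valleys.

# Numerical conventions and degenerate inputs

* Times are decimal hours since DD start; ZT/CT conversions always carry
  an explicit offset. Bins and gates are half-open; events and completions
  on an edge go right.
* Images are matrices of intensities in [0, 255]; pixel coordinates are
  1-based (row, col) in the R API with the origin at the top-left.
* Truncated-normal draws reject up to 1000 times before failing loudly.
* `detect_onset`/`detect_emergence` return `NA` for "nothing found",
  reserving errors for malformed input (traces under 3 samples, ROIs
  smaller than 3x3).
* Stabilization ties prefer the smallest displacement; burst-selection
  ties prefer the lowest burst index.

# Problem sizes

The test suite and the acceptance script simulate 300-fly, 7-day records
at 0.5-h bins (10 seeds for across-seed medians and means), cohorts of
15-120 flies for the scheduling properties, and image round-trips of nine
animals rendered at 120 x 120 px with 5-image bursts over ~35-h spans —
sizes at which every property under test is already stable while the whole
suite runs in a few minutes on one CPU.

# Known limitations

* The onset detector assumes an established flat baseline (about a
  quarter of the record) before roughening starts; records that begin
  mid-roughening are flagged unreliable.
* The RI peak-counting convention differs between analysis packages in
  the field; ours (period at the first significant peak, RI at the
  second) is documented above and switchable, and the 0.3/0.1 cutoffs
  were verified to behave sensibly under it, but RI values are only
  comparable within one convention.
* The renderer's appearance model is deliberately minimal; see the
  synthetic-rig section for what passing its round-trip tests does and
  does not establish about real footage.
* Entrainment is not modeled: records start in DD with a phase given by
  `ct0_offset_h`, and light-driven responses (e.g. lights-on bursts) are
  out of scope.
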