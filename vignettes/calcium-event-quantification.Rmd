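---
title: "Quiescence-based quantification of urothelial Ca²⁺ events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quiescence-based quantification of urothelial Ca²⁺ events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caquant)
```

## The measurement problem

Intact urothelial sheets loaded with a Ca²⁺ indicator show spontaneous and
evoked intensity transients. Two properties of these preparations defeat the
habitual analyses. Dye loading is uneven — neighbouring cells can differ
several-fold in baseline brightness — so ΔF/F₀ understates events in bright
cells and overstates them in dim ones. And the cells are ovoid, so the
line-profile ST-map averaging common in smooth-muscle work has no natural
axis. `caquant` instead standardizes each pixel against the variability of
its own inactive ("quiescent") periods, yielding a per-pixel Z-score in
which a single threshold is meaningful across the whole field of view.

## Pipeline and assumptions

The analysis chain is: (optional) rigid stabilization → (optional)
debleaching → temporal box averaging → spatial Gaussian smoothing → pixel
binning → quiescence model → Z-scores → thresholding and particle filter →
per-frame particles → overlap tracking → ST objects → Zum²s output. Every
step preserves frame count, shape and calibration, and logs itself in the
movie's provenance so a chain can be replayed bit for bit
(`apply_chain()`).

Key parameters, with defaults and rationale:

| parameter | default | units | role |
|---|---|---|---|
| `pixel_size_um` | 0.689 | μm/px | native calibration of the target recordings |
| `frame_interval_s` | 0.625 | s | ditto; the acquisition hardware also reports a 16 Hz burst rate, but the analysis timebase is 0.625 s and both are parameters |
| `halfwidth` (temporal) | 2 | frames | ±2-frame box, a 3.125 s ("3.13 s") window |
| `kernel`, `sd` (spatial) | 5, 1.0 | px | light smoothing that does not bridge cells |
| `bin_size` | 10 | px | 6.89 μm bins, matching ovoid cell scale |
| `quiescence_fraction` | 0.20 | — | dimmest 20% of each pixel's samples as the conservative noise floor |
| `sd_multiplier` | 11.0 | — | quiescent-period cut in SDqmin units |
| `z_threshold` | 2.7 | Zscr | active-event threshold, inclusive |
| `min_particle_px` | 3 | binned px | per-frame components this small are noise |

The quiescence model assumes each pixel is inactive for at least the
quiescence fraction of the recording; the synthetic generator's default
event loads respect this by a wide margin, and pixels that violate the
model's preconditions (constant dim samples, an empty quiescent set, or
zero quiescent SD) are flagged invalid and excluded from every downstream
map rather than guessed at.

## Numerical and design choices

Several points are under-determined by the method's verbal description;
the package fixes them as follows and exposes each as configuration.

**Noise floor per pixel, not per frame.** The "dimmest 20%" is read as the
dimmest 20% of *time samples at each pixel*: the standardization
(I − AVGq)/SDq requires a per-pixel noise estimate, and a per-frame reading
would mix bright and dim cells.

**Anchoring the 11 · SDqmin cut.** Intensities carry an arbitrary offset, so
a bare multiple of an SD is not a usable cut. The cut is anchored at the
dim-sample mean: quiescent ⇔ I < AVGmin + 11.0 · SDqmin (`anchor =
"avgmin"`; `"none"` gives the un-anchored comparison for data that are
already offset-free). For sample sizes up to several hundred frames the
dim set itself always falls below this cut (Samuelson's bound: no sample
sits more than (n−1)/√n ≈ 10 SDs from the mean of n = 100), so the
quiescent mask provably covers at least the assumed fraction.

**Ties.** Samples tied with the 20th-percentile boundary value are all
included in the dim set — deterministic and order-independent.

**Connectivity.** Within a frame, 4-connectivity ("contiguous" read
conservatively); across consecutive frames, one shared bin links particles;
the transitive closure forms the object, so merging or splitting blobs
remain a single event. This makes the chain exactly equivalent to 3-D
connected components (6-connectivity in row × col × frame) on the
thresholded, particle-filtered mask — an equivalence the tests assert
against an independent brute-force flood fill. 8-connectivity is available
as an option.

**Particle filter domain.** The ≤ 3-pixel filter runs per frame in binned
space, before tracking, mirroring its position in the chain (after
binning/thresholding, before coalescing).

**Output integral.** Zum²s integrates the *instantaneous* per-voxel Z over
an object (Σ Z · bin area · frame interval), not a per-object peak times a
bounding area: "pixels × size × intensity × duration" is read as a
voxel-wise integral, which makes the FOV total additive over objects and
exactly equal to the suprathreshold voxel sum (a conservation property the
tests check to 1e−6).

**Debleaching.** The exponential model fits log frame means by least
squares and divides by the fitted relative decay; sparse events perturb
frame means negligibly, and if the fit fails or finds no decay the
frame-mean normalization (every frame rescaled to the first frame's mean)
is used instead. Both stabilization and debleaching default to *off*:
the synthetic recordings are drift- and bleach-free unless asked otherwise.

**Temporal-filter broadening.** A ±h-frame box filter spreads an event's
suprathreshold support by exactly h frames per side whenever the plateau
Z-score is well above threshold — at the study's event amplitude (8× the
per-pixel noise SD) the binned-scale contrast is two orders of magnitude
above the 2.7 cut, so this broadening is deterministic, not noise. Recovery
assessments therefore compare measured frame spans against the ground-truth
support plus 2·halfwidth; residual deviations reflect genuine detection
error.

## What the generator emulates — and what it does not

`generate_movie()` renders: random non-overlapping ellipses with axes
10–30 μm (ovoid cells); per-cell log-normal baseline brightness on a dim
background (uneven dye loading); Gaussian noise with SD =
`noise_sd`·√(I/`noise_ref`), the variance-scaling of shot noise without
integer-count bookkeeping; optional exponential bleaching (events bleach
with the rest of the dye) and rigid integer drift; and injected events
that raise their footprint by `amplitude` multiples of the local per-pixel
quiescent noise SD, with a 1-frame linear rise and 2-frame linear decay
*inside* the stated duration (so the rendered support equals the
ground-truth duration and amplitude-recovery checks read the plateau).
Event hosts are placed first, large enough for the requested footprint and
mutually separated, so planned event sets are always realizable; onsets are
uniform over the usable frame range, and events sharing pixels at
overlapping times are rejected to keep ground truth unambiguous.

It deliberately does **not** model IP₃/ryanodine-receptor kinetics, optical
point-spread, cell-to-cell waves, or inflammation mechanistically —
treatment groups are parameter sets, nothing more. Passing tests therefore
demonstrate that the *measurement chain* recovers known signals under
realistic loading, noise and geometry; they say nothing about biological
fidelity of real recordings, where event kinetics, spatial correlation of
noise and focal drift are richer.

`generate_voiding_session()` draws a renewal process of gamma inter-void
intervals and i.i.d. positive-truncated normal void masses. The default
shape 1 (exponential) keeps renewal expectations exact — the expected void
count over duration T is simply T/μ, which the tests verify over 500
seeded sessions; for more regular rodent-like rhythms a larger shape
(cv = 1/√shape) is a parameter, and the demonstration cohort in
`analysis/04_voiding_analysis.R` uses shape 4.

**Estimating the mean IMI from finite sessions.** The mean of *all*
complete intervals in a fixed 24-h window is biased low: the interval
straddling the session end is length-biased long and always excluded, which
at a 120-min exponential mean costs roughly 10 minutes — far more than the
estimator's standard error at 200 sessions. The recovery assessment
therefore pools the first five intervals of each session; each of those is
observed with probability > 0.99 (P(S₅ > 24 h) < 0.01 for the gamma sum),
making the pooled mean effectively unbiased without touching the generator.

**Voiding windows.** Windows are half-open [k·4 h, (k+1)·4 h) — a void at
exactly 4 h belongs to 4–8 h — and each inter-void interval is attributed
to the window containing its *later* void, keeping windows causal. The
water-intake exclusion is strict: over 20% above baseline excludes, exactly
20% keeps. Cumulative balance traces are segmented by increments of at
least `min_void_g` (default 0.1 g), a documented surrogate for whatever the
cage software does, since balance jitter and the minimum detectable void
are hardware-specific.

**Statistics.** Cohen's *d* defaults to the difference-score (paired) form,
matching the within-subject designs these measurements serve; the pooled
form is available and both are labelled in the output. The paired t-test is
the classical one (delegated to `stats::t.test` behind the module surface);
zero-variance differences raise an error rather than returning t = 0, since
a degenerate denominator is a data problem, not a finding. Mixed-model
repeated-measures ANOVA is intentionally out of scope: the module prepares
its square-root / natural-log transformed inputs, and the fit itself
belongs to standard software.

## Problem sizes

The full-scale recovery assessments (tests and `scripts/acceptance.R`) use
the study's native geometry: a 510 × 510 px, 500-frame sheet (an exact
multiple of the 10-px bin) with 20 events of amplitude 8, 8-frame support
and 8-bin footprints, plus a matched no-event control; oracle-equivalence
checks use 50 random movies of at most 12 × 12 × 20 bins; voiding recovery
uses 200 sessions. Unit tests run the same code on smaller frames so the
whole suite stays quick.

## Known limitations

- Stabilization is integer-pixel and rigid; sub-pixel or non-rigid motion
  is out of scope, and a shift beyond `max_shift_px` leaves the frame in
  place with a warning rather than extrapolating.
- The quiescence model needs enough frames (≥ 10, realistically hundreds)
  and fails gracefully — but uninformatively — on pixels that are never
  quiet; such pixels are reported, not rescued.
- Zum²s is a field-of-view aggregate; per-cell attribution of events is
  deliberately not attempted (no segmentation of ovoid cells is performed).
- The generator's event kinetics are piecewise-linear by design, chosen to
  be analytically checkable rather than biophysically detailed.
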