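---
title: "Quantifying retinal movements under a fixed compound-eye lens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal movements under a fixed compound-eye lens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyretina)
```

## The measurement problem

Flies carry muscles that translate the retina beneath the rigid lens array
of the compound eye. The retinal position of one eye can be read out
optically through the *deep pseudopupil*: an enlarged virtual image of a
single ommatidium's photoreceptor array that forms at the eye's center of
curvature and appears in infrared video as seven bright dots (a central dot
ringed by a hexagon). Because the lenses stay put while the retina moves,
the pseudopupil's displacement is a direct proxy for retinal displacement,
and dividing pixel displacements by the pixel distance between neighboring
dots converts them into units of inter-photoreceptor spacings — hence into
degrees once one spacing is equated with the inter-ommatidial angle
$\Delta\phi$ (default 5°, configurable for higher-acuity species).

`flyretina` implements that readout and everything downstream of it:
saccade detection and main-sequence fits, optokinetic gain and optomotor
indices, binocular vergence metrics around gap-crossing events, angular
receptive-field shift estimation from bar-sweep electrophysiology, and a
correlator model of spatial aliasing. A synthetic-data generator produces
every input with recorded ground truth, so each stage is validated by
parameter recovery rather than by eye.

## Synthetic data: what is emulated, and what is not

The generators emulate the *structure* of the recordings, not their optics:

* `gen_frames()` renders seven isotropic Gaussian dots (hexagon + center)
  whose common centroid follows a ground-truth trajectory, over a flat
  background with additive Gaussian pixel noise. There is no simulation of
  virtual-image formation, illumination gradients, or occlusion.
* `gen_okr_trace()` produces smooth tracking at
  $v = -\,\mathrm{dir}\cdot g \cdot v_{stim}$ (the retina moves against the
  stimulus: the lenses form an inverted image, so only a counter-directed
  retinal translation slows image motion), interrupted by counter-saccades
  drawn as a censored Poisson process. Saccade waveforms are minimum-jerk
  steps. Because a minimum-jerk step of amplitude $A$ and duration $d$ has
  peak velocity $1.875\,A/d$, honoring a main-sequence law
  $v_{peak} = k|A|^b$ fixes the duration at $d = 1.875|A|^{1-b}/k$ — about
  21–31 ms over the default amplitude range, consistent with the
  fast-but-brief character of retinal saccades.
* `gen_gap_session()` builds a wheel-position trace crossing a detection
  threshold exactly the configured number of times and locks a
  mirror-symmetric (convergent) raised-cosine vergence pulse to every
  crossing: left-eye $x$ up, right-eye $x$ down by the same amplitude.
* `gen_bar_sweep()` and `gen_flash_grid()` sample a Gaussian receptive
  field; a response latency enters the sweep curves as a direction-signed
  screen offset of $v_{bar}\cdot\tau_{lat}$, which is the bias that
  direction-combining must cancel.
* `gen_crossing_trajectories()` draws per-crossing minimum heights from a
  Gaussian group distribution and wraps them in smooth descend-ascend
  paths.

Noise is additive and Gaussian everywhere (positions and pixel
intensities). Consequently, passing tests demonstrate correct *parameter
recovery under the stated noise model*; they do not certify performance
under real-world nuisances such as illumination drift, partial pseudopupil
occlusion, non-stationary noise, or body-movement artifacts.

Default study conditions, chosen once: sample rate 100 Hz; trace noise SD
0.02°; stimulus 15 °/s; tracking gain 0.2 (so the default initial velocity
is 3 °/s); counter-saccade rate 0.2 s⁻¹ with amplitudes uniform on
0.5–3°; main sequence $k = 90$ °/s, $b = 0.8$ (placing a 2.6° saccade near
195 °/s peak velocity); wheel speed 3.5 °/s, which with two gaps per
revolution yields one forward crossing per ~51 s; vergence pulse 1 s wide,
2° amplitude; gap-crossing height groups at −1.0 and −1.4 mm with SD
0.3 mm, 20 flies × 10 crossings. Where a test must resolve the 15–30 ms
saccade waveform itself (recall/precision, main-sequence exponents), the
generator is run at 500–2000 Hz — the camera rate is an explicit free
parameter of the synthetic setup — with a correspondingly short
differentiator window (5 samples).

## Tracking and calibration

`detect_pseudopupil()` thresholds each frame at the background median plus
$k\cdot\mathrm{MAD}$ (default $k = 6$). The robust threshold degenerates on
noiseless or near-noiseless backgrounds (MAD → 0) and can fail to separate
dots from background; in both cases the Otsu threshold is used instead.
Supra-threshold pixels are grouped into connected components, ranked by
integrated intensity, and at most seven are retained; the retinal position
is the intensity-weighted centroid of the retained pixels (weights are
intensities above the background median), which is sub-pixel by
construction. Internally pixel coordinates are image-style (origin top-left,
y down); `to_degrees()` flips to the head-centered convention (+x toward
the fly's right, +y up) used by every analysis function.

`estimate_spacing()` identifies the central dot (nearest the cluster
centroid) and returns the median distance to the other dots — the pixel
equivalent of one spacing. The calibration then maps a 36 px (three
spacing) excursion to exactly 15°.

Degenerate inputs: a flat frame raises a `fr_no_pupil` condition; more
components than `max_components` raises `fr_ambiguous_scene`; frames that
fail inside a stack are flagged and filled by a hold-last (default) or gap
policy, never silently dropped.

## Kinematics

Velocities come from a Savitzky–Golay differentiator (local quadratic fit)
with odd point-reflection padding at the endpoints, which keeps linear
trends exact everywhere. The default window is ~15 ms at the trace rate
(minimum 5 samples).

`detect_saccades()` is a threshold-crossing detector on the 2-D speed
trace (default threshold 15 °/s): events extend outward until speed falls
below a hysteresis bound, and events closer than 100 ms merge. Two
numerical choices matter:

* The hysteresis bound is threshold/3 *plus the trace's median speed*. A
  purely fixed bound is swallowed by the slow phase at high gain (0.5 × 15
  °/s = 7.5 °/s exceeds 5 °/s), which would fuse the whole trace into one
  event. The median speed is a robust slow-phase estimate because saccades
  occupy a tiny fraction of samples. Expansion is additionally capped at
  0.15 s per side.
* Amplitudes are median positions in 50 ms windows after offset minus
  before onset, minus the local pre-onset drift (estimated by a line fit
  over up to 200 ms) times the window separation. Without the drift term,
  every amplitude would absorb ~80 ms of slow-phase displacement, which at
  3 °/s is a 0.24° bias — fatal for sub-degree saccades.

`main_sequence()` fits $\log v_{peak}$ on $\log|A|$ by least squares and
refuses fewer than three saccades or zero amplitude variance.
`desaccade()` bridges each saccade linearly and subtracts its step from all
later samples; `initial_velocity()` fits a robust line (M-estimation) to
the desaccaded position over 0.5 s from stimulus onset, and `okr_gain()`
reports $|v|/v_{stim}$ with the response sign kept separate. The optomotor
index is the net desaccaded displacement over the total absolute
displacement per motion epoch, signed so that proper tracking scores +1;
this concrete formula is this package's construction (the quantity is
conventionally defined per-study), and it is exposed as such.

## Binocular analysis

The vergence metric is $V(t) = -(x_L - b_L)(x_R - b_R)$ in deg²: positive
when the eyes move oppositely (convergence/divergence), negative for
conjugate shifts. Baselines $b$ are either whole-trace means (display) or
per-event means over $[-2.5, -1.5]$ s before each event (default for event
analysis, matching the vergence baseline window below).

`detect_crossings()` finds threshold crossings of the unwrapped wheel
angle with a Schmitt trigger; the threshold repeats every 180° because the
wheel carries two gaps per half revolution. The detector starts armed on
the side the trace begins on; re-arming requires a full retreat through
the hysteresis band, so noise dithering across the threshold yields one
event. Same-direction events closer than 10 s are dropped so that ±5 s
analysis windows never overlap.

`triggered_average()` aligns snippets at event times (events whose window
leaves the trace are excluded and counted) and averages per lag.
`event_deltas()` applies fixed windows: position-like channels use
mean over $[+2, +5]$ s minus mean over $[-5, -2]$ s; the vergence channel
uses mean over $[-0.5, +0.5]$ s minus mean over $[-2.5, -1.5]$ s.
`deltas_ttest()` runs two-sided one-sample t-tests with a Bonferroni
family of 9 by default. Crossing heights are summarized per fly by the
median over crossings of each path's minimum y, and groups are compared
with a two-sided Welch test; crossing rates are forward counts per epoch
duration with a paired t-test across flies between lighting conditions.

## Receptive-field shifts

Flash maps subtract a 100 ms pre-flash baseline from a 200 ms response
window (the flash is 100 ms; windows are configurable and validated
against overlapping the flash onset). `estimate_shift()` maximizes the
normalized cross-correlation between two tuning curves over a ±20° lag
range at the data's own spacing, then refines the peak by parabolic
interpolation — chosen over spline refinement for determinism. Formalizing
the curve match as normalized cross-correlation (rather than a visual
match) is a design decision; normalization makes the estimate invariant to
peak-normalizing either curve. `combine_directions()` averages the two
directions' condition shifts, cancelling latency bias, and additionally
reports the observable latency offset (half the direction-to-direction
displacement within one condition), which equals $v_{bar}\cdot\tau_{lat}$.

## The aliasing model

A 1-D array of receptors spaced $\Delta\phi$ apart feeds nearest-neighbor
delay-and-multiply correlator pairs with opponent subtraction; the delay
arm is a first-order low-pass with $\tau = 50$ ms. For a drifting
sinusoidal grating the time-averaged opponent output is

$$\bar R \;=\; \mathrm{dir}\cdot C^2\, G\,\sin\delta\,\sin\!\big(2\pi\Delta\phi/\lambda\big),$$

with $G$, $\delta$ the filter gain and phase lag at the drift frequency.
The spatial factor alone carries the science: the response is veridical
for $\lambda > 2\Delta\phi$, zero at the cut-off
$\lambda_L = 2\Delta\phi$, and inverted on
$(\Delta\phi,\, 2\Delta\phi)$ — for 5° sampling, the 5–10° band. $\tau$
and the optional Gaussian acceptance-angle blur scale the magnitude but
never move the zero crossings, which is what the package's headline
quantities use. The simulation integrates the exact exponential
discretization of the low-pass at 500 samples per period and averages over
an integer number of periods after an 8τ warm-up; with `normalize = TRUE`
the output is divided by the realized discrete-filter envelope
$C^2 G\sin\delta$, so the simulated curve matches
$\sin(2\pi\Delta\phi/\lambda)$ to near machine precision and the
normalized response at $\lambda = 4\Delta\phi$ is +1. `inversion_band()`
locates the negative run adjacent to the cut-off on a wavelength grid and
refines both edges by root bracketing (`uniroot`).

One sign-pattern remark: at $\Delta\phi = 5°$, $\lambda = 3°$ lies in the
*second* aliasing lobe ($\sin(10\pi/3) < 0$); the first veridical window
below the main band is $10/3 < \lambda < 5$, e.g. $\lambda = 4°$.

## Problem sizes and reproducibility

All validation runs at desk scale: 600-frame stacks at 128×128 px over 10
seeds for tracking (RMS < 0.1 px); ≥200 generated saccades for
recall/precision ≥ 0.95; 120 s traces for main-sequence fits; 8-crossing
sessions for vergence; 100 seeded replicates of the 20-fly × 10-crossing
crossing-height comparison. Every generator takes a single integer seed
and restores the caller's RNG state, so identical parameters give
bit-identical outputs. `run_pipeline()` embeds the resolved configuration
and package version in its report; the wall-clock timestamp is kept
outside the comparable payload.

## Known limitations

* The pixel→degree conversion assumes one dot spacing equals one
  inter-ommatidial angle; both numbers are configurable but the proxy
  itself is an approximation to a full optical calibration.
* Saccade detection assumes saccades are fast relative to both the smooth
  phase and the sampling interval; at 100 Hz, sub-degree saccades sit at
  the edge of detectability (their waveforms span 2–3 samples).
* The optomotor-index formula is package-defined (see above).
* The aliasing model is a minimal correlator: no optic-lobe dynamics, no
  contrast adaptation, and it is not fitted to behavioral magnitudes —
  only the sign structure over wavelength is claimed.
* Torsional eye movements, head/body compensation, and real-time tracking
  are out of scope.
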