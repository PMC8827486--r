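---
title: "Detecting and classifying traveling waves on microelectrode arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying traveling waves on microelectrode arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cortical oscillations recorded on a dense microelectrode grid are rarely
synchronous across the array. Often the phase of the oscillation advances
systematically across the cortical surface, so the amplitude peak appears
to travel — a *traveling wave*. wavemap analyses this spatial structure in
local field potentials (LFPs) from an 8x8 "Utah" array (400 um pitch,
1 kHz sampling): it extracts band-limited instantaneous phase maps,
detects planar traveling waves, distinguishes planar from rotating waves,
estimates propagation speed, and quantifies how task epochs of a
working-memory trial modulate wave incidence and direction.

Everything downstream of preprocessing operates on the **phase map**: the
64 instantaneous phases at one sample. The package's phase convention is
that 0 marks the oscillation peak and positive phases are *approaching*
the peak (the negated argument of the analytic signal). Under this
convention the phase increases along the direction of travel, which fixes
the signs of all correlations below.

Grid coordinates are `(x, y)` with `x` the column (left to right) and `y`
the row counted from the top — the orientation in which array data are
displayed. Azimuths are measured counterclockwise on screen, so 45
degrees points from the bottom-left corner to the top-right corner.

## Preprocessing

1. **Band-pass filtering.** 4th-order Butterworth applied forward and
   reverse (`filtfilt`), so the filter is zero-phase and oscillation
   peaks are not displaced in time. Bands default to theta (4–8), alpha
   (8–12), beta (12–30) and gamma (40–120 Hz). Signals are padded by odd
   reflection (about three low-edge periods) before filtering; the
   package does not re-apply any acquisition-chain filters, which are
   recorded as metadata only.
2. **Missing electrodes.** Arrays occasionally have a few dead sites.
   Each missing site is filled per sample with the mean of its available
   4-neighbours — the simplest linear scheme on a lattice, exact for
   planar gradients at interior sites. More than half the grid missing is
   refused.
3. **Analytic signal.** The Hilbert transform (computed by FFT) gives
   each site's instantaneous phase and envelope. Zero-envelope samples
   have undefined phase and are returned as `NA` rather than erroring.

`morlet_power()` supports band-power summaries with complex Morlet
wavelets; the width is 7 cycles, a conventional compromise between time
and frequency resolution, and trial power is expressed as change from the
pre-fixation baseline.

## Planar wave detection (quadrant distance maps)

A planar wave crossing the array produces a phase gradient along its
direction. The detector correlates the phase map with Euclidean distance
maps built per quadrant (the four 4x4 blocks of the grid): for each of
the 12 ordered quadrant pairs, the source quadrant's map increases
towards its outer edge against the travel direction and the destination
quadrant's along it, so a wave passing from source to destination
correlates negatively with the first and positively with the second. Both
conditions must hold at once. One traversal can legitimately fire several
direction labels.

Only sites with phase in `[0, pi)` (approaching the peak) enter the
correlations, with at least 6 qualifying sites per quadrant. This
restriction separates consecutive traversals — each positive half-cycle
is one wave — at the cost of limiting the method to wavelengths long
relative to the array, which is why the property tests only require
detection for wavelengths of at least twice the array width.

Events are counted with a 20 ms window sliding one sample at a time (20
ms resolves anything below 50 Hz); a wave event is a maximal run of
contiguous active windows, so two traversals separated by a
sub-threshold gap register as two events.

**Thresholds.** Chance levels come from spatial shuffling: phase values
are permuted uniformly across sites (10,000 draws) and the 99th
percentile of the absolute correlation is taken. For full-array
statistics — Pearson correlation against a full-array distance map, or
the circular-circular correlation against a rotation map (63–64 sites) —
this percentile is approximately 0.3, the operational chance threshold
used for every rho_c analysis. The per-quadrant detection statistic uses
only up to 16 (masked) sites, so its own shuffling null is much higher
(about 0.85); the detector is calibrated against *that* null rather than
against 0.3, otherwise several percent of random maps would trigger each
direction label. This is the one place where a single global threshold
cannot serve both statistic families honestly.

## Circular-circular correlation and the three-point fingerprint

Wave types are classified with circular statistics on the whole array.
The template is a **rotation map**: the polar angle of every site about
an origin. For a phase map \(\varphi\) and rotation map \(\theta\),

\[
\rho_c =
\frac{\sum_{ab} \sin(\varphi_{ab}-\varphi_m)\,\sin(\theta_{ab}-\theta_m)}
{\sqrt{\sum_{ab}\sin^2(\varphi_{ab}-\varphi_m)\,
       \sum_{ab}\sin^2(\theta_{ab}-\theta_m)}},
\qquad \theta_m = \mathrm{Arg}\textstyle\sum_{ab} e^{i\theta_{ab}},
\]

the Fisher–Lee circular correlation: subtract the circular mean, sine
transform, correlate. It is bounded in \([-1, 1]\), invariant to adding a
constant phase, and flips sign when the map is negated. (We use the
standard denominator with the square root of the product of the two sine
sums; it is the form that is bounded and reproduces the worked-example
values below.)

Each rotation map has a **net direction**: planar waves towards it give
\(\rho_c > 0\), away give \(\rho_c < 0\), and waves along the orthogonal
**bisecting axis** fall inside the chance zone \((-0.3, 0.3)\). The
package computes the net direction operationally, as the
correlation-weighted resultant over planar probe directions, which is
sign-consistent with `circ_corr()` by construction; a naive mean gradient
of the sine-transformed map can point away from the direction that
actually maximizes the correlation, because boundary terms dominate on an
8x8 grid.

A single origin cannot distinguish a planar wave from a rotating wave
with the same net direction, so three origins are combined into a
**fingerprint**: `(4,4)` near the array centre (net direction along the
bottom-left to top-right diagonal), `(1,4)` mid-left (vertical net
direction), and `(4,1)` mid-top (horizontal). For the canonical
long-wavelength diagonal planar wave the fingerprint is approximately
(0.90, 0.59, 0.59); a rotating wave with the same net direction keeps the
central coefficient but lowers the edge coefficient to about 0.57.
An origin placed on a grid node is singular there; that site is excluded
from the correlation.

## The wave simulator

All reference data are simulated from

\[ g(t, \varphi) = A\,e^{i(w t - k \varphi)} + \sigma\,\gamma(t), \]

where \(\varphi\) is the spatial phase input (a planar projection map in
grid units, or a rotation angle about a centre), \(w\) the temporal
angular frequency, \(k\) the spatial wavenumber and \(\gamma\) i.i.d.
standard complex Gaussian noise per site and sample. The noise-free
analytic phase at a site is exactly \(w t - k\varphi_{ab}\), giving
closed forms for every downstream quantity (phase differences \(k\,d\),
speed \(w/k\)).

Tunable parameters, defaults, and why:

* `A = 1` (arbitrary units) — the phase-based analyses are
  amplitude-invariant, so `A` only matters relative to `sigma`.
* `sigma = 0.25 A` — the noise level used for reference fingerprints.
  The source analyses do not state their simulation noise; 0.25 gives
  realistic fingerprint attenuation while keeping every library entry
  above the chance threshold.
* `k = 0.62` rad per grid unit (wavelength about 10 grid units, 1.3
  array widths) for the canonical long-wavelength planar wave. The value
  is calibrated jointly against the three published worked-example
  coefficients (0.9 and 0.64 for the diagonal planar wave; 0.52 for the
  curvature-matched rotating wave): the matched-rotating coefficient
  tracks the planar central coefficient, and k = 0.62 is the minimax
  joint fit (20-realization averages 0.90 / 0.59 / 0.57).
* Rotating templates come in two parameterizations. `scale = "angle"`
  uses the raw polar angle (k is a winding rate per radian); this is the
  library form, whose structure genuinely fades as k drops towards 0.1.
  `scale = "arc"` multiplies the angle by the centre-to-array distance
  so k keeps its radians-per-grid-unit meaning at the array; this form
  parameterizes the curvature-matched comparisons with planar waves. In
  both, the local wavelength grows with distance from the rotation
  centre, so an array far from the core sees a nearly planar,
  long-wavelength wave — the geometric degeneracy that motivates the
  three-point fingerprint in the first place.

### The reference library

`build_reference_library()` simulates 32 planar types spanning all
directions 11.25 degrees apart at the long-wavelength k, and 40 rotating
types: 5 rotation-centre placements x 8 wavenumbers evenly spaced in
[0.1, 0.9]. Fingerprints are averaged over 20 independent noise
realizations. Construction *fails* if any entry's largest absolute
coefficient is not above 0.3 — the guarantee that every library member
retains classifiable structure.

The placements (array centre, two steps towards the top-left corner, and
the two horizontal mid-edges, all on-array) were chosen to satisfy two
constraints that do not hold for arbitrary centres: (i) the noisy
fingerprints keep at least one coefficient above 0.3 across the whole k
range (centres at or beyond the corner fail at the extremes — very long
wavelengths carry too little phase range against the noise, and
many-cycle wrapped maps have an unstable circular mean); and (ii) all
three coefficients decay as k falls towards 0.1, the structural-fading
behaviour expected of rotating waves observed far from their core.
Coefficients lying on a bisecting axis stay at chance level for all k and
are exempt from (ii).

Classification is nearest-neighbour in the 3-D fingerprint space
(Euclidean distance), with instants whose largest absolute coefficient is
at most 0.3 left unclassified, and exact distance ties broken towards the
planar entry (and reported). Templates with k >= 0.5 are labelled
short-wavelength, the rest long — the boundary is the library midpoint,
as no published cutoff exists. With a noise-free library, noise-free
self-classification is exact; note that a noise-*averaged* library is
systematically attenuated relative to noise-free fingerprints (by up to
~40% for the weakest entries), so noise-free queries against a noisy
library can migrate towards planar entries — queries should be compared
against a library built at a matching noise level.

## Wave speed

Speed is the ratio of the temporal to the spatial phase gradient.
Temporal gradients use two-sided circular differences across +-1 sample;
spatial gradients use circular central differences on the grid (circular
differencing avoids 2-pi wrap artifacts). Both are averaged across
electrodes *before* the ratio — mean temporal gradient over mean spatial
gradient magnitude — and converted to cm/s with the 400 um pitch. On
noise-free planar waves the estimate equals \(f \lambda\) to machine
precision away from edges; the test suite requires 2% across
frequencies 6–20 Hz and wavelengths at least twice the array width.
Speed is only meaningful for long-wavelength instants (short-wavelength
rotating waves have spatially varying wavelength), and spatially uniform
(standing) maps are flagged invalid rather than given a speed.

## Task-epoch statistics

Trials follow the working-memory layout: 0.5 s pre-fixation baseline,
0.5 s fixation, 0.5 s sample, 2 s delay, 0.5 s test. Statistics compare
epochs against the baseline at p < 0.01 with trial permutations (the
published analyses mark significance without naming a test; two-sided
permutation tests with 10,000 permutations and a fixed seed are the
package-wide choice, uncorrected per bin to match the per-instant dot
convention):

* **Wave-count timecourses** bin events at 20 ms. Because per-trial
  per-bin counts are small integers, sign-flip permutations of
  count-minus-baseline differences are invalid (the difference
  distribution is far from symmetric); instead, the null exchanges each
  trial's tested-bin count with a randomly chosen baseline-bin count
  from the same trial, which respects the discreteness exactly.
* **rho_c histograms** pool the correlation timecourse (at a per-array
  origin, sign-oriented so the task-enhanced direction is positive) per
  epoch, normalize per trial, and compare each bin against baseline with
  paired sign-flip permutations (valid here: per-trial proportions are
  effectively continuous).
* **Direction-bias timecourses** report, per 0.5 s interval, the
  fraction of instants with rho_c > 0.3 (and < -0.3) minus the baseline
  fraction. Flipping the sign convention negates both curves exactly.
* **Direction histograms** use 12-degree polar bins (within the
  conventional 10–15 degree segment width); `align_preferred()` rotates
  each array's modal direction to 0 before averaging, preserving
  secondary lobes near 180 degrees.
* **Standing waves**: non-wave instants are split by the circular SD of
  their phase maps with a two-component (k-means) partition; instants
  below the midpoint of the two centres are standing. The cutoff is
  data-driven and reported with the result; if the non-wave SD
  distribution is genuinely unimodal the split is arbitrary, which is
  acceptable because the label then affects a homogeneous population.
* **Spike rate by wavelength** compares mean per-electrode rates during
  short- versus long-wavelength instants with label permutations.

## The synthetic-session generator

`synthesize_session()` emulates the study structure end to end: Poisson
wave events (2 events/s by default) within each epoch, each a 0.25 s
Hann-windowed band-limited burst (beta carrier at 20 Hz, amplitude 30 uV)
over pink-plus-white background noise (10 uV), organized into 50-trial
sessions by default. Event direction is the preferred azimuth (45
degrees, the direction that yields positive rho_c at the `(4,4)` origin)
with the epoch's bias probability, else the opposite; defaults are
unbiased (0.5) except 0.8 during sample and delay, giving bidirectional
baseline waves and a task-epoch direction bias. Rotating bursts can be
mixed in; their envelope decays with distance from the rotation centre
(strongest near the core), so amplitude-driven synthetic spikes
(inhomogeneous Poisson, rate rising with the local envelope) reproduce
the association between short wavelengths and higher spike rates.

What the generator does *not* emulate: volume conduction, electrode
impedance variation, artifacts, non-stationary background spectra,
multi-band interactions, or waves with time-varying direction within a
burst. Passing end-to-end tests therefore demonstrates that the analysis
recovers known structure from realistically noisy phase maps — not that
real cortical recordings contain such structure.

A note on the bias-recovery experiment: the injected bias grid
(0.5–1.0) is simulated with common random numbers (one seed for all
levels), so an event's direction flips monotonically from anti-preferred
to preferred as the bias rises. This isolates the bias effect from
between-session sampling noise and makes the monotone-recovery check a
test of the analysis rather than of the generator's variance.

## Numerical choices and degenerate inputs

* Angles are wrapped to \((-\pi, \pi]\); circular means use the argument
  of the resultant vector.
* `circ_corr()` refuses maps with zero circular variance (undefined
  correlation) with a typed error; the vectorized timecourse returns
  `NA` at such samples instead.
* The analytic signal of an all-zero trace yields `NA` phase with zero
  amplitude, not an error.
* Shuffling with a constant phase map is skipped with a warning.
* Classification ties (exactly equal distances) go to the planar entry
  and are reported via a message.
* All simulation and permutation randomness is seeded; the same seed
  reproduces sessions, libraries and p-values bit for bit. Seeds are
  applied with local RNG state, so library construction does not disturb
  the caller's random stream.

## Problem sizes

The shipped tests run the full stack at deliberately modest sizes: null
calibrations at 2,000–10,000 shuffles, libraries of 72 types with 20
noise realizations, sessions of 8–50 trials (32–200 s of 64-channel
1 kHz data), and permutation tests at 500–2,000 draws. These sizes keep
the whole suite within a few minutes while leaving every statistical
margin wide relative to its tolerance; all of them scale up linearly via
the corresponding arguments.

## Known limitations

* The quadrant detector is restricted to long spatial wavelengths by the
  positive-phase design; short-wavelength planar waves are the
  classifier's job, not the detector's.
* The three canonical origins cannot separate wave types whose
  fingerprints coincide (e.g. far-core rotating waves from planar waves
  of the same direction) — a geometric identifiability limit, not an
  implementation one.
* Wave speed assumes a single coherent wave per instant; superimposed
  waves bias the spatial-gradient average.
* The epoch statistics assume the trial layout above; other task
  structures require a custom `trial_epochs()`.
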