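---
title: "Methods: TDOA tracking of echolocating whales with clicktrackr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TDOA tracking of echolocating whales with clicktrackr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clicktrackr)
```

# The tracking problem

A deployment of four autonomous seafloor recorders — two 4-channel
tetrahedral arrays (~1 m hydrophone spacing, 100 kHz sampling) and two
single-channel instruments (200 kHz), all 470–1075 m apart — records the
echolocation clicks of deep-diving whales for months. Reconstructing a
3-D track from these recordings requires four things: detecting clicks on
each instrument, estimating per-click directions of arrival (DOA) on the
volumetric arrays, deciding which detections on different instruments came
from the same animal, and inverting time differences of arrival (TDOA)
into positions with honest uncertainties.

All positions live in a local East-North-Up Cartesian frame in meters,
with z positive up and the seafloor near z = 0. This matches the angle
conventions used throughout (azimuth counter-clockwise from East, East 0°,
North 90°; elevation 0° straight down, 90° horizontal, 180° straight up):
a DOA unit vector points *from source to receiver* (the direction of
propagation), and the display angles negate it to point from receiver to
source.

Propagation is modelled as straight rays at a constant sound speed `c`.
The field value of `c` is never measured by this package; it is a
configuration input (default 1500 m/s, a nominal deep-water value that
should be replaced by a site estimate) and the error made by assuming it
constant is carried as an uncertainty term (`sigma_c`, plus `sigma_ray`
for ray bending) rather than modelled.

# Detection

Clicks of Cuvier's beaked whale concentrate energy above ~20 kHz. The
detector applies a 4th-order elliptic high-pass at 20 kHz (0.1 dB passband
ripple, 40 dB stopband attenuation) forward and backward, so the response
is zero-phase and the effective stopband attenuation doubles; peak times
are not shifted. Detections are local maxima of the absolute filtered
waveform above a linear threshold, and within ±5 ms of a larger peak all
smaller peaks are removed (greedy, descending amplitude), so a multi-cycle
click registers once.

The amplitude threshold is accepted in linear recorded units, or converted
from a sound pressure level via a single flat sensitivity
(`amplitude_threshold_from_db()`; `10^(dB/20) × calibration`). The
threshold is interpreted as *peak* pressure — the level convention (peak
vs. peak-to-peak) is ambiguous in common usage, so the choice is stated
here and in the function documentation. Full frequency-dependent
hydrophone calibration is out of scope.

# Small-aperture TDOAs and DOA

For each detection on a 4-channel array, a window of 2 ms plus the
physical TDOA bound (aperture / c, ~0.7 ms for a 1 m array) around the
click is cross-correlated between all six hydrophone pairs, in the fixed
order (1,2), (1,3), (1,4), (2,3), (2,4), (3,4). Correlation is done on the
*filtered* snippets.

At 100 kHz a raw sample is 10 µs, while the whole TDOA range across a 1 m
aperture is only ~667 µs, so sub-sample interpolation is essential. The
correlation function is upsampled ×16 by zero-padding its spectrum
(band-limited interpolation) and the peak is then refined with a 3-point
parabolic fit on the fine grid. A parabola on the raw grid alone is biased
by the 35 kHz carrier ripple of the correlation function (~0.05 samples);
the upsampled variant measures clean delays to ~10⁻³ samples. Measured
TDOAs are clipped to the physical bound plus one sample.

The DOA solves the stacked plane-wave system `H s = c τ` (H the 6×3 matrix
of pair vectors) by least squares and renormalizes `s` to unit length; the
TDOA-domain RMS residual and the normalization gap are reported on the
result. Least-squares-then-normalize keeps the estimator linear and makes
the leave-one-out jackknife cheap; the residual records how far the six
TDOAs are from exact consistency.

# Association across instruments

Detections on the labelled reference array are associated with the other
instruments by click-train correlation. A click train is a binary vector
on a 1 ms grid (floor convention for cell assignment), 1 where that
source has a detection, convolved with a 20 ms Hann window so that small
arrival-time and inter-click-interval changes still correlate. The
labelled train of each source is cross-correlated (raw, unnormalized —
the acceptance rule below is scale-invariant) with the unlabeled
instrument's all-detections train over lags up to the physical
inter-instrument bound plus a clock-drift allowance.

The lag of the global maximum is the coarse delay τ. The window is
*accepted* only if no other correlation peak rivals it: among local maxima
separated by at least one Hann width (so the main peak's shoulder cannot
count as a second peak), the second-highest must stay below 80% of the
highest. Rejected windows propagate no labels — a deliberately
conservative rule, since a silent or sparsely detected source produces
only small, ambiguous peaks.

Windows are 30 s long and step forward through the labelled detections
(default one detection per step in the CLI; the validation scenes use a
step of a few detections purely to bound runtime). Unlabeled detections
within 10 ms (half the Hann width) of a shifted labelled click receive
that label as a *vote*; after all windows, each detection takes the
majority label, ties left unlabeled. The majority rule replaces an
analyst's final interactive pass and is the package's own choice.

Accepted coarse delays are refined by cross-correlating the waveforms
themselves around the predicted arrivals (snippets ±8 ms, residual search
±5 ms, same ×16 sub-sample interpolation). When sampling rates differ,
the higher-rate snippet is resampled to the lower rate in the frequency
domain — exact band-limited resampling with zero group delay, with the
input trimmed to a commensurate length so the output time grid is exact.
(Polyphase time-domain resamplers carry an uncompensated filter delay of
a few samples, which would bias every mixed-rate TDOA by tens of
microseconds.) Two further conventions matter at this accuracy and are
easy to get wrong: correlation lags must be referenced to the actual
snippet start times, which are rounded to each instrument's sample grid;
and the measured TDOA belongs to the *reference hydrophone* of each
instrument (channel 1), so the hyperboloid foci in localization are the
channel-1 positions, not the array centroids — the ~0.5 m difference is
worth 200–400 µs.

# Localization

Per detection, two geometries are available:

- **DOA ray × hyperboloid** — the source lies along the receiver-to-source
  ray of a 4-channel array; the measured large-aperture TDOA to a partner
  instrument selects the range. The range is found on a 1 m grid
  (default 0–8000 m) by minimizing the squared TDOA error, refined with a
  local parabolic fit; a minimum at the grid edge (e.g. a TDOA
  inconsistent with every ray point) flags the estimate as a boundary
  solution.
- **DOA × DOA** — the 2-unknown least-squares intersection of the two DOA
  lines; the estimate is the midpoint of the closest points, and the miss
  distance is reported. Lines within 0.1° of parallel are rejected as
  ill-conditioned.

## Error budgets

The TDOA standard deviations used for perturbation are the propagated
budgets

- small aperture: `σ_sml² = (σ_H/c)² + (‖H‖/c)²(σ_hi²/100² + σ_ray²) +
  (TDOA/c)²σ_c² + σ_xcorr²`
- large aperture: `σ_lrg² = (σ_hi² + σ_hj²)/c² + TDOA²σ_c²/c² +
  σ_traveltime² + σ_drift² + σ_xcorr²`

with σ_H the hydrophone-pair geometry uncertainty (m), σ_hi the instrument
position uncertainty (m), σ_ray a plane-wave/ray-bending timing error (s),
σ_c the sound-speed uncertainty (m/s), σ_xcorr the cross-correlation
timing uncertainty (s), σ_traveltime and σ_drift residual travel-time and
clock-drift uncertainties (s). The 1/100² factor on the instrument-position
term of σ_sml is applied exactly as the budget is specified (it originates
in a unit conversion in the budget's derivation, which is outside this
package's scope). All σ are user inputs in the geometry configuration.

## Monte-Carlo bootstrap

Each detection's TDOAs are perturbed 50 times with Gaussian noise at
σ_sml/σ_lrg; the DOAs are re-solved from the perturbed small-aperture
TDOAs and every instrument combination is localized, keeping all samples
with combination tags. Perturbation is seeded explicitly and the seed is
recorded, so runs are reproducible.

Samples are weighted by the inverse of their combination's variance
(mean of the three per-axis variances; zero-variance combinations are
capped at 1/(0.1 m)² so a degenerate noiseless cloud cannot produce
infinite weights). Weights apply to each sample individually. The cloud is
resampled with replacement 50 times; each resample yields a weighted
average, and the final position is the mean of the 50 resampled averages.

The 95% intervals are Studentized against the spread of
*per-perturbation replicate estimates*: combining all combinations within
one perturbation gives one complete localization under one fresh draw of
TDOA noise at the assumed σ, so the standard deviation of these replicates
estimates exactly the error scale of the final estimator under measurement
noise. The replicates are Studentized about the final position, their
2.5%/97.5% pivot quantiles are averaged over bootstrap resamples, and a
Student-t floor `qt(0.975, n−1)·√(1+1/n)` corrects the known downward bias
of empirical quantiles from ~50 replicates. Two plausible alternatives
fail on first principles: the pooled cloud spread ignores the
inverse-variance combination (intervals several times too wide), and the
standard error of the cloud mean treats perturbations as independent data
(intervals ~√50 too narrow). The exact Studentized-bootstrap variant is an
interpretation — the method family is standard, but its application to a
perturbation cloud is specified here rather than inherited.

Short gaps in a pair's TDOA series may be filled by linear interpolation
when the bracketing measurements are at most 5 minutes apart; interpolated
entries are flagged and longer gaps left empty.

## Jackknife for the two-DOA path

For two-array deployments, uncertainty comes from 12 leave-one-TDOA-out
re-estimates: each of the six TDOAs on each array is dropped, that DOA
re-solved from the remaining five, and the intersection recomputed with
the other array's full DOA. The jackknife variance of the 12 positions
enters a Student-t quantile (df = 11) for per-axis 95% intervals.

# Calibration

- **Hydrophone geometry from ship noise.** With the ship's GPS position
  known per 1-s bin, each binned pair TDOA contributes one plane-wave
  equation in the unknown hydrophone positions. The stacked system is
  solved with the Moore–Penrose pseudoinverse; since TDOAs are invariant
  to translating the whole array, the minimum-norm solution fixes the
  gauge at the array centroid. Bearing coverage is checked through the
  singular values outside the 3-dimensional translation null space.
- **Trilateration.** Instrument positions minimize
  `Σ(2‖ship−p‖/c − t_twoway)²` (BFGS), optionally with a soft depth
  prior; the Jacobian's conditioning flags collinear ship tracks.
- **Clock drift.** Synchronization pings are detected with a band-pass at
  the *effective* frequency — a 75 kHz ping sampled at 100 kHz folds to
  25 kHz, and 200 kHz streams are first decimated by simple sample
  dropping (no anti-alias filter: the aliasing is the point) — followed by
  envelope thresholding and an interval-outlier rejection (median absolute
  deviation of the offset from the nominal ping grid, 5× threshold),
  which automates what would otherwise be manual removal of false ping
  detections. Pings are paired across instruments by nearest time within
  half the nominal interval; drift is the measured pair TDOA minus the
  expected (survey-epoch) TDOA, fitted with a degree-5 polynomial over
  centered, scaled time. The reference for the expected TDOA is the value
  measured during the instrument-survey epoch, not a modelled source
  position. Corrections subtract the fitted drift from detection times;
  the model maps uncorrected times, so correction is applied once, not
  idempotently.

# The synthetic-scene generator

The simulator is first-class, tested code: it renders multichannel
waveforms for the default deployment layout (two tetrahedra at ±535 m on
an East–West baseline, two single-channel instruments 500 m North/South,
100/200 kHz) from parametric dive tracks (descent to foraging depth, then
level transit at ~1.5 m/s), regular inter-click intervals of 0.3–0.5 s
with 10% uniform jitter, spherical spreading (1/r), optional cosine-power
beam directivity, Gaussian noise, Poisson clutter (rendered per instrument
with random but physically consistent channel delays), injected clock
drift, and optional 75 kHz synchronization pings. Clicks are Hann-windowed
35 kHz tone bursts of 0.2 ms — inside the detection band at both sampling
rates — evaluated directly at each channel's sample times, so fractional
sample delays are rendered exactly. Instrument-level arrivals use the
exact spherical model; per-channel delays use the plane-wave model with
the true instantaneous DOA, making the DOA inversion exactly consistent
with the forward model. All randomness flows from a single scene seed;
identical seeds give bit-identical waveforms.

What passing tests on these scenes do and do not show: they verify the
geometry, the estimators, the association logic and the uncertainty
propagation end-to-end, but the scenes have no multipath, no
frequency-dependent absorption, no realistic beaked-whale click spectra,
no surface reflections and no mooring motion. Wavefront-curvature error
across an array exists in the exact instrument-arrival model but not in
the channel rendering, and σ_ray exists precisely to absorb such
model mismatch on real data. Performance numbers from synthetic scenes
are therefore upper bounds on real-data performance.

# Numerical choices and degenerate inputs

- DOA vectors within 10⁻⁶ of unit length are renormalized silently; larger
  deviations are an error.
- Cross-correlation upsampling ×16, 3-point parabolic refinement, peak
  clipped to the physical bound; a peak within one sample of the search
  limit is flagged unreliable, as is a normalized peak below 0.3 in
  fine-TDOA refinement.
- Range grid 1 m over 0–8000 m with parabolic refinement; boundary minima
  flagged rather than silently returned.
- Coplanar pair geometries, parallel DOAs, zero-norm DOA solutions,
  all-zero click trains, < 7 matched ping pairs (degree-5 fit needs more)
  and missing instrument combinations all raise typed errors or flagged
  results rather than NaNs.
- Encounter usability: at least 5 minutes long *and* at least 300 clicks
  for at least one label (the click rule applies per label, since a track
  needs that label's detections, not the encounter total).

# Validation problem sizes

The shipped test-suite scenes are sized to run comfortably on one CPU:
20 s single-source waveform scenes for the end-to-end checks (~55 clicks
per instrument), 500–1000 random directions for DOA accuracy, 120 s
detection-level scenes with 2–5 sources for association accuracy, 150–200
noisy detections for interval coverage, and a 120-day, 1-minute-interval
ping record (172 801 pings) for clock-drift recovery. The end-to-end
noiseless track error is ~0.03 m on both localization paths; association
accuracy is ≥ 90% at five interleaved sources with 30% clutter; interval
coverage is ~92–95% at a nominal 95%.

# Known limitations

- Constant sound speed, straight rays, no multipath ranging.
- One DOA per detection window: overlapping clicks from several animals
  within the small-aperture TDOA range corrupt the cross-correlations
  (dolphin pods are the classic case) and must be removed by label
  editing, e.g. by their high elevation angles.
- The majority-vote conflict rule and the Studentized-bootstrap variant
  are this package's own resolutions of genuinely open design points, and
  are documented as such above.
- No multi-target tracker or swim-speed prior smooths the per-click
  estimates; tracks are independent per-detection localizations.
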