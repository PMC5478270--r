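---
title: "threatconn: models, methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{threatconn: models, methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the models and their assumptions, the parameters that
matter, what the synthetic cohorts do and do not emulate, and the
places where the design was genuinely open and a choice had to be
made.  It states no empirical result that the test suite does not
itself compute.

## 1. The experimental design being emulated

The threat-of-shock paradigm alternates *safe* and *threat* blocks;
unpredictable electric shocks can occur only during threat, inducing a
sustained anxious state rather than a phasic fear response.  The
package models the two acquisition arms of such an experiment:

* **fMRI arm** — four runs of 490 s at TR = 2 s (245 volumes per run),
  each containing two 2-min blocks per condition, no startle probes,
  0-3 shocks per run at random times inside threat blocks.  Frames
  before the first block are labelled `pre` and excluded from
  condition contrasts.
* **MEG arm** — four runs opening with four habituation startle
  probes, then two blocks per condition of eight probes each,
  inter-probe intervals uniform on 6-14 s; each threat interprobe
  interval carries a 1/12 shock probability, capped at two shocks per
  run, with the shock placed 2-4 s after the preceding probe.
  Analysis epochs are the 2 s preceding each probe.

`build_block_schedule()` generates both; every stochastic quantity in
the package flows from an explicit integer seed, and all generators
restore the caller's RNG state.

## 2. fMRI: global brain connectivity

### Model

For voxel time courses `x_v` restricted to one condition's uncensored
frames, `GBC(v) = mean over u != v of atanh(r(x_v, x_u))`.
Correlations are clipped to `|r| <= 1 - 1e-7` before `atanh` so maps
stay finite; self-correlations are excluded from the average
(`exclude_self = FALSE` reinstates them, since descriptions of the
measure are ambiguous between "every other voxel" and matrix-row
averages — the difference is a fixed affine map and cannot change any
paired contrast).  Signed correlations are averaged; negative
correlations are not down-weighted.

Upstream of GBC: motion censoring (frames whose 6-parameter motion
first-difference Euclidean norm exceeds 0.5 mm), per-run nuisance
regression (Legendre polynomials of order 0-3 for drift, the six
motion parameters, and event regressors built from shock/button
onsets convolved with a peak-normalized gamma-variate response
`h(t) ~ t^8.6 exp(-t / 0.547 s)`, peaking at 4.7 s — no specific
response shape is canonical, this is a standard single-gamma choice),
and in-mask Gaussian smoothing.  Betas are fit on uncensored frames
only; correlation uses concatenated uncensored condition frames across
runs.  Block-transition frames carry their block's label; transition-
response regressors are out of scope.

### Robustness re-test

Shock effects are removed by censoring the shock TR plus the following
nine (10 TRs total), an equal number of safe frames closely matched
for motion is censored (greedy nearest-enorm matching without
replacement, largest first), and the remaining condition difference in
cluster-mean GBC is tested with the residual motion difference as
covariate in an ANCOVA on difference scores.

### Within-mask smoothing

The smoothing operator renormalizes the Gaussian kernel over in-mask
voxels, so nothing bleeds across the mask edge and a constant field is
reproduced exactly.  Exact constant preservation and exact mass
conservation are incompatible at the mask edge; constants were chosen
because a mean shift of a connectivity map is analytically inert while
edge-mass loss would bias edge-voxel variance.  The impulse response
therefore integrates to ~1 with a few-percent edge excess (tested).

### Synthetic cohort and its ground truth

Every in-mask voxel loads on a global latent `g(t)` with weight
`w0 = sqrt(rho0)` (`rho0 = 0.25` by default), giving an equicorrelated
baseline.  During threat frames the loading of a contiguous blob of
hub voxels is raised to `w_h = w0 + delta_rho / w0`, which raises each
hub voxel's correlation with every other voxel by exactly `delta_rho`
— the closed form that makes the injected effect an analytic target
(`atanh(rho0 + delta_rho) - atanh(rho0)` on the Fisher-Z scale).  The
construction requires `delta_rho < w0 (1 - w0)`; larger values are
rejected as a parameter error, matching the non-real-weight failure
the closed form implies.

The residual component is AR(1) in time (phi = 0.3 by default; no
noise model is canonical for this design, and 0.3 is a typical
grey-matter value at TR = 2 s) and spatially correlated by passing
white noise through the in-mask 6-mm smoothing operator.  The
spatial smoothing is applied to the *noise only*: smoothing the summed
field would leak hub loadings into neighbours and destroy the
closed-form ground truth the generator exists to provide.  The
consequence — injected loadings are spatially sharp while noise is
smooth — is a deliberate trade of realism for verifiability.

Motion is a 6-parameter random walk (0.05 mm/frame) with occasional
0.8 mm spikes (2% of frames) so the censoring rule has real work; a
random cubic drift and event responses are added so the nuisance
regression does too.  Defaults: 12 subjects, 12x12x12 grid of 3 mm
voxels, ellipsoidal mask of ~672 voxels, 20 hub voxels,
`delta_rho = 0.15` — a desk-scale stand-in for a ~43k-voxel
grey-matter mask that keeps every acceptance simulation under a few
seconds.

What a green test establishes: that the pipeline recovers a known
connectivity increment, at the right location, at approximately the
right magnitude, with calibrated false positives.  What it does not:
realistic haemodynamics, multi-echo physics, physiological noise,
registration error — all out of scope.

## 3. Cluster inference

### fMRI route: ACF-matched Monte-Carlo cluster-size threshold

Residual spatial autocorrelation is estimated from voxel-pair
correlations binned by exact grid distance and fitted with the
Gaussian-plus-mono-exponential model
`ACF(r) = a exp(-r^2 / (2 b^2)) + (1 - a) exp(-r / c)`, constrained to
`a` in [0, 1] and `b, c > 0` so `ACF(0) = 1` and the fit decreases.
Binning by *exact* distance matters: rounding distances to voxel
multiples mixes face (3 mm) and diagonal (4.24 mm) neighbours into one
bin and visibly deflates the short-range curve.

Null statistical maps with the fitted ACF are synthesized by exact
covariance-root (eigen) sampling over the in-mask voxels.  The
spec-suggested FFT/spectral colouring was implemented first and
abandoned: on a 3 mm grid the mono-exponential kernel's spectrum
aliases, and the realized nearest-neighbour correlation came out ~17%
low, breaking the generator's own generate-and-refit contract.  At
desk scale (<= a few thousand voxels) the eigendecomposition is
exact and cheap; the trade-off would reverse on a full-size mask.

Each null map is thresholded two-sided at the voxelwise p (0.005), the
largest suprathreshold component recorded (face connectivity,
positive and negative signs separately), and the minimum significant
cluster size is the `ceiling((1 - alpha) n_iter)`-th order statistic
of that null.

### MEG route: sign-flip permutation cluster-mass test

"Condition labels shuffled across subjects" in a paired design has
exactly one exchangeable reading: within-subject condition exchange,
i.e. sign flips of the per-subject difference maps.  One-sample t
statistics per node are thresholded two-sided at the node p (0.005,
df = n - 1), connected components formed per sign, and each cluster's
mass (summed t) compared against the permutation null of the maximum
absolute cluster mass.  All `2^n` flips are enumerated when feasible
(`2^n <= n_perm`); otherwise `n_perm` random flips are drawn and
p-values use the add-one rule, which keeps them valid (never
anti-conservative) at the cost of a floor of `1/(n_perm + 1)`.
Positive and negative clusters compete against the single max-|mass|
null, giving a two-sided correction at alpha.

Adjacency is face connectivity for voxels, a distance threshold
(default 4 cm) for sensors, and 1.5x grid spacing for source grids —
the neighbourhood definitions are configurable because no canonical
choice exists.

## 4. MEG spectral analysis

Epochs are demeaned and linearly detrended per trial, low-passed at
90 Hz and notch-filtered at 60 Hz (zero-phase frequency-domain
filters with raised-cosine transitions; short fixed-length epochs make
FFT filtering the natural zero-phase implementation), and decimated to
300 Hz — the low-pass doubles as the anti-alias filter.

Muscle artifacts are detected before decimation: 110-140 Hz band-pass,
envelope (magnitude of the band-limited analytic signal), envelope
averaged within trial per sensor, and the per-trial means z-scored
across trials per sensor with median/MAD centring so contaminated
trials cannot mask themselves; any sensor exceeding z = 4 flags the
trial.  The band and threshold are field-standard defaults.  Averaging
the envelope within trial keeps the null false-alarm rate near zero
while a 300 ms burst still shifts the trial mean by many SDs (both
tested against generator ground truth).

Spectra use orthonormal Slepian tapers from the standard tridiagonal
eigenproblem.  The 1-20 Hz survey spectrum uses a single taper; the
IAF-band power uses two tapers (time-half-bandwidth 2).  Power is
scaled so the one-sided spectrum integrates to signal variance.  The
IAF is the largest strict local maximum of the trial- and
sensor-averaged spectrum on the 0.5 Hz grid; if it falls outside
8-12 Hz the subject is flagged and assigned the mean IAF of the
subjects with detected peaks (whether the original fallback averaged
over peaked subjects only or all subjects is unstated; peaked-only is
the reading that does not contaminate the average with undefined
values).  Band power is the two-taper power averaged over
[IAF - 1, IAF + 1] Hz.

The synthetic MEG cohort places 64 radial sensors on an upper
hemisphere of radius 12 cm around a 9 cm conducting sphere, sources on
a 2 cm grid — a scaled-down stand-in for a 275-channel, 8-mm-grid
recording.  One active source emits an alpha oscillation at the
subject's IAF with random phase per trial and amplitude multiplied by
`alpha_mod` on threat trials (power ratio `alpha_mod^2`); incoherent
pink-noise background sources and white sensor noise set a realistic
floor, which is why measured sensor-power ratios sit between
`alpha_mod^2` and 1 (the no-floor ratio is verified separately with
noise turned off).

## 5. DICS source analysis

The forward model is the closed-form field of a current dipole in a
homogeneous conducting sphere projected on radial sensor directions —
an analytic replacement for a realistic single-shell model, and the
one deliberate geometry-level simplification in the package.  Its
radial-silence property (volume currents produce no radial field)
doubles as an exact test oracle: the radial projection must equal the
primary dipole's Biot-Savart field alone.  The beamformer consumes any
externally supplied leadfield matrix unchanged.

The cross-spectral density is the mean over trials, tapers and band
frequencies of outer products of tapered Fourier coefficients —
Hermitian positive semidefinite by construction.  Filters use the real
part of the CSD (standard for fixed-orientation power mapping),
regularized as `C + lambda tr(C)/N I` with lambda = 0.05 — the "5%"
is read as a fraction of mean sensor power, the standard convention;
whether the original scaled the covariance or CSD trace is unstated.
Per source, `w = (l' C^-1 l)^-1 l' C^-1`, so unit gain `w l = 1` holds
to machine precision.  The filter is estimated from all trials pooled
(the *common filter*) and applied to each condition's CSD separately;
the tests verify both that condition power maps through the common
filter localize correctly and that they differ from per-condition
filters — the difference is precisely why the common filter is
mandated for condition contrasts.

## 6. Startle and ratings

EMG scoring: band-pass from 30 Hz up, rectify, smooth with a 20 ms
time constant, take the maximum in the 20-100 ms post-probe window.
Three scoring decisions were forced by physics or ambiguity:

* The nominal 30-500 Hz blink band is unrealizable at the 600 Hz
  recording rate (Nyquist 300 Hz); the upper edge is `0.99 fs/2`,
  preserving the stated lower edge without aliasing fiction.
* "20 ms time constant" is implemented as a single-pole RC exponential
  on the rectified signal, run forward and backward so the peak
  latency is unbiased; a boxcar alternative is available by flag.
* All filtering is zero-phase for the same reason.

T-scores are `50 + 10 (x - mean)/sd` with the sample (n-1) SD, applied
across all scored probes within subject *before* condition averaging.
Normalizing per-condition means only would leave two numbers per
subject with no within-subject variance and make the paired test
degenerate; the published degrees of freedom of such analyses imply
per-sample variance exists.  Habituation probes are excluded from
scoring by default (flagged, not dropped); whether the original
excluded them is unstated, but they precede the block structure and
have no condition interpretation.

The EMG generator gives each probe a Gaussian-envelope (10 ms SD)
80 Hz burst peaking at a uniform 40-80 ms latency, lognormal
trial-to-trial amplitude jitter (SD 0.6 — startle magnitudes are
highly variable), baseline noise, and a threat multiplier.  A shared
subject-level anxiety factor (SD 0.3) scales both the startle
potentiation and the rating shift, which is what makes APS and rating
differences correlate across subjects — with it set to zero the
generator produces saturated, near-identical T-score differences and
implausibly large group t statistics.  Ratings live on the 0-255 hue
scale with noise SD 25, clipped.

## 7. Statistics

Paired t, Pearson correlation and the ANCOVA are textbook formulas
with sample (n-1) SDs throughout.  The trial-count/motion ANCOVA is
formalized as the intercept test of an OLS regression of difference
scores on a centred covariate, `F(1, n - 2)` — the only reading
consistent with difference-score degrees of freedom of the form
(1, n - 2).  Within-subject SEMs remove subject means, restore the
grand mean, and apply the Morey `sqrt(C/(C-1))` correction
(toggleable; the correction matters only for C = 2 bar plots here).

## 8. Numerical choices

* Correlation clipping at `1 - 1e-7` before `atanh`; infinities are
  rejected rather than propagated.
* FFT filters pack pairs of real signals into one complex transform
  (the gain is real and symmetric, so real and imaginary parts filter
  independently); decimation by 2 folds the gained spectrum onto the
  half-length grid and inverts once.  Both are exact, not
  approximations, and are tested against the plain path.
* EMG traces are zero-padded to 5-smooth lengths before FFT filtering
  (R's mixed-radix FFT degrades on awkward prime factors).
* DPSS tapers and simulation geometry are cached per session; both are
  deterministic functions of their parameters.
* The ACF fit runs BFGS from three start points on transformed
  parameters (logit a, log b, log c), keeping the constraints
  satisfied by construction.

## 9. Known limitations

* No multi-echo physics, physiological noise, registration, or
  realistic head anatomy anywhere; the forward model is a sphere.
* The synthetic fMRI noise ACF is inherited from the smoothing
  operator, not fitted to real residuals; absolute cluster-size
  thresholds on the desk-scale grid do not transfer to full-size
  masks (the published 80-voxel threshold depends on unprinted fitted
  ACF parameters and is not reproducible even in principle).
* Probe/shock randomization uses one session-level RNG stream by
  default (per-run streams are available by seeding runs explicitly);
  which the original used is unstated.
* The behavioural acceptance comparison against the study's deposited
  per-figure source data requires a download and is therefore red in
  offline environments; `behavioral_stats_from_source_data()` is the
  entry point once the files exist.
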