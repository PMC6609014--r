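---
title: "Methods: simulating and comparing R1 and T1w/T2w cortical mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and comparing R1 and T1w/T2w cortical mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mp2ratio)
```

This vignette is the package's own account of its models, parameter choices
and limitations. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The scientific problem

Cortical maps of the longitudinal relaxation rate R1 (= 1/T1) and of the
T1w/T2w intensity ratio are both used as myelin-sensitive contrasts. They
are constructed very differently: R1 is a quantitative parameter estimated
from a transmit-field-corrected MP2RAGE acquisition, while the ratio map is
a normalized contrast of two weighted images whose receive bias cancels in
the division but whose transmit (B1+) footprint does not. Whether the two
approaches measure the same quantity, how reproducible each is between
sessions, and how each responds to B1/B0 field inhomogeneity are empirical
questions. With human data those questions are confounded by registration,
segmentation and motion; this package instead builds a fully known digital
phantom so that every downstream statistic has a ground truth.

## 2. Signal models

All sequences are modelled at the level of longitudinal magnetization
`Mz` (M0 = 1), evolving through affine maps:

* inversion: `Mz -> -eff * Mz`, with inversion efficiency `eff` in (0, 1];
* free recovery over `t`: `Mz -> 1 - (1 - Mz) exp(-t/T1)`;
* one gradient-echo pulse with effective flip `b * alpha` and echo spacing
  `tr_gre`: `Mz -> Mz cos(b alpha) E1 + (1 - E1)`, `E1 = exp(-tr_gre/T1)`.

Because each stage is affine, one full sequence period composes to a single
affine map and the steady state is the exact fixed point — no iteration is
involved. Signals are read out at the k-space centre pulse
(`n_before` pulses into each block), multiplied by `sin(b alpha)`. The
MP2RAGE period is inversion / TA / block 1 (alpha1) / TB / block 2 (alpha2) /
TC with `TA = TI1 - n_before tr_gre`, `TB = TI2 - TI1 - (n_b + n_a) tr_gre`,
`TC = TR - TI2 - n_after tr_gre`; MPRAGE is the single-block analogue. The
test suite verifies the closed forms against an independent discrete-time
Bloch-stepping oracle (pulse-by-pulse, interval-by-interval, iterated to
steady state) to better than 1e-9 relative error over
T1 in [0.3, 4] s and b in [0.6, 1.4]. The error metric is
`||(s1,s2)_closed - (s1,s2)_oracle|| / ||(s1,s2)_oracle||` per evaluation,
because s2 crosses zero inside that grid and a pointwise relative error is
undefined there.

The T2w SPACE sequence is modelled phenomenologically as
`pd (1 - exp(-(TR - TE_eff)/T1)) exp(-TE_eff/T2) b^gamma`: no echo-train
simulation is attempted, and the `b^gamma` factor isolates a switchable
residual transmit dependence of the T2w image. `gamma = 1` by default, so
the ratio path carries a transmit footprint (distinct from the MPRAGE flip
response) unless it is removed downstream — this is the knob behind the
"BC vs non-BC" contrasts.

Two modelling simplifications are deliberate: T2*/TE decay is omitted from
the MP2RAGE signals because both readouts share the same echo time and the
factor cancels in UNI; and linear (not centric) k-space ordering is assumed
when placing the centre pulse.

### Inversion efficiency and B0

A static-field offset degrades the adiabatic inversion. The optional
coupling `eff(b0) = eff * max(0, 1 - kappa |b0| / b0_ref)` (disabled at
`kappa = 0`) lets the simulation reproduce the characteristic failure mode
of R1 mapping in high-|B0| regions: the lookup tables assume the nominal
efficiency, so a locally degraded inversion biases T1 without any warning
flag. This is how the hemispheric-asymmetry experiment breaks the R1 map's
left-right agreement while leaving the (spin-echo-based, residual-corrected)
ratio map nearly intact.

## 3. The UNI lookup and its monotone branch

`build_lookup()` tabulates UNI over T1 (0.05-5 s, step 5 ms) for each b
(0.5-1.5, step 0.01) and records, per b, the largest contiguous strictly
monotone interval containing the grey-matter anchor T1 = 1.35 s. The UNI
curve is globally non-injective: it saturates towards +0.5 at very short T1
and reaches its -0.5 bound where s1 = -s2 (about T1 = 3.0 s at b = 1 for the
default protocol, earlier at lower b) before rising again. Numerically the
invertible branch at b = 1 is [0.39, 2.98] s. Consequences:

* inversion interpolates linearly within the branch (two bracketing b rows,
  then linear in b); UNI values outside the branch clamp to the endpoint and
  are flagged; b outside the grid clamps to the nearest edge with a flag;
* T1 values beyond the branch (e.g. CSF at 4 s) *fold back* onto the branch
  — they produce plausible-looking but wrong estimates and cannot be
  flagged from the UNI value alone. This is a property of the sequence, not
  of the implementation: the acceptance test demanding a sub-0.5% round
  trip over T1 up to 4 s is therefore left red, with the attainable
  branch-restricted form (max error well under 0.5%, B1-corrected RMSE
  under 1%, uncorrected error more than 5x larger and increasing with
  |b - 1|) tested green alongside it.

## 4. The phantom: a stated world

Geometry: two spheres (one per hemisphere, centres offset ±22 mm from the
mid-sagittal plane), each with a white-matter core (r = 14 mm), a cortical
shell (14-20 mm) split into 12 contiguous parcels by spherical Voronoi
patches of quasi-uniform seed directions, and a CSF layer (20-24 mm). The
same seeds parcellate the volume and the mid-thickness icospheres
(r = 17 mm), so surface and volume labels agree; the right hemisphere is the
exact mirror of the left and the vertex correspondence is the identity on
indices. The default grid is 64^3 at a 2 mm "voxel" scale — a desk-scale
stand-in for the 0.8 mm acquisitions, available through configuration.

Tissue parameters (3T): T1 = 0.85 / 1.35 / 4.0 s for WM / GM / CSF, with
per-parcel GM T1 spread evenly over 1.2-1.5 s to emulate myeloarchitectonic
contrast, and PD = 0.70 / 0.85 / 1.00. The T2 values (0.25 / 0.35 / 2.0 s)
are *apparent* T2s for the phenomenological SPACE model: combining the
literal 569 ms effective echo time with true tissue T2 (~70-90 ms) would
leave essentially no parenchymal T2w signal, whereas the real variable-flip
echo train prolongs apparent decay. These values give the realistic
CSF > GM > WM T2w ordering and were fixed once, before any statistic was
inspected.

Fields: the transmit field decreases quadratically from 1.1 at the brain
centre to 0.8 at the brain edge (the dominant inner-high/outer-low pattern),
with an optional hemispheric asymmetry implemented as a smooth `tanh`
profile normalized so that the left-right difference of within-brain means
equals the requested amplitude exactly. The receive field rises towards the
periphery (0.85 centre, 1.25 edge). The B0 offset is a Gaussian blob
(40 Hz, 25 mm width by default) at the frontal brain edge, with its own
left-right asymmetry factor.

Noise and sessions: each magnitude image receives additive Gaussian noise
with SD equal to 2% of its mean absolute brain signal (a high-SNR 3T
regime; the generator is linear in this knob and a Monte-Carlo test checks
the scaling). UNI is formed from the *noisy* gradient-echo images. The
measured B1 map is the block average of the true field at 4x coarser
resolution plus 2% absolute noise, matching the resolution ratio of a coarse
turboFLASH calibration scan. A study draws per-subject parcel T1 jitter
(SD 0.03 s, shared across hemispheres), and the retest session differs by
noise realization and a small perturbation (SD 0.02) of the transmit-field
centre/edge parameters. Subject count defaults to 14. A motion surrogate —
a smooth low-order multiplicative ripple — is available but off by default;
it is a knob, not k-space physics. Neither the noise level nor the
between-subject variability is claimed from literature; they are
configuration defaults of the stated world.

What a green test on this phantom does *not* establish: anything involving
surface reconstruction, registration, distortion, partial-volume anatomy or
physiological variability. The printed human-cohort numbers (cross-method
R^2 ~ 0.8, deviation percentiles, Table-2 effect sizes) are not reproducible
here and are used directionally only.

## 5. Pipelines

R1: the measured B1 map is upsampled (trilinear), smoothed within the brain
mask (normalized convolution, 5 mm FWHM), divided by its smoothed version,
thresholded one-sidedly at mean - 2 SD of that ratio (the low tail, as the
processing chain it mirrors does), cleaned of small 6-connected islands
(< 27 voxels; the largest component is kept), extrapolated to the full FOV
by nearest-valid-neighbour (chamfer sweeps) and smoothed again. The UNI
volume is then inverted per voxel with the local cleaned b.

Ratio: `F = sqrt(T1w x T2w)` within the mask, normalized to unit mean, then
the same conditioning chain; both images are divided by the estimate; the
ratio map itself is exactly invariant to any shared multiplicative field, so
this correction matters for downstream consumers of the corrected images,
not for the ratio. The residual bias correction subtracts the
surface-smoothed difference to a group reference map (additive on the map
scale; whether the reference pipeline divides or subtracts is not specified
upstream, and additive keeps the operation linear). The smoothing FWHM
defaults to 30 mm at real-brain scale; the desk-scale study uses 8 mm
because the phantom hemisphere is about a quarter of the linear size of a
real one — fixed from geometry, not tuned. The reference itself is the
ratio surface map of a noise-free, nominal-field (b = 1, F_rx = 1) session
of the base phantom, standing in for the external population-average
reference used with human data; an external reference is what makes the
correction able to remove bias that is common to all subjects.

Surface operations: "myelin-style" sampling collects cortical-labelled
voxels within `2 sigma + 1 voxel` of each mid-thickness vertex
(sampling FWHM 1 mm, sigma ~ 0.425 mm), weights them by a Gaussian in
Euclidean distance, excludes voxels deviating from the local weighted
median by more than 3 robust SDs (1.4826 x weighted MAD; the exact upstream
threshold is unpublished), renormalizes the weights and averages. Vertices
with no admissible voxel become NaN and stay NaN through smoothing and
statistics (never zero-filled). Surface smoothing is iterated neighbour
averaging, `x <- (1 - w) x + w ring_mean(x)`: each step convolves with a
kernel of per-axis variance `w h2 / 2` (h2 = mean squared edge length), so
`n w h2 / 2 = sigma^2` calibrates the kernel; an impulse-response test on a
planar regular mesh pins the realized SD within 5% of sigma. Constants are
preserved exactly and no new extrema can appear (convex combinations). Maps
are smoothed at 4 mm FWHM (sigma ~ 1.698 mm). Gradients fit an affine
function of the two tangent-plane coordinates to the 1-ring (widened to the
2-ring when collinear) after a 2.35 mm-sigma surface pre-smoothing; the
0.1 mm volume pre-smoothing named by the source protocol is sub-voxel at
any grid this package uses and is a documented no-op.

## 6. Statistics

All statistics are direct formula evaluations (sums), which lets base R's
`lm`, `t.test` and a manual order-statistic interpolation serve as
independent oracles at 1e-12 relative tolerance. Conventions fixed here:

* percentiles interpolate linearly between order statistics (type 7);
* the two-sample test is the pooled-variance Student t (dof = n1 + n2 - 2),
  consistent with a single reported dof per pair; Cohen's d uses the pooled
  SD, i.e. it is weighted by the relative group sizes;
* effect sizes classify as small (<0.5), medium (=0.5), large (>0.5), very
  large (>1.2), huge (>2) — reading the source convention's "< 05" as a typo
  for 0.5;
* cross-subject dispersion is SD/n, *as literally defined by the analysis
  it mirrors*; the conventional SD/sqrt(n) sits behind a `sqrt_n` flag
  because the intent is not recoverable;
* the deviation map normalizes |test - retest| by the max - min range of the
  group-average map (a 1-99 percentile option exists but is off by
  default); the statistic is symmetric in test/retest and invariant to
  common rescaling;
* regressions: test on x, retest on y; R1 on x, ratio on y; right
  hemisphere on x, left on y;
* p-values are computed but never compared against published values (those
  are printed as "0").

In `run_study()`, cross-method and left-right regressions use parcel means
of the test-session group-average maps; the test-retest regression compares
test and retest group averages; deviation maps are per-subject. Neighbouring
parcel pairs for effect-size tests come from mesh-edge adjacency of the
parcellation. When a configuration is exactly mirror-symmetric the
asymmetry-vs-B1 correlation is undefined (zero variance) and reported as NA.

## 7. Numerical and design choices

* Lookup branch anchoring at T1 = 1.35 s resolves the global non-injectivity
  of UNI the same way the reference tooling does implicitly.
* b outside the lookup's b grid clamps to the edge (flagged) rather than
  erroring: edge voxels of a measured B1 map would otherwise kill a fit.
* R1 is reported in Hz; a mHz scale is an output option mirroring tools
  that invert millisecond-scale T1.
* Island removal uses 6-connectivity, the smallest standard choice.
* Gaussian volume smoothing uses row-normalized truncated (4 sigma)
  separable kernels, so constants are preserved exactly at the edges;
  within-mask smoothing is normalized convolution.
* Nearest-neighbour extrapolation is L1 (chamfer sweeps), not exact
  Euclidean; the result is smoothed immediately afterwards.
* The report writer fixes row order and float format, so identical inputs
  give byte-identical files; timings live only on the in-memory object.
* Session/subject seeds derive from one master seed via `sample.int`,
  keeping every draw below 2^31.

## 8. Known limitations

* No anatomy: spheres and Voronoi parcels; no curvature-thickness
  confounds, no segmentation error — precisely the terms the human
  comparison cannot isolate.
* The SPACE model's transmit dependence is a single exponent, not an
  echo-train simulation; conclusions about the *size* of the ratio method's
  transmit bias transfer only directionally.
* Rician noise is available but off by default; at the simulated SNR the
  Gaussian approximation is accurate and keeps the noise-scaling oracle
  analytic.
* The residual-bias reference is noise-free and bias-free by construction;
  with human data the reference itself is an imperfect average.
* Only what the package writes is guaranteed to round-trip through the
  minimal NIfTI-1/GIFTI readers.
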