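---
title: "Functional conductivity imaging: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional conductivity imaging: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funCI)
```

## The model

Phase-based MR electrical properties tomography (MREPT) estimates tissue
electrical conductivity from the image phase of a balanced steady-state
acquisition. Under the transceive-phase assumption — the transmit phase is
half the measured transceive phase $\varphi^\pm$ — the conductivity at the
Larmor frequency is

$$\sigma \;\approx\; \frac{\nabla^2 \varphi^\pm}{2\,\mu_0\,\omega},$$

with $\mu_0 = 4\pi\times10^{-7}$ H/m and $\omega = 2\pi f_0$
($f_0 = 127.76$ MHz for the 3 T default). The factor 2 is the transceive
assumption: feed this package half phase and every $\sigma$ halves.
Everything difficult about phase-MREPT hides in $\nabla^2$: the Laplacian
amplifies noise and is badly corrupted near tissue boundaries, where the
true phase curvature is discontinuous.

### Tissue-restricted average parabolic fitting

`phaseLaplacian()` estimates the second derivative along each axis by
fitting least-squares parabolas separately to {target voxel + left-side
row} and {target voxel + right-side row} and averaging the two one-sided
curvatures. Kernel rows live inside a box of at most 9 x 9 x 6 voxels
(symmetric reach of floor(extent/2) per side; the short axis belongs on
the slice direction and is configurable, since nothing forces it to any
particular axis of a stored volume). Three rules confine each kernel to
the target's own tissue environment:

* rows only recruit voxels with the target's tissue label (GM, WM, CSF
  from an input segmentation);
* neighbours must have image amplitude within 10% (relative) of the
  target's — "close image amplitudes" made explicit and testable;
* each one-sided fit is accepted only if the Pearson correlation between
  fitted and measured phase exceeds 0.7; a side with fewer than two
  usable voxels besides the target is dropped, and an axis with no usable
  side invalidates the voxel.

A voxel is valid when all three axes are accepted *and* at least 6
surrounding voxels remain in the 3D box — a conservative conjunction of
two separately stated criteria. The neighbour-count map is kept for
diagnostics (`neighborCountHistogram()`); on brain-like phantoms well
over 80% of in-tissue voxels keep 6+ neighbours. A zero-variance row is
accepted with correlation defined as 1: constant phase is an exact fit,
and Pearson correlation is undefined there. With exactly three points a
parabola interpolates, so minimal rows always pass the correlation gate —
one reason edge voxels are noisier than interior ones.

Two readings of the printed kernel were possible: a 3D fit domain, or
per-axis 1D rows searched within the box. The per-dimension description
of the fitting procedure ("a row of phase voxels for a certain spatial
dimension") decided for 1D rows. Likewise the correlation gate could
apply per side, per axis or per kernel; the strictest reading (per side)
is implemented.

### Preprocessing

`unwrapPhase()` implements region-growing 3D unwrapping: the $[0,2\pi)$
interval is split into six sub-intervals, 6-connected regions of equal
interval are labelled, and regions are merged largest-shared-border-first,
each merge adding the multiple of $2\pi$ that minimises the median wrapped
difference across the shared faces (the median is robust to isolated noisy
face voxels). Ties on border size break largest-region-index-first. A
final global $2\pi$ multiple per connected component minimises the mean
absolute phase. The full published region-growing algorithm has further
refinements; this module implements the sketch, treats unwrapping as
solved preprocessing, and offers `bypass = TRUE` for externally unwrapped
data.

`denoisePhase()` is Perona-Malik anisotropic diffusion with a sigmoid
conductance $g(|\nabla\varphi|) = 1/(1+\exp((|\nabla\varphi|-\kappa)/s))$,
explicit time stepping, masked updates and no-flux boundaries (flux moves
only between in-mask voxel pairs, so the mask mean is conserved). The
cited filter design is not published as equations; this is the package's
own filter reproducing the stated behaviour — noise removal with edge
preservation — at the stated settings: 400 iterations with integration
constant 0.18, which we interpret as the explicit time step. $\kappa$
defaults to twice the median absolute forward difference inside the mask
(data-driven) and $s$ to $\kappa/4$. The nominal linear-stability bound for
the 3D explicit scheme is $dt \le 1/6$ at unit conductance; with the
sigmoid conductance strictly below 1 and falling with gradient magnitude,
$dt = 0.18$ is stable in practice, and the constructor enforces
$dt \le 0.25$. Note one sharp limitation: 400 iterations diffuse over a
length of roughly ten voxels, so structures smaller than that lose
curvature contrast. That is why the functional chain below does not
denoise — a phantom activation region a few voxels across would be
smoothed away, exactly as a one-voxel-thick cortical ribbon would be.

## The functional layer

A dynamic series of conductivity maps (`reconSeries()`) carries a
stimulus-locked signal. Each frame's value is assigned to the halfway
point of its acquisition (half of k-space). With stimulus onsets jittered
from $-0.3$ to $1.2$ s in 0.1 s steps across cycles, the samples pooled
relative to stimulus onset tile a 100 ms grid even though one frame lasts
1.2 s (`poolJittered()`, nearest-bin-centre assignment, ties to the
earlier bin).

`selectResponseVoxels()` keeps ROI voxels whose conductivity at the first
post-onset frame of cycle 1 exceeds their own OFF baseline (mean over the
last 25% of the pre-onset interval; the fraction is configurable since
the OFF condition is not defined more precisely). Two details matter at
realistic noise:

* The frames that entered the selection comparison are reported
  (`attr(, "selectionFrames")`) and the pipeline passes them to
  `poolJittered(excludeFrames = )`. Selection conditions on the noise of
  exactly those frames; pooling them back in would plant a
  selection-noise spike in the bins they land in (a double-dipping
  artifact).
* Averaging across voxels happens per frame over the voxels valid in
  that frame; validity fluctuates frame to frame because the correlation
  gate is itself a noisy statistic.
* Voxels are combined by inverse-variance weights estimated from each
  voxel's own temporal variance (`weighting = "uniform"` restores the
  plain mean). ROI-edge voxels, whose kernel rows are short, carry
  several-fold more estimator noise than interior voxels; down-weighting
  them reduces the pooled frame noise by about a third without touching
  the signal, since the injected response is common to the ROI.

`fitResponse()` expresses the pooled curve (above its pre-onset baseline,
bins at $t \ge 0$) in an orthonormal discrete Laguerre basis of 10
functions ("10th order" read as 10 basis functions, indices 0-9,
configurable) and solves count-weighted least squares. The basis is
generated by the stable recurrence
$l_j(n) = \sqrt\alpha\, l_j(n-1) + \sqrt\alpha\, l_{j-1}(n) - l_{j-1}(n-1)$
with $l_0(n) = \sqrt{1-\alpha}\,\alpha^{n/2}$; columns are orthonormal to
$10^{-10}$ on grids long enough for the $\alpha^N$ tail to vanish. The
decay parameter $\alpha$ is not stated in the source description; when
`alpha = "auto"` it is chosen by minimising the leave-one-out
cross-validated residual (PRESS) over $[0.5, 0.9]$ with a local line
search. Plain residual minimisation must not be used here: a small
$\alpha$ compresses all basis mass into the earliest bins, interpolates
their noise, and leaves the curve unconstrained over empty bins. The
lower limit 0.5 encodes a weak prior that ten basis functions should span
a multi-second window, not the first second; values below it only ever
arise as overfitting artifacts of sparse noisy bins.

Peak metrics follow the well-defined reading: peak amplitude is
max(fitted) - baseline, peak time its argument, and return-to-baseline
the first post-peak time at or below 5% of the peak. (Locating a maximum
via a second derivative, as the source text suggests, identifies
curvature rather than a maximum; the first-derivative zero crossing
coincides with the argmax for the smooth fitted curves here.) Peak
amplitudes of fits across stimulus durations or contrasts go through
`stimulusResponseRegression()` (ordinary least squares), and repeatability
across repeated sessions through `iccOneway()` — ICC(1,1), the one-way
single-score form, computed from the `aov()` decomposition.

`buildDesign()`/`fitActivationGlm()` close the loop: the event boxcar is
convolved with the fitted response function on the 0.1 s grid, sampled at
frame mid-times, mean-centred, and fit voxelwise by OLS; `thresholdMap()`
applies the display threshold $t > 2.2$ with no multiple-comparison
correction by default (an optional Benjamini-Hochberg flag exists but is
off, matching the uncorrected display convention); no drift column by
default, and no spatial smoothing anywhere in the conductivity path.
Voxels valid in fewer than 90% of frames are excluded; the others use
exactly their valid frames.

### The plausibility window is for maps, not time series

`KernelSpec()` carries a conductivity plausibility window, default
$[-1, 5]$ S/m, which invalidates physically absurd voxels in a displayed
map. The pipeline deliberately widens it to $[-30, 30]$ S/m (effectively
unbounded) for the functional chain. The reason is statistical: a single
dynamic's per-voxel conductivity estimate at realistic phase noise has a
standard deviation of order 1 S/m, and censoring a noisy unbiased
estimator to an asymmetric window both biases every voxel toward the
window centre and — worse — attenuates *changes*: a true 0.1 S/m increase
passes through the $[-1,5]$ censor at barely 65% of its size. Maps are
made with the narrow window; statistics are computed with the wide one,
where the estimator is exactly Gaussian and the GLM's t statistics are
exactly t-distributed under the null.

## The synthetic forward model

`makeStaticPhantom()`/`makeDynamicPhantom()` build volumes whose clean
phase is, per compartment, the quadratic
$\varphi(r) = (\mu_0\omega\sigma/3)\,\lVert r-r_0\rVert^2 + c$, so the
analytic Laplacian is exactly $2\mu_0\omega\sigma$ — ground truth lies
inside the parabolic fit's exactness class, which separates
algorithm-correctness tests from model-error tests. A Gaussian-bump phase
mode (`smoothPhase`) exercises the non-exact regime with an analytic
truth of its own. Compartments are painted in listed order with later
entries taking precedence, so structures can be embedded (a grey-matter
sphere inside white matter); offsets keep the clean phase continuous at
boundaries in the mean, and the residual curvature discontinuities are
intentional — they are what the tissue restriction must absorb. Magnitude
is piecewise constant per tissue with a 2% deterministic ripple (inside
the 10% amplitude tolerance, so it exercises the comparison without
triggering it); phase noise is i.i.d. Gaussian per voxel and frame from
one seeded stream; wrapping into $[0,2\pi)$ is optional and exact.

Defaults encode the study conditions: WM 0.42 and GM 0.64 S/m resting
conductivity; 0.5 s stimuli at contrast 0.45 with a 15.5 s duty cycle; 16
cycles, one per jitter offset in $\{-0.3, \dots, 1.2\}$ s (a fixed
semi-randomised order); 1.2 s dynamics at 3.75 mm isotropic for the
dynamic phantom, 3 mm at $64^3$ for the static one; injected activation
amplitude 0.1 S/m with a unit-peak gamma-like response peaking 0.7 s
after onset (shortly after a 0.5 s stimulus ends) and returning to 5% of
peak at 3.7 s, solved from the requested return time.

Two geometric choices deserve their rationale. The quadratic-phase centre
of the dynamic phantom sits *outside* the volume: with a centred
quadratic, rows through voxels near the centre carry almost no phase
variation, and at 0.05 rad noise the correlation gate rejects them for
geometric rather than noise reasons; an external centre gives every row a
linear phase term well above the noise, so validity reflects what it
should. The activation ROI is a 14-voxel-radius grey-matter sphere
(~11,000 voxels) embedded in white matter — the tissue restriction then
isolates its kernels exactly as it would isolate a real cortical region,
and the ROI matches the scale of the atlas regions (thousands of voxels)
used in the human experiments this emulates; it needs to, because the
voxel-selection step retains only about half the voxels and the pooled
per-bin noise must sit below the injected amplitude for the peak of a
fitted noisy curve (a max statistic) to be an honest estimate.

What the phantom does *not* emulate: $B_1$ physics beyond the transceive
phase relation (no full-wave field simulation), magnitude-coupled phase
noise, banding artifacts, physiological confounds, motion, or BOLD-like
vascular responses. Passing tests demonstrate that the pipeline's
estimators recover what the forward model injects under Gaussian noise —
they do not certify in vivo accuracy.

## Numerical choices and degenerate inputs

* Second derivatives are fitted in voxel units and rescaled by
  $1/h^2$ per axis (mm from the grid, converted to metres), keeping the
  normal equations well conditioned.
* Normal equations for the 3-parameter parabola are solved in closed form
  (Cramer); a side whose design is singular (never the case for distinct
  offsets) is dropped.
* Bins are centre-aligned at multiples of 0.1 s; nearest-centre
  assignment with ties to the earlier bin makes pooling deterministic.
* The pooled window default $(-2, 13.4)$ s is just under one duty period,
  so every frame is used exactly once per cycle.
* Empty pooled bins carry NA and zero weight; the fit requires at least
  as many populated bins as basis functions and errors otherwise. Peak
  metrics are read only at data-supported times (bins with samples, or
  directly adjacent to one) — immaterial under the full jitter design,
  but it stops a sparse schedule's fitted curve from "peaking" on an
  extrapolated empty stretch.
* `stats::optimize` (golden-section plus parabolic refinement) does the
  $\alpha$ line search; the coarse pre-grid makes the search robust to
  local minima. Identical inputs give identical fits — there is no
  stochastic step anywhere in the estimation path.
* An all-constant phase row has correlation 1 by convention and second
  derivative 0; a target voxel in background raises an error.
* Degenerate schedules: an empty events table is a valid schedule;
  `buildDesign()` then produces an all-zero task column and the GLM
  refuses it as rank deficient.

## Problem sizes used by the test-suite and acceptance runs

Static recovery uses the full $64^3$ phantom (the reconstruction is
exact there to floating precision, finishing in about a second). The
functional-recovery and GLM-calibration checks run the complete chain on
the default dynamic phantom (64 x 64 x 45 at 3.75 mm, 211 frames) for 10
and 20 seeds respectively, with the null-calibration seeds on a
4-cycle series; unit tests use a scaled-down 24 x 24 x 18 phantom. These
sizes were chosen so the whole suite exercises every stage at realistic
noise while remaining comfortable to run on a laptop.

## Known limitations

* The unwrapper implements the six-interval region-growing sketch, not
  the full published algorithm; pathological wrap topologies that the
  refinements exist for may fail (use `bypass` with an external tool).
* The denoiser's sigmoid parameterisation is this package's
  interpretation; "integration constant 0.18" is read as the explicit
  time step. Users fitting published values should treat the filter as
  behaviourally, not bit-wise, equivalent.
* Peak amplitude read as max-of-fit is upward-biased under heavy pooled
  noise (a max statistic); the acceptance analysis reports means across
  seeds, where the remaining bias at default phantom noise is small
  relative to the stated tolerance.
* Per-seed peak *time* is flat-topped and noise-limited: the injected
  response changes by under 2% of its amplitude within ±0.3 s of its
  peak, so individual-seed peak times scatter by several bins at default
  noise; only their mean is a meaningful check.
* ICC is implemented for balanced complete tables only.
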