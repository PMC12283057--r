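---
title: "Simulating and analysing dual-FOV zero-TE MB-SWIFT fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing dual-FOV zero-TE MB-SWIFT fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dualswift)
```

## The problem this package addresses

Simultaneous functional MRI of the brain and the lumbar spinal cord is
normally defeated by the impossibility of shimming two distant regions at
once: echo-planar readouts need a water linewidth of tens of hertz, which a
single shim cannot deliver over both fields of view. Zero echo time (zero-TE)
sequences such as MB-SWIFT (Multi-Band SWeep Imaging with Fourier
Transformation) sidestep this because the readout starts essentially at
excitation with a very high bandwidth per voxel: line broadening is tolerated
up to `bandwidth / matrix_size` — 192 kHz / 64 = 3 kHz under the default
protocol — so an "average" shim over both targets suffices. Acquiring two
fields of view (FOVs) through two independent transmit-receive coils,
interleaved spoke by spoke, gives virtually simultaneous brain and cord time
series at a common 3-s volume rate.

`dualswift` implements a desk-scale, end-to-end *simulator and analysis
pipeline* for this experiment: it encodes the dual-FOV sequence timing,
renders ground-truth dual-organ phantoms with block-design hemodynamic
responses, forward-models the interleaved 3D-radial k-space sampling,
reconstructs the image series (RF-pulse deconvolution, spoke apodization,
density-compensated gridding, FISTA), and runs the functional statistics
chain (centre-of-mass motion estimation and translation correction,
ICA-based motion-component regression, high-pass filtering, AR(1)
prewhitening, voxelwise GLM with a gamma-variate impulse response, cluster
extraction, and group-level sign-flip permutation inference with
threshold-free cluster enhancement). Because every stage consumes synthetic
data with known ground truth, each stage's claims are testable: effect
sizes, latencies, motion, noise levels and false-positive rates are
recovered quantities, not visual impressions.

## The acquisition model

One repetition time `tr_pair` (default 1.94 ms) covers two spokes: the
readout gradient is held at one orientation while FOV 0 and then FOV 1 are
excited `tr_pair/2` apart, so the two organs are sampled within about 1 ms
of each other and the k-space centre — which carries the functional
contrast — is revisited on every spoke for both FOVs. A volume needs
`n_spokes_per_volume` (default 1547) orientations, giving the 3-s volume
rate (1547 x 1.94 ms = 3.001 s); 248 volumes span the 744-s paradigm.

Spoke orientations follow a single pole-to-pole spherical spiral per volume
(uniform steps in the polar cosine, azimuth advanced inversely to the local
circumference). The published protocol states only "spiral trajectory"; the
single continuous spiral is the simplest scheme matching that description
with near-uniform angular coverage, and the same direction set is reused
for every volume (no inter-volume rotation is mentioned in the protocol, so
none is modelled). For FOVs of different sizes the readout-gradient
amplitude per FOV scales as 1/FOV, which the schedule records as a
dimensionless `gradient_scale`.

Each excitation is modelled as an instantaneous excitation followed by a
center-out Fourier readout of the current truth volume: the sample at
radius `j` along direction `d` is the volume's continuous-space Fourier
transform at `k_j = j * dk * d`, up to the prescribed grid's Nyquist
frequency `matrix_size / (2 fov)`. The gapped, frequency-swept fine
structure of the excitation (4 pulse elements, 32 samples per 167.5-us gap)
is carried as timing metadata only; its one computationally relevant
consequence — a spectral weighting along the spoke — can be injected as an
optional `pulse_profile` and is undone by the reconstruction's
deconvolution step. Complex Gaussian noise is added in k-space (standard
deviation expressed relative to the mean DC magnitude), because that is
where measurement noise enters; rigid motion is frozen within a volume and
applied between volumes, matching the volume-level motion correction
downstream.

## Reconstruction

The production Fourier operator is a Kaiser-Bessel gridded NUFFT
(oversampling 1.5, kernel width 5, dense kernel table, separable
deapodization), validated in the test suite against an exact type-II NUDFT
to better than 1e-3 relative error on 16-cube grids; the exact operator
remains available (`nufft_plan(..., exact = TRUE)`) and is the oracle in
all operator tests. A narrower kernel (width 4 at oversampling 1.25) was
measured at ~7e-3 relative error and rejected for missing that bound. The
forward/adjoint pair is an exact transpose by construction and satisfies
the inner-product test to machine precision.

Per volume, the pipeline is: deconvolve the pulse profile (regularised
division `s conj(h) / max(|h|^2, lambda)`), taper the top 25 % of each
spoke with a half-cosine falling to 0.2 (the standard Gibbs-ringing
mitigation for radial acquisitions, at the cost of slight smoothing), and
run 13 iterations of monotone FISTA. The data term is the
density-compensated weighted least squares
`0.5 * || W^(1/2) (A x - y) ||^2` with `W` the radial `|k|^2` weights:
this is the iterative-gridding formulation implied by "gridding + FISTA" —
the DCF-weighted adjoint is both the initialisation and the fixed point the
iteration refines. The unweighted least-squares alternative was measured to
be far from converged after 13 iterations (its normal operator's
conditioning scales with the square of the samples-per-spoke count because
of the radial centre oversampling), whereas the weighted problem reaches
noise-free NRMSE < 0.05 on 16-cube tests within the 13 iterations the
protocol prescribes. The monotone (MFISTA) variant is used so that the
recorded objective trace is non-increasing by construction — a testable
invariant — and the proximal step is a nonnegativity projection (an
optional image-domain l1 soft threshold exists but is off by default, since
the source protocol names no regulariser). The step size is `1/L` with `L`
from a cached power iteration (tolerance 1e-3, at most 50 iterations,
deterministic start).

## The synthetic subject

`make_dual_phantom()` renders FOV 0 as an ellipsoidal head (semi-axes 0.42,
0.36, 0.32 of the grid) containing a lateralised cortical sphere and a
midline cerebellar sphere, and FOV 1 as a cylindrical cord segment (radius
0.14 of the grid) with an activation region confined to one lateral half
and the dorsal half of the cross-section — emulating a response ipsilateral
to a hindlimb stimulus and mostly in the dorsal horn. Baselines are 100
signal units with a smooth seeded texture (+-15 % brain, +-10 % cord).

The stimulation paradigm is 60 s rest then six repeats of 24 s on + 90 s
rest (744 s, 248 volumes at 3 s). The hemodynamic kernel is a gamma density
moment-matched to "delay 2.8 s, variation 1.4 s": mean = delay and SD =
variation, i.e. shape 4 and scale 0.7 s, mode at 2.1 s. This moment
matching is the package's documented reading of a gamma-variate
"delay/dispersion" pair; the original rodent impulse-response reference
gives no closed form. The task response is the boxcar convolved with this
kernel on a 50-ms grid and rescaled to unit peak, so that the phantom's
`effect_size` *is* the peak fractional signal change: 0.5 % in the brain
ROIs and 1 % in the cord ROI by default, the magnitudes reported for this
kind of experiment. Functional contrast is injected phenomenologically as
that fractional change — the inflow physics underlying zero-TE functional
contrast is not modelled mechanistically, because no quantitative inflow
model is available to parameterise.

The cord response is additionally delayed by `latency_shift` (default 9 s)
relative to the brain, emulating the observed slower dorsal-cord
hemodynamics (brain peaking ~9 s, cord ~18 s after stimulation onset);
recovery of that 9-s shift to within one volume TR is one of the package's
acceptance checks. Motion is injected as step events (absolute integer-voxel
displacements holding from a given volume onward), applied by circular
shift so the commanded centre-of-mass displacement is exact.

What the generator does *not* emulate: physiological noise spectra
(respiration, cardiac), rotations, within-volume motion, coil sensitivity
profiles, relaxation and flip-angle effects, and inflow physics. Passing
tests therefore demonstrate correctness of the algorithms under the stated
noise model, not robustness to everything real data can contain.

## Preprocessing

Motion is *estimated* as the displacement of the intensity centre of mass,
and *corrected* by translation-only registration to the first volume (FFT
cross-correlation, integer peak plus per-axis parabolic sub-voxel
refinement, Fourier-shift resampling). Rotations are reported as zero: the
phantom injects translations only, and a full rigid registration would add
a dependency without exercising anything the synthetic data contains.
Volumes whose peak normalised correlation falls below 0.2 are flagged and
passed through.

Spatial ICA (15 components by default) is computed by PCA reduction
followed by FastICA with symmetric orthogonalisation and tanh contrast,
seeded and deterministic. No installed package provides FastICA, so it is
implemented here (~40 lines) and verified by planted-source recovery. The
decomposition is restricted to the object mask dilated by two voxels, as a
brain-masked ICA would be: with whole-volume ICA on radial
reconstructions, the out-of-object noise voxels (the vast majority of the
volume) dominate every component's suprathreshold set and the edge rule
below would label *every* component motion — including the task component,
which measurement confirmed. The dilated rim keeps genuine edge/outside
structure visible to the rule. A component is labelled *motion* when (1) the maximum |Pearson r| between its
time course and any of the three centre-of-mass traces strictly exceeds
0.75, or (2) strictly more than 70 % of its suprathreshold spatial-map
voxels (|z| > 2 within the component map) lie within 1 voxel of the object
boundary or outside it. Both thresholds are read as strict inequalities
(deterministic tie-break), the map threshold |z| > 2 is the package's
documented choice for "spatial map voxels", and the motion parameters used
for rule (1) are the three centre-of-mass traces — the stated motion
estimate — rather than six rigid parameters. Labelled components are
removed by voxelwise projection (with intercept; voxel means restored), an
idempotent step.

High-pass filtering is discrete-cosine-basis regression: DCT terms with
frequency below 0.01 Hz are removed, exact in its passband semantics and
therefore testable. The paradigm's fundamental (1/114 s = 0.0088 Hz) lies
*below* that cutoff; the filter's gain on the task regressor is ~0.5, so
the package (a) always filters the design matrix with the same basis, which
keeps the GLM effect estimates unbiased, and (b) exposes `highpass_gain()`
so the attenuation is reported rather than ignored. Percent-signal-change
time courses are read from the cleaned but *unfiltered* series for the same
reason. Autocorrelation is removed by single-pass Cochrane-Orcutt AR(1)
prewhitening estimated per voxel from first-pass GLM residuals, with the
first sample dropped and coefficients clipped at |phi| = 0.99.

## Statistics

The subject-level GLM regresses each voxel on the filtered task regressor
plus intercept, prewhitened as above; t statistics are mapped to z through
the t CDF at the residual degrees of freedom (z capped at 50 where the
noise-free limit overflows). Subject maps are thresholded at z > 3.1 and
6-connected clusters tabulated (size, peak z, mean z, 0-based centroid).
TFCE is applied at *group* level, matching the published pipeline's use of
permutation inference on group maps; the package reads the ambiguous
phrase "tfce z > 3.1" as plain z thresholding at subject level with TFCE
reserved for the permutation statistic. TFCE uses E = 0.5, H = 2 (the
method's standard defaults; the protocol names the method, not parameters)
with a brute-force threshold sum at dh = 1 % of the map maximum, verified
against a closed form for an isolated voxel and an independent per-voxel
oracle.

Group inference is a one-sample test over subject effect (beta) maps:
sign-flip permutations (exhaustive 2^n for n <= 12 subjects — 256 flips at
the study's n = 8 — else 1000 seeded random flips), statistic = TFCE of the
one-sample t map, and FWE-corrected p at each voxel = fraction of
permutation *maxima* at or above the observed TFCE value; significance at
p < 0.05. The one-sample design is the only group model the experiment's
single-group average supports. Calibration is tested by Monte-Carlo: under
a pure-noise null the family-wise rejection rate over repeated simulated
groups must be 0.05 within Monte-Carlo error.

Peak latency is measured on the block-triggered average of the ROI
percent-signal-change curve at volume-TR resolution (no sub-TR
interpolation), as the mean lag of the near-peak region (block average
within 80 % of its maximum). A plain argmax is degenerate here: a 24-s
boxcar convolved with a 2.8-s kernel saturates into a plateau over which
all values tie to within a fraction of a percent, so under any noise the
argmax lands uniformly at random across ~15 s of plateau. The near-peak
mean equals the argmax for single-peaked curves and shifts by exactly the
injected latency for shifted saturated curves. Percent change is
referenced to the initial 60-s rest (the baseline definition is the
package's documented choice).
Per-subject brain-vs-cord latencies are compared with a paired t test, with
a guarded limit when the differences have zero variance.

## Problem sizes, defaults and calibration

The full protocol (64-cube, 1547 spokes, 248 volumes, two FOVs) is
expressible (`experiment_profile("paper")`) but heavy; the package's
standard synthetic case (`experiment_profile("validation")`) uses a 32-cube
matrix with 387 spokes per volume — chosen to preserve the full protocol's
angular undersampling ratio (1547 spokes is 0.12 of the radial-Nyquist
count pi * 64^2; 0.12 * pi * 32^2 = 387) — the full paradigm, and an
injected transient 2-voxel motion step. The `"fast"` profile (16-cube, 100
spokes, one block) exists for smoke tests. The k-space noise level of the
validation profile was calibrated once, by a sweep over relative noise
levels, so that single-subject cortical cluster statistics land near the
plausibility band reported for this experiment type (cluster-mean z
roughly 4.3-5.8); the calibrated value (5e-4 of the mean DC magnitude) is
then fixed for all tests, including the null-calibration and
parameter-recovery checks. Because the cord response is delayed 9 s
against the single zero-latency task regressor (design-response
correlation ~0.6, further attenuated by prewhitening when the mismatch
dominates the residual autocorrelation), subject-level detection is
strongest in the brain FOV; parameter recovery is therefore measured in
the ground-truth ROIs, and the cortical cluster carries the
cluster-statistics calibration.

Numerical conventions: voxel indices are 0-based with half-open crop
intervals; images are written RAS with voxel size in mm and TR in s in the
NIfTI header; k-space coordinates are cycles/mm (cycles/voxel internally);
all randomness flows from explicit integer seeds through local RNG scopes
that never disturb the caller's RNG state.

## Known limitations

* The swept, gapped excitation is not Bloch-simulated; the pulse profile
  hook exercises the deconvolution step but is not a physical model.
* Translation-only motion correction cannot correct rotations; the
  generator correspondingly injects none.
* The Kaiser-Bessel operator's 1e-3 validation bound is established at
  16-cube and spot-checked, not proven, at larger sizes.
* Sign-flip inference assumes a symmetric null; heavy-tailed or skewed
  subject noise would degrade its calibration.
* The FISTA data term is the density-weighted least squares; with very few
  spokes the weighting amplifies high-frequency noise relative to the
  unweighted problem (the apodization taper counteracts this).
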