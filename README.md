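# dualswift

Desk-scale simulation and analysis of **simultaneous brain + spinal-cord
fMRI** with dual field-of-view (FOV) zero-TE MB-SWIFT acquisitions.

## The problem

Functional MRI of the brain and the lumbar spinal cord *at the same time*
fails with conventional echo-planar imaging: no single shim can give both
distant regions the required field homogeneity. Zero echo time sequences
such as MB-SWIFT tolerate a water linewidth up to `BW / N` (192 kHz / 64 =
3 kHz under the default protocol), so one average shim suffices, and the
3D-radial readout lets two FOVs — excited through two independent coils —
be interleaved spoke by spoke, about 1 ms apart, with the functionally
sensitive k-space centre resampled on every spoke.

`dualswift` implements the full computational chain of such an experiment
on synthetic data with known ground truth:

1. **sequence** — dual-FOV timing and interleaved 3D-radial (spherical
   spiral) spoke schedules; protocol arithmetic (`timing_summary()`);
2. **phantom** — dual-organ 4D digital phantoms: ellipsoidal head with
   cortical + cerebellar activation regions, cylindrical cord with a
   unilateral dorsal activation region; block paradigm (60 s rest +
   6 x [24 s on + 90 s off]); gamma-variate impulse response (delay 2.8 s,
   dispersion 1.4 s); per-FOV effect sizes and response latencies; rigid
   motion events;
3. **acquisition** — interleaved radial Fourier sampling of both truth
   series with complex k-space noise (exact NUDFT and validated
   Kaiser-Bessel gridded NUFFT operators, Rcpp);
4. **recon** — RF-pulse deconvolution, spoke-end apodization,
   density-compensated gridding and 13-iteration monotone FISTA;
5. **preprocess** — centre-of-mass motion estimation, translation motion
   correction, spatial ICA with automatic motion-component labelling
   (|r| > 0.75 with a motion trace, or > 70 % edge/outside map voxels) and
   regression, DCT high-pass (0.01 Hz), AR(1) prewhitening;
6. **stats** — voxelwise GLM (boxcar x gamma IRF regressor), z > 3.1
   cluster tables, threshold-free cluster enhancement (E = 0.5, H = 2),
   group-level sign-flip permutation inference with FWE control
   (exhaustive 256 flips at n = 8), ROI percent-signal-change time
   courses, block-triggered averages, peak latencies and their paired
   comparison;
7. **io / cli** — NIfTI-1 images, YAML configs, onsets and k-space
   containers, a `run_experiment()` orchestrator and a thin CLI
   (`inst/cli/dualswift.R`).

## A worked example

A single synthetic subject under the standard desk-scale conditions
(32-cube matrix, 387 spokes/volume, full 744-s paradigm, calibrated
k-space noise, 0.5 % brain / 1 % cord peak effects, cord response delayed
9 s):

```r
library(dualswift)

cfg  <- experiment_profile("validation")
sim  <- simulate_subject(cfg, subject_seed = 1)       # truth -> k-space -> FISTA
prep <- preprocess_series(sim$recon[[1]], seed = 102) # brain FOV
gl   <- glm_subject(prep$series, prep$mask, sim$paradigm, sim$irf)
gl$clusters$table[1, c("n_voxels", "peak_z", "mean_z")]
#>   n_voxels   peak_z   mean_z
#> 1       66 6.476334 4.263054

tc <- extract_timecourse(prep$series, gl$clusters$labels == 1L, sim$paradigm)
round(c(peak_pct = tc$peak_psc, latency_s = tc$peak_latency_s), 2)
#>  peak_pct latency_s
#>      0.54     15.00

prep2 <- preprocess_series(sim$recon[[2]], seed = 103) # cord FOV
tc2 <- extract_timecourse(prep2$series, sim$phantom$activation_masks[[2]],
                          sim$paradigm)
round(c(peak_pct = tc2$peak_psc, latency_s = tc2$peak_latency_s), 2)
#>  peak_pct latency_s
#>      0.89     24.00
```

The detected cortical cluster (66 voxels, cluster-mean z 4.3) recovers
the injected 0.5 % peak signal change, the cord ROI recovers its 1 %
(0.89 % after reconstruction smoothing), and the cord's block-average
peak occurs 9 s later than the brain's — the injected inter-FOV latency
shift. `timing_summary()` prints the protocol arithmetic (0.97 ms
single-spoke time, 670 us readout per spoke, 3-s volume time, 625-um
voxels, 6-kHz sweep range, 3-kHz linewidth tolerance).

## Documentation

The methods vignette (`vignettes/dualswift-methods.Rmd`) describes the
acquisition and signal model, every tunable parameter with its default and
rationale, the numerical choices (operator accuracy bounds, FISTA
formulation, tie-breaks), what the synthetic data do and do not emulate,
and known limitations.
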