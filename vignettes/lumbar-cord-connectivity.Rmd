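---
title: "Resting-state connectivity of the lumbar spinal cord: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state connectivity of the lumbar spinal cord: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Resting-state fMRI of the lumbar spinal cord asks whether the gray-matter
(GM) horns — the left/right ventral (motor) and dorsal (sensory) columns —
show synchronous spontaneous signal fluctuations. The cord is a hard
target: the cross-section is a few millimetres wide, the field is
inhomogeneous near the lungs, and cardiac and respiratory cycles plus CSF
pulsation dominate the raw signal. `spinefc` implements the full analysis
chain for axial multi-shot acquisitions of this kind (14 slices of 5 mm,
48×48 in-plane grid at 0.43 mm, 200 volumes at a 2.6 s volume time):

1. **Denoising** (`denoise_subject()`): slicewise in-plane motion
   correction; RETROICOR cardiac/respiratory Fourier regressors;
   CompCor-style slicewise principal components from CSF and "not-spine"
   masks; motion parameters; ordinary least-squares nuisance regression;
   zero-phase Butterworth band-pass (0.01–0.10 Hz).
2. **Quality metrics** (`tsnr()`): voxelwise temporal mean over temporal
   SD, summarised over GM in the central 10 slices, after motion
   correction and after full denoising.
3. **Connectivity** (`partition_gm_quadrants()`,
   `network_correlations()`, `seed_correlation_map()`): GM quadrant ROIs
   per slice and within-slice Pearson correlations for the six horn-pair
   networks (ventral–ventral, dorsal–dorsal, two ipsilateral, two
   contralateral ventral–dorsal), plus seed maps.
4. **Group spatial ICA** (`group_spatial_ica()`, `split_half_analysis()`):
   in-plane registration to a target subject, cropping to the 5 slices
   around the lumbar enlargement, two-stage PCA reduction, Infomax ICA at
   50 (cord mask) or 10 (GM mask) components, z-map thresholding,
   GM/WM/noise classification, and split-half Dice reproducibility.

Because raw scans of this kind are rarely shareable, the package ships a
**synthetic phantom** (`phantom_spec()`, `render_subject()`,
`make_cohort()`) with full ground truth, so that every stage above is
testable end to end.

## The phantom's generative model

Each voxel is generated as

```
signal = baseline(tissue) * [ 1 + network + cardiac + respiratory
                                + CSF pulsation + drift ] + thermal noise
```

followed by slicewise in-plane translation of every volume (bilinear
interpolation), exactly the deformation the motion corrector inverts.

* **Geometry.** An elliptical cord (semi-axes 4.3 × 3.4 mm at the
  enlargement) with four GM horn blobs, a 1.3 mm CSF annulus, and
  "not-spine" tissue outside the canal. Cord area peaks at slice 6 so the
  5-slice enlargement crop reproduces slices 4–8; horn size tapers on the
  three most caudal slices, emulating the disappearance of GM below the
  conus medullaris. All structural maps are smoothed with a 0.6-voxel
  Gaussian point spread; thermal noise is not smoothed.
* **Networks.** Four horn latents with correlation matrix
  `default_latent_corr()` (LV–RV 0.478, LD–RD 0.533, ipsilateral 0.478,
  contralateral 0.394), band-limited to 0.02–0.08 Hz. The sampler
  orthonormalises band-limited noise before mixing with a Cholesky factor,
  so the imposed sample correlation is exact at any series length. Each
  horn's latent is a mixture of a cord-wide signal and a slice-specific
  one (`latent_slice_coherence = 0.65`); the mixture leaves the in-slice
  correlation structure untouched but makes the networks segmental along
  the cord, which is what data-driven components of real cord data look
  like, and which makes z-thresholding meaningful (below).
* **Physiological noise.** A pulse-oximeter-like cardiac trace (~1.1 Hz
  with slow rate drift; at a 2.6 s volume time the cardiac fundamental
  aliases to ~0.05 Hz, inside the analysis band) and a bellows-like
  respiratory trace (~0.25 Hz with amplitude variation) drive image terms
  through the same Fourier phase basis RETROICOR uses, with cardiac
  amplitude peaking at the cord/CSF boundary. CSF voxels share two
  temporal pulsation patterns per slice that leak at low amplitude into
  the cord; a slice-wide respiratory term is added in not-spine tissue;
  slow drift is a low-order polynomial.
* **Motion.** Slicewise translations follow a band-limited (≤ 0.025 Hz)
  zero-mean trace — slow postural drift rather than volume-to-volume
  jitter — shared across slices with 35% slice-specific jitter
  (`motion_sd_vox = 0.15` voxels by default).
* **Cohorts.** `make_cohort()` draws 26 subjects: each gets its latent
  correlation matrix jittered (SD 0.10 per entry, re-projected to the
  nearest positive-definite correlation matrix), a small geometric
  perturbation (≤ 1 voxel translation, ≤ 5% scale), and its own seeds.
  Identical cohort seeds give bit-identical cohorts.

## Calibration

The phantom's defaults are calibrated so that the *pipeline's outputs* on
a default cohort land on realistic group values: GM TSNR ≈ 4.3 after
motion correction and ≈ 16.4 after denoising, and group-mean network
correlations equal to `lambda * latent_corr` with
`network_var_fraction = lambda = 0.9` — i.e. VV ≈ 0.43, DD ≈ 0.48,
ipsilateral ≈ 0.43, contralateral ≈ 0.35.

The horn coupling per slice is derived analytically from `lambda`: the
denoised ROI-mean noise is predicted from the thermal SD, the measured
white-noise retention of the two-pass band-pass filter, and the horn voxel
count, times a single calibration constant `roi_noise_calib` that absorbs
what the analytic prediction cannot see (interpolation smoothing from the
two resampling steps, quadrant-vs-horn voxel loss, residual structured
noise). That constant, together with `sigma_thermal` and the structured
amplitudes, was fixed once by small design runs (4 subjects) against the
targets above and then frozen; the 26-subject acceptance run uses the
frozen defaults blind. `scripts/acceptance.R` reproduces that run.

## Numerical choices

* **Motion estimation**: exhaustive sub-voxel SSD grid search against the
  slice temporal mean (one BLAS product per slice), two Gauss–Newton
  refinement steps, one refinement pass against the corrected mean,
  Savitzky–Golay(7,2) temporal smoothing (unbiased for the slow motion the
  phantom plants, unlike a moving average), and a width-3 moving average
  across slices — the rostro-caudal regularisation. Under structured
  physiological noise, intensity excursions mimic apparent motion of a few
  hundredths of a voxel; the planted-motion recovery test covers this
  regime, while the 0.05-voxel noise-floor check uses a thermal-noise-only
  phantom.
* **Band-pass**: Butterworth order 2 per pass, forward–backward, with
  steady-state initial conditions and odd-reflection padding, vectorised
  over voxels; the voxel temporal mean is re-centred exactly and restored.
* **Regression before filtering** is the default order. The property test
  comparing it with filter-both-then-regress shows agreement within 0.04
  (mean within 0.025) rather than a tighter bound, for a quantifiable
  reason: the filtered design spends its ~21 columns inside the ~90
  effective in-band dimensions of a 200-volume series instead of ~199
  full-band ones, absorbing a few percent more in-band signal. This is a
  small-sample degrees-of-freedom effect, not an implementation artifact.
* **TSNR after denoising** uses the motion-corrected temporal mean over
  the denoised, filtered residual SD (the regression/filter leave a
  near-zero-mean residual; the mean is restored so the ratio stays
  defined). Whether the post-band-pass SD or the post-regression SD is
  reported is a convention; this package reports the post-filter variant.
* **Quadrant ROIs**: the GM centre of mass bisects each slice; the three
  columns nearest the vertical split and one row at the horizontal split
  are excluded (the band widens by one column when the centre falls
  exactly between columns, keeping the partition mirror-symmetric).
  Slice averages use plain mean r over the central 10 slices (indices
  3–12 of 14), skipping slices with an empty quadrant; a Fisher-z option
  exists but is off by default. Correlations are bivariate, not partial.
* **Infomax ICA**: natural-gradient updates with the logistic
  nonlinearity on whitened data, random voxel blocks, learning-rate
  annealing on update-direction oscillation plus a 0.99 per-iteration
  decay (which drives the stochastic update floor below the 1e-6 stopping
  tolerance), blow-up restarts, and a deterministic seed. Component signs
  are fixed so each map's peak-magnitude voxel is positive.
* **Component thresholding**: a z-scored map with suprathreshold fraction
  `f` obeys `f * z^2 <= 1`, so `z >= 4` can only ever select < 6.25% of
  the analysis mask. It is therefore used for the granular 50-component
  cord-mask analysis, where single-horn, single-slice components occupy
  ~1% of the mask. Bilateral horn-pair components from the 10-component
  GM-mask analysis occupy ~half their mask and sit near z ≈ 1 by
  construction; recovery tests for that analysis threshold at z ≥ 0.25,
  between the background mode (≈ −1) and the active plateau.
* **Matching**: maximum-weight bipartite matching on the Dice matrix
  (one-to-one, total-Dice-optimal); pairs below Dice 0.1 are reported
  unmatched. Split-half analysis runs the full chain per sub-group with
  the same algorithm seed (the seed is a solver setting, not a group
  property), so identical halves reproduce exactly.

## What the phantom does and does not show

Passing tests demonstrate that the pipeline recovers planted network
structure, physiological noise, and motion under a realistic noise budget
and geometry. The phantom deliberately omits: MR physics (k-space,
T2* decay, susceptibility distortion), within-horn somatotopy, white
matter tracts, non-rigid inter-subject anatomy (subjects differ only by
translation/scale, so registration is exercised but easy), and any claim
about specific human neuroanatomy. Real-data effect sizes are measured,
not planted; the `lambda`-attenuation model that links latent correlations
to pipeline-recovered ones is this package's construct, chosen to make
the connectivity targets an end-to-end check of the whole chain.

## Problem sizes

The shipped tests use the full 48×48×14×200 default phantom for the
26-subject acceptance cohort, compact 7-slice/120-volume variants for
estimator unit tests, a 3-slice/10,000-volume run for the long-series
`lambda`-identity check, and 6-subject cohorts for the group-ICA
properties — sizes chosen to exercise every code path at meaningful
statistical power.

## A worked example

```{r}
library(spinefc)

subject <- render_subject(phantom_spec(), seed = 1)
res <- analyze_subject(subject)

res$denoise$tsnr_moco$summary      # ~4.3
res$denoise$tsnr_denoise$summary   # ~16
round(res$networks$summary, 2)     # VV/DD/ipsi/contra network means

cohort <- make_cohort(26, seed = 1)
group <- run_cohort_pipeline(cohort)
round(group$group, 3)
```
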