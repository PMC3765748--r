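---
title: "Voxel-wise hub connectivity and long-axis volumetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise hub connectivity and long-axis volumetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hubfc)
```

`hubfc` implements a resting-state fMRI analysis in which every voxel is
scored by how strongly it is coupled to the rest of the brain, and group
differences in those coupling maps are tested with cluster-level permutation
inference. It also implements a simple structural companion analysis: a
labelled, elongated cortical structure is cut into thirds along its long
axis and the section volumes are compared between groups. Because no image
data are distributed with the package, a seeded synthetic-cohort generator
reproduces the statistical structure the analysis assumes, and every stage is
tested against it.

## The hub connectivity model

For one subject, let $x_i(t)$ be the preprocessed BOLD series of in-mask
voxel $i$. The weighted degree of voxel $i$ is

$$ d_i = \#\{\, j \ne i : r_{ij} > \theta \,\}, \qquad
   r_{ij} = \mathrm{cor}(x_i, x_j), $$

with $\theta = 0.25$ by default and only positive correlations counted
(global-signal regression can manufacture negative correlations, so the
negative side is not interpreted). The self term is excluded; including it
would add a constant 1 to every voxel and be removed by the z-normalisation
anyway. "Weighted by the number of strongly correlated links" is read as
this binarised link count; a variant that sums the supra-threshold
correlation values is available via `degree_map(weighted = TRUE)` but is not
the default.

Each subject's degree map is then standardised across in-mask voxels,
$z_i = (d_i - \bar d) / s_d$, with the sample ($n-1$) standard deviation.
This within-subject z-normalisation makes maps comparable across subjects
while leaving the spatial topography (the rank order of voxels) unchanged.
An alternative reading — Fisher r-to-z of the correlations before
thresholding — would change nothing after binarisation and was rejected.

## Preprocessing

`run_preprocess()` applies, in order: dropping the first four volumes
(non-steady-state frames), per-voxel linear detrending, zero-phase low-pass
filtering at 0.08 Hz, regression of nine nuisance series (six motion
parameters plus whole-brain, white-matter and CSF means, with an intercept),
Gaussian spatial smoothing at 4 mm FWHM, and resampling to a 4 mm isotropic
analysis grid. Notes on the open choices:

* **Filter design.** The low-pass is a 4th-order Butterworth applied
  forward and backward (zero net phase, so temporal alignment between voxels
  — what correlations measure — is preserved), with odd-reflection end
  padding and steady-state initial conditions. An ideal FFT filter is
  available with `filter_kind = "fft"`. A two-pass 4th-order Butterworth has
  a gradual shoulder: its passband is flat to 1 dB below roughly
  0.7 × cutoff (not arbitrarily close to the cutoff), and its stopband
  attenuation exceeds 20 dB beyond 1.5 × cutoff; the tests assert exactly
  these achievable properties.
* **Nuisance series are filtered like the data.** Detrending and low-pass
  filtering are applied to the nuisance columns before the regression.
  Without this the filtered data retain a component of the (unfiltered)
  regressors that the regression cannot remove, and shared nuisance variance
  leaks into every correlation — in synthetic data this inflated background
  degree dramatically. With matched filtering the regression removes the
  nuisance component exactly (the design also gains an intercept; regressor
  columns rendered constant by the filtering are dropped).
* **Order of smoothing and downsampling.** Smoothing happens at the
  acquisition resolution, then the image is resampled to 4 mm. The 3 mm to
  4 mm factor is not integral, so trilinear interpolation onto a grid
  sharing the source origin is used; an exact block-mean path exists for
  integer factors and is exercised by the tests.
* **Mask.** Voxels with nonzero temporal variance and mean intensity above
  10% of the robust (0.98-quantile) image maximum, estimated on the raw
  post-drop data (the later stages remove the mean), then carried to the
  analysis grid. A caller-supplied mask or `mask_source = "all"` bypasses
  the heuristic.

## Group inference

Two-sample (pooled variance), paired, and simple-regression t maps are
computed per voxel and converted to z scores through the t CDF
(`t_to_z()`, evaluated in log space so large statistics survive). Clusters
are connected components of $\{z > 2.3\}$ under 26-connectivity (6 and 18
selectable), and candidates need at least 10 contiguous voxels.

Cluster-level multiple-comparison correction is by permutation of the
maximum suprathreshold cluster size: group labels are shuffled for
two-sample contrasts; subject difference maps are sign-flipped for paired
and regression tests. Each candidate receives

$$ p = \frac{1 + \#\{\text{perm max size} \ge \text{observed size}\}}
           {n_\text{perm} + 1}. $$

This replaces the Gaussian-random-field cluster correction used by the
common GLM tools: the smoothness estimation that GRF correction requires is
both heavyweight and under-determined here, whereas the permutation test is
exact under exchangeability and reuses the same thresholds (Z > 2.3, 10
voxels). This is a deliberate methodological substitution and is reported as
such.

Degenerate voxels (zero between-subject variance, detected at relative
tolerance $10^{-10}$) get z = 0 with a warning rather than propagating
non-finite values.

The per-patient pain covariate is the change in the scan-level rating, where
each scan's rating is the mean of its pre- and post-scan values; the
regression map tests the slope of the map change on that rating change.

## ROI thirds volumetry

The "long axis" of a labelled structure is the first principal component of
the labelled voxels' world coordinates — the standard, reproducible reading
— with the sign fixed superior (+z). If the two leading eigenvalues are
within 5% of each other the axis is declared non-unique and an error is
raised (a sphere has no long axis). Sections are equal-length intervals of
the projection onto the axis (`method = "count"` gives equal-count tertiles
instead), and "top" is the section with the highest mean world z, matching
the somatotopic reading of the superior third. Volumes are voxel counts
times the affine's voxel volume; with covariates the group comparison is the
group coefficient of `lm(volume ~ group + covariates)`.

## The synthetic cohort

`generate_cohort()` emulates the study design: two groups of 18 subjects;
controls scanned once; patients scanned in a low-pain (LP) and a high-pain
(HP) state; TR 3 s; 120 frames (a 6-minute run); a 24 × 24 × 18 grid of
3 mm voxels with an ellipsoidal brain occupying ~30% of the field of view.
A compact hub region (a 6 × 6 × 3 voxel box by default) carries a shared
latent series: hub voxels are $w\,s(t) + e_i(t)$ with
$w = \sqrt{\rho/(1-\rho)}$, so two hub voxels correlate at $\rho$ in
expectation. Default couplings are 0.4 (controls), 0.3 (LP) and 0.5 (HP)
with a 0.06 between-subject SD, reproducing the qualitative ordering the
analysis is meant to detect (controls above LP, HP above both LP and
controls' deficit direction). Pain-rating changes follow
$\Delta\text{pain} = 1 + 9.5\,(\rho_{HP} - \rho_{LP}) + \varepsilon$,
$\varepsilon \sim N(0, 0.8)$, giving a mean increase of ~2.9 points on the
0–10 scale from LP ratings centred at 3.8 — the magnitudes the study
design targets. A per-subject flag (`resting_subjects`) forces
$\Delta\rho = 0$ to emulate a patient who rested instead of exercising.
Pre/post scan ratings are the scan-level rating plus small jitter (SD 0.3);
the analysis consumes their mean.

Noise is AR(1) with coefficient 0.3 and unit marginal variance, plus a
linear drift (peak-to-peak 2 in units of the noise SD) and a random-loading
mixture of the written nuisance series — the minimal structure that makes
detrending, filtering and nuisance regression consequential. None of this
models hemodynamics or physiological (cardiac/respiratory) noise; passing
tests demonstrate the pipeline's statistical behaviour under its own
assumptions, not performance on real scanner data.

Label volumes are mirror-symmetric ellipsoid pairs (40 mm long axis,
10.5 mm radius, 1.2 mm voxels — the bilateral top third then measures about
4.8 cm³, a realistic scale), with the patient group's top third inflated by
a factor 1.13 in volume and a per-subject lognormal-like size jitter at 17%
CV so the between-subject spread matches the effect-to-noise ratio the
volumetric comparison faces.

## Calibration at reduced scale

Two properties are measured by simulation: the family-wise false-positive
rate of the cluster correction under pure noise (200 cohorts of 18 vs 18)
and the recovery of a planted coupling increase (0.3 → 0.5 in a 50-voxel
hub, 50 paired cohorts). Running the full image pipeline for the 9,000-odd
subject maps involved would be disproportionate, so `calibrate_fwer()` and
`planted_effect_recovery()` use a reduced harness
(`simulate_subject_zmap()`) that synthesises subjects directly at the 4 mm
analysis grid:

* Temporal structure: an AR(1) series ideal-low-pass filtered at 0.08 Hz
  lies exactly in the passband subspace — 27 cosine/sine pairs for 116
  frames at TR 3 s — so each voxel is simulated as 54 Fourier coefficients
  with the AR(1) spectrum's SDs. Pearson correlations between voxels equal
  the correlations of these weighted coefficients, so degree maps have
  identical statistics at less than half the cost.
* Spatial structure: Gaussian smoothing with sigma 0.68 analysis voxels,
  calibrated once so the harness's null z maps match the full pipeline's
  z-map neighbour correlation (~0.37, measured on pipeline-processed
  synthetic scans) — the quantity that governs null cluster sizes.
* Hub planting: the shared latent is added *after* the spatial smoothing,
  scaled per voxel, so that the tested voxels' pairwise correlation is the
  nominal coupling. Planting before smoothing (as the acquisition-stage
  generator does) lets spatial averaging inflate the realised coupling far
  above the nominal value — at 0.3 and 0.5 alike the analysis-stage
  correlations then saturate the 0.25 link threshold, and the two conditions
  become indistinguishable in the degree map.
* The temporal preprocessing stages (detrend, nuisance regression) are
  linear and preserve the null, so they are skipped; the full chain is
  exercised end to end on smaller cohorts elsewhere in the test suite.

### Detectability of coupling contrasts

The recovery simulations expose a genuine limitation of thresholded degree
mapping at this acquisition scale. With ~54 effective temporal degrees of
freedom (116 frames low-passed at 0.08 Hz), the per-link probability of
crossing r = 0.25 rises by only ~0.33 when a 50-voxel hub's coupling rises
from 0.3 to 0.5, and part of that is absorbed by smoothing-induced
saturation of nearby pairs. The resulting shift in the hub's mean z is
about 0.3 SD — while the per-scan sampling noise of the hub mean z is about
0.85, because the correlation errors of all intra-hub pairs share the same
latent realisation and fluctuate coherently. A paired design with 18
subjects then sees per-voxel t statistics near 1.2, and the corrected
paired contrast detects the hub in only ~20% of replicates (the regression
slope sign is recovered in ~78%). Much larger coupling contrasts (e.g. 0.15
vs 0.70, as in the packaged end-to-end example) are detected reliably. The
power simulations report what the machinery actually delivers under these
conditions; they are not tuned to a desired rate.

One subtlety is documented rather than hidden: under these study conditions
the null group maps' largest suprathreshold cluster is only a few voxels, so
the 10-voxel candidate filter removes every null candidate and the filtered
procedure's family-wise error is essentially zero — safe, but uninformative
as a calibration check. The FWER calibration therefore runs the correction
with `min_voxels = 1`, measuring the permutation mechanism itself; the
candidate filter can only remove candidates, hence only lower the rate. The
planted-effect recovery uses the full analysis defaults (including the
10-voxel filter), since planted clusters comfortably exceed it.

## Numerical choices and degenerate inputs

* Degree uses strict inequality ($r > \theta$); ties at the threshold are
  excluded. Zero-variance series are flagged, set to zero, and receive
  degree 0.
* Blocked degree computation is exactly independent of the block size and is
  tested against a naive per-pair oracle.
* Peak ties within a cluster are broken by the lowest linear voxel index.
* Permutation p values live on the grid $k/(n_\text{perm}+1)$ with floor
  $1/(n_\text{perm}+1)$.
* World coordinates in reports are whatever the input affine defines; the
  package performs no registration, so they are standard-space coordinates
  only if the inputs were registered upstream.

## Problem sizes in the tests

The packaged suite runs on one CPU in tens of minutes: the FWER calibration
uses 200 cohorts at n = 18 per group with 99 permutations each; the
planted-effect recovery 50 paired cohorts; oracle-equivalence checks 50
random instances up to 200 voxels; end-to-end runs use compact grids
(16 × 16 × 12, 80 frames, 8 subjects per group) that the planted effect
still dominates. Full-size cohorts (24 × 24 × 18, 120 frames, 18 + 18
subjects) run through the same code paths.

## Known limitations

* The generator's noise model is stationary Gaussian; real BOLD data carry
  physiological rhythms, motion artefacts and scanner drifts richer than a
  linear trend. Results on the synthetic cohorts validate the machinery,
  not its behaviour on any particular scanner.
* Slice-timing correction, motion correction and registration are out of
  scope; inputs are assumed aligned (the generator constructs them aligned,
  and motion parameters enter only as nuisance regressors).
* Anatomical labelling of cluster peaks is not attempted; region names in
  report tables are caller-supplied free text.
* The permutation correction assumes exchangeability under the null
  (group-label shuffling) or sign-symmetric subject effects (sign
  flipping); strong distributional asymmetries would degrade its
  calibration.
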