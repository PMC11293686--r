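---
title: "Quantifying thymic vasculature: models, estimators and phantom validation"
author: "ThymoVasc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying thymic vasculature: models, estimators and phantom validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ThymoVasc)
```

## Scope and scientific setting

ThymoVasc quantifies the microvasculature of the thymus from two kinds of
two-photon data:

* **intravital time-lapse movies** of Evans-blue labelled cortical vessels,
  in which circulating red blood cells (RBCs) appear as *negative-contrast*
  (dark) objects against the bright plasma, recorded at roughly
  0.31 µm/pixel and 30/60/120 frames per second; and
* **3D stacks of optically cleared whole thymus lobes** with
  antibody-labelled vasculature and anisotropic voxels.

From the movies it measures blood-flow velocity, vessel diameter, wall
shear rate and Evans-blue leakage; from cleared volumes it measures vessel
diameter, vessel frequency (segments per mm² of organ) and Otsu vessel-area
fraction inside randomly sampled fields of view (FOVs) restricted to a
peripheral shell of the organ. A statistics layer compares an untreated
group against a sublethally irradiated (SL-TBI) group, the experimental
contrast this pipeline was designed around.

No imaging data ship with the package. Instead, the synthetic-phantom
module generates ground-truthed stand-ins for both data types, and the test
suite scores every estimator against that truth. This vignette records the
models, the tunable parameters, the numerical choices and the places where
the design was genuinely open.

## Conventions

Images are numeric matrices indexed `[row = y, col = x]`, 1-based, so a
point is `(y, x)`; movies are `[y, x, t]` arrays and volumes `[y, x, z]`
with a named `voxelSize` in micrometres. Pixel rectangles are
`(y0, x0, height, width)` covering rows `y0 .. y0 + height - 1`. We use
1-based indexing throughout because every index in the package flows into R
subscripts; a mixed 0/1-based convention is the classic source of
half-pixel bugs in ports between array languages.

## The flow phantom

`flowPhantom()` renders one vessel as a tube of diameter $d$ around a
centreline polyline. The tube edge is an error-function profile,

$$I(r) = I_\text{out} + (I_\text{lumen} - I_\text{out})\,
  \Phi\!\left(\frac{R - r}{\sigma_e}\right),\qquad R = d/2,$$

which has the convenient property that the half-maximum crossing of a
perpendicular profile sits *exactly* at $r = R$, whatever the edge
smoothing $\sigma_e$ (default 2 px; sharper edges are used in tests that
require exact extravascular levels). Extravascular pixels take
$I_\text{out} = I_\text{bg} + \lambda\, I_\text{lumen}$, where $\lambda$ is
the leak fraction, so the leakage ratio of a noise-free phantom with zero
background is $\lambda$ by construction.

RBCs are Gaussian-profile dark disks whose diameter parameter is the full
width at half depth; they advect along the axis at the true velocity with
wrap-around at the ends, spaced evenly with a small seeded offset — the
single-file spacing typical of capillary flow. Per-frame rigid jitter is
i.i.d. uniform in $[-A, A]$ per axis and is recorded exactly in the
`PhantomTruth`, which is what makes registration recovery testable. All
randomness is drawn once under the caller's seed, so identical parameters
and seed give bit-identical output.

Provenance of the defaults: pixel pitch 0.31 µm/px and the
30/60/120 fps set are the acquisition settings of the modelled microscope;
lumen/background/RBC intensity levels, RBC diameter (5 µm), and noise SD
are free parameters of the phantom — realistic choices, *not* measured
values, since the modelled experiments did not report them.

What the phantom deliberately omits: optics (no PSF convolution, no photon
shot noise, no depth attenuation) and physiology (no pulsatility, no
deformable motion). Passing tests therefore demonstrate correctness of the
estimators under the stated image-formation model, not robustness to every
artefact of real intravital data.

## Frame alignment

Frames are aligned by translation only. The estimator is FFT
cross-correlation of mean-subtracted, Hann-windowed frames for the integer
shift, followed by a gradient-based (optical-flow) refinement: the integer
shift is undone, both frames are lightly smoothed (smoothing commutes with
translation, so this debiases the gradients without biasing the shift), and
the linearised residual shift is solved from the normal equations,
iterating up to three times. Whitened phase correlation was rejected
because these scenes are smooth — vessel walls and cell-scale blobs — so
whitening amplifies empty high-frequency bands and the peak collapses. The
published workflow used feature-based alignment; the contract here is shift
recovery, not algorithm brand, and the implementation recovers ±5 px
injected shifts to ~0.05 px at realistic noise (asserted at 0.25 px).

Constant (featureless) frames report shift (0, 0) with a per-frame
low-confidence flag rather than an error. A known limitation, shared with
any registration of these scenes: if the only image structure is the moving
cells themselves, the x-shift of a vessel-parallel scene is confounded with
flow; real recordings contain enough static structure for this not to
matter, and phantom tests use stationary content.

## Velocimetry

Two estimators per vessel, mirroring the two-tier practice of automatic
line-scanning velocimetry with manual cell tracking as fallback:

* **Kymograph streak slope** (`estimateVelocityKymograph`). The movie is
  sampled at unit arc-length spacing along the axis into a space–time
  image; moving cells draw slanted streaks. For each candidate angle
  $\varphi$ the kymograph is projected onto the coordinate perpendicular to
  the streak direction and the weighted variance of unit-bin means —
  directional coherence — is computed; the estimate is
  $v = \tan(\varphi^*)\cdot s_\text{px} \cdot f$ at the coherence-maximising
  angle. The sweep is coarse at 0.25°, then a ±0.5° fine sweep at 0.01°
  with a final parabolic refinement; the fine stage matters because
  $d\tan\varphi/d\varphi$ blows up at the steep angles produced by fast
  flow at 30 fps. Kymographs whose best coherence is below 5% of the total
  variance raise a "no measurable flow structure" error — the condition
  under which the fallback runs (`estimateVesselVelocity`). The failure
  condition is deliberately exposed as a threshold because the original
  workflow's switch to manual measurement was not given a quantitative
  criterion.
* **RBC centroid tracking** (`trackRbcVelocity`). Dark blobs are detected
  per frame by thresholding depth below the median lumen level at half the
  maximum depth, inside a lumen mask eroded by 2 px (the dimmer lumen-edge
  band otherwise masquerades as cells); centroids are depth-weighted.
  Consecutive frames are linked by greedy mutual nearest neighbours inside
  a gating radius of 1.5× the displacement implied by `vMax` (default
  1000 µm/s); ties resolve to the smallest displacement. Each link's
  velocity is the signed arc-length displacement times pixel size times
  frame rate, and the vessel estimate is the mean over links (SD reported
  as dispersion) — velocity is reported per vessel, not per cell. Links
  within an end guard (1× the `vMax` displacement) of either axis end are
  discarded, because cells entering or leaving the field produce spurious
  short links.

Both estimators recover 50–500 µm/s phantoms within 5% at matched frame
rates and agree within 2% on noise-free phantoms; reversing the frame
order negates both.

## Vessel diameter

Diameter follows the cross-line FWHM recipe: perpendicular lines every
`spacing` px (default 2) along the centreline, each profile reduced to a
full width at half maximum, with the vessel diameter the mean of per-line
widths. Choices inside `profileFwhm()` that the width definition leaves
open:

* **Background** is the lower of the two tail means (outer 10% of samples
  at each end). Taking the lower tail protects against a neighbouring
  vessel brightening one side.
* **Crossings** are the *outermost* half-level crossings bracketing the
  global peak, linearly interpolated. Outermost (not innermost) so that
  intraluminal dips from negative-contrast RBCs cannot truncate the width.
  The corollary — a bright neighbour inside the sampled line can extend it
  — is why the cross-line half-length should stay below the typical vessel
  separation (`crossHalfLength` in the morphometry driver, default 12 px).
* Profiles that never fall below the half level on one side raise "vessel
  wider than cross-line"; flat profiles raise "no vessel signal"; failing
  lines are dropped and counted, and at least 3 usable lines are required.

A single-line "manual" mode (`measureManualDiameter`) measures one
user-given segment with the same width rule, standing in for a
straight-line tool measurement; which mode was used is recorded in the
result. Tube phantoms of 4–30 px diameter at arbitrary orientation are
recovered within 0.5 px; a Gaussian profile of scale $\sigma$ yields
$2\sqrt{2\ln 2}\,\sigma$ within 2%. Test tubes are rendered with 2 px edge
smoothing (proportionally less below 8 px so the profile still reaches its
plateau), which avoids grid aliasing inside the ±0.5 px tolerance.

## Shear rate and leakage

Wall shear rate uses the Poiseuille approximation
$\dot\gamma = 8 v / d$ (s⁻¹ for µm/s and µm), computed exactly; the
magnitude is reported with the signed velocity kept alongside.

Leakage is the ratio of mean intensity in a FOV immediately adjacent to
the vessel over a FOV at the vessel centre, on an image averaged over 30
frames (the frame count is recorded). **Orientation matters**: the package
reports extravascular / intravascular. The defining sentence of the source
workflow reads centre-vs-adjacent, but its reported group means increase
after irradiation, which is only consistent with the extravascular signal
in the numerator; the package adopts that orientation, states it in the
class documentation, and never flips it silently. FOVs must be equal-sized,
disjoint rectangles; on noise-free phantoms with zero background the
measured ratio equals the generator's leak fraction exactly, and it is
strictly increasing in the leak fraction under noise.

## Cleared-organ morphometry

The chain is: preprocess → organ mask → distance shell → FOV sampling →
per-FOV measurements.

* **Preprocessing** (`preprocessVolume`): halve y/x by 2×2 block mean per
  slice, 3×3 median ("despeckle") per slice, Gaussian blur σ = 2 px per
  slice, in that order; y/x voxel metadata doubles. Filters are 2D per
  slice, matching the slice-wise workflow this models; the median is exact
  (a vectorised exchange network), so constants pass through unchanged.
* **Organ mask** (`segmentOrganMask`): Otsu on a heavily smoothed copy,
  largest 3D connected component, per-slice hole filling. Intensities are
  clipped at the 95th percentile first so sparse bright vessels cannot drag
  the organ/background threshold up and erode the organ rim. The
  learning-based masking used as one alternative in the original workflow
  is out of scope; manual per-slice polygons are supported as the equal
  alternative and rasterise by the even-odd rule.
* **Distance shell** (`distanceShell`): an exact anisotropy-aware Euclidean
  distance transform (separable lower-envelope algorithm in compiled code;
  oracle-tested against brute force) thresholded at strictly less than the
  shell depth (default 150 µm) — "~150 µm" is implemented strictly because
  the FOV rule is stated as a strict inequality. A "downscaled" fidelity
  mode reproduces the halve-then-upscale shortcut of the original recipe.
* **FOV sampling** (`sampleFovs`): candidate centroids are rejection-
  sampled uniformly from shell voxels under a single recorded seed;
  accepted FOVs are 300×300 µm squares (default) that fit the volume and do
  not overlap previously accepted ones; the retry budget is 10,000
  candidates and failure reports how many were placed. Identical seeds give
  bit-identical FOV sets.
* **Per-FOV measurements**: the FOV's z-slice at the centroid provides the
  Otsu vessel-area percent (256-bin histogram over the FOV's own range;
  foreground over *total* FOV pixels) and the 8-connected component count
  with a minimum-size filter (a 2 µm disk at the working pixel size);
  frequency is count over organ area in the FOV (mm⁻²). Two guards close
  gaps that a by-eye workflow never faced: the histogram is restricted to
  organ pixels when an organ mask is supplied (so a boundary FOV separates
  parenchyma from vessels rather than organ from background), and a
  threshold is accepted only when its between-class/total variance ratio
  reaches 0.8 — pure noise scores about 0.64, so vessel-free FOVs report 0%
  instead of a meaningless split. Diameters are measured per vessel on the
  slice through that vessel's own centreline, on the portion of a supplied
  centreline ROI crossing the FOV footprint; automatic centreline
  extraction is intentionally out of scope, so real data require ROI input
  (phantom truth provides them in tests).

The FOV-count rule is 2D non-overlap of the xy footprints; FOVs at
different depths still may not overlap laterally, which is the conservative
reading of "non-overlapping".

### Problem sizes in the validation suite

Two phantom scales are used, because one grid cannot hold both a mm-scale
organ with twenty disjoint 300 µm FOVs and 8 µm vessels resolved finely
enough for FWHM:

* a **whole-lobe-scale** phantom (256³ voxels at 10 µm, organ semi-axes
  1150×1150×550 µm) exercises the sampling constraints — twenty disjoint
  300 µm FOVs with centroids strictly inside the 150 µm shell, reproducible
  under seed;
* a **capillary-bed** phantom (1/3 µm raw voxel, pancake organ of
  165×165×10 µm semi-axes) packed with 8 µm vessels oriented along z — so
  every slice is crossed by many lumina, as in the cortical plexus — plus
  three in-plane vessels as diameter ROIs. On it the chain recovers the
  true mean diameter within 10% and the true vessel volume fraction within
  3 percentage points. Vessels below ~12 px width would inflate the Otsu
  area (the threshold sits below the half level when edge pixels are a
  large share of the histogram), which is why the validation voxel size
  keeps vessels at 12+ px; the same caveat applies to real data and is
  inherent to the published area recipe, not to this implementation.

## Statistics and reporting

`compareGroups` reproduces the two-group testing convention: Shapiro–Wilk
at α = 0.05 per group (constant samples count as non-normal); both normal →
two-sided unpaired Student's t-test; otherwise a two-sided Mann–Whitney U
whose p-value is computed by full enumeration of rank assignments for
combined n ≤ 20 — exact under ties, unlike the usual normal fallback — and
by the tie-corrected normal approximation above that. Group means, SDs and
the percent difference relative to the reference (untreated) group are
reported; positive percent difference means a reduction, so the 27.7%
thymus-size contraction is positive by convention. No multiple-testing
correction is applied, matching per-metric reporting. `gridAreaFraction`
scores an organ footprint on a gridded reference with fractional per-cell
coverage. `buildReport` assembles per-metric comparisons with the
`*p<0.05 … ****p<0.0001` annotation convention, dot plots, and CSV/JSON
summaries; metrics missing or with n < 3 in either group are skipped with a
warning.

The known inferential limitation is inherited deliberately: vessels are
pooled across animals (the unit of analysis is the vessel or the FOV, not
the mouse), so p-values understate animal-level uncertainty. The record
schema keeps `animal_id` so a mixed-effects reanalysis is possible, but
none is implemented.

### The simulated group study

The end-to-end validation constructs two cohorts with the published effect
directions — wider vessels and higher leakage after irradiation, velocity
differences within noise — using the published group means (velocity
191.8 vs 169.2 µm/s, in vivo diameter 8.9 vs 7.3 µm, leakage 0.4734 vs
0.3278; the cleared-organ frequency phantoms use the ex vivo calibres 7.0
vs 6.3 µm with identical vessel counts). Per-vessel spreads are fixed at
velocity SD 110 µm/s, diameter SD 1.5 µm, leakage SD 0.08 — sized once so
the simulated study reproduces the published significance pattern: with
these spreads the velocity and shear contrasts are genuinely underpowered
(as the published p-values report them to be) while diameter and leakage
are detected essentially always. Sample sizes are 12 vessels per group for
movie-based metrics, 50 for the diameter cohort, and 3 organs × 3 FOVs per
group for frequency, echoing the 3-animals-per-group design. Over 100
seeded replicates the suite requires diameter and leakage significant in
≥90% of replicates, velocity/shear/frequency nonsignificant in ≥90%, and a
false-positive rate near 5% per metric when the cohorts are identical.

## Degenerate inputs and tie-breaks, in one place

Otsu ties resolve to the lowest threshold; constant FOVs report 0% with a
warning; empty detection lists are valid results while "no trackable
cells" and "no measurable flow structure" are errors; featureless frames
align with a low-confidence flag; cross-lines leaving the image are
dropped with a warning, and fewer than 3 usable lines is an error; FOV
sampling failure reports the number placed; the distance transform treats
the array border as foreground (an organ touching the border has no edge
there); zero-length manual lines and zero reference means are errors.

## File formats

Movies and volumes travel as multi-page 32-bit float TIFF with a JSON
sidecar holding physical calibration and an affine intensity code (the
float writer accepts only [0, 1]); masks as 8-bit TIFF; vessel axes and
manual lines as JSON ROIs; alignment shifts and measurement records as
CSV with the schema `animal_id, group, metric, value, units, method,
roi_id, seed, timestamp`.
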