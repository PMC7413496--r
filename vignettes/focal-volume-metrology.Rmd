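---
title: "Focal-volume metrology and image quality in depth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Focal-volume metrology and image quality in depth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focalmetry)
```

## The problem

Two-photon microscopy of living brain tissue degrades with depth: spherical
aberration from the refractive-index (RI) mismatch between the immersion
liquid and the tissue stretches the focal volume, mostly along the optical
axis, which dilutes the excitation photon density and washes out fine
structure. Two practical counter-measures are adjusting the immersion RI
toward the tissue's effective index and trading pupil fill for transmitted
power (an underfilled pupil passes more light at a lower effective NA).

`focalmetry` implements the measurement side of that programme: how large
is the focal volume under a given condition, how much signal and contrast
does an image stack carry, and how strongly do spontaneous calcium
transients register — plus the nonparametric statistics used to compare
conditions, and a synthetic-data generator so the whole chain can be
validated against known ground truth.

## Focal-volume metrology

The focal volume is probed with sub-resolution fluorescent beads (200 nm).
A bead image is a 3D intensity blob; its lateral and axial full widths at
half maximum (FWHM) are measured from one-dimensional intensity profiles
through the peak voxel — a single-voxel-wide line along x for the lateral
width and along z for the axial width. Each profile is fit with

$$ I(u) = A \exp\!\left(-\frac{(u-\mu)^2}{2\sigma^2}\right) + b,
   \qquad \mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma . $$

Two fitting modes exist and are always chosen explicitly:

* `free_center` — all four parameters free; appropriate for clean
  preparations (beads in gel).
* `fixed_center` — the centre is pinned to the peak voxel
  ($\mu \equiv 0$). This encodes the presumption needed for blurry,
  motion-affected beads in living tissue, where the profile peak is taken
  to be the Gaussian centre. Pinning the centre on an off-centre sample
  biases the width upward; the test suite asserts that the free fit never
  has larger residuals than the fixed fit on the same data.

Fits use the Levenberg–Marquardt least-squares routine with moment-based
starting values and box constraints ($A \ge 0$, $\sigma > 0$ bounded by
the window width). A fit is flagged unreliable when its root-mean-square
residual exceeds 20% of the fitted amplitude; summaries drop unreliable
beads. Profiles need at least 7 samples and a peak away from the window
edge. Default profile half-windows are 1.5 um laterally and 4 um axially.

The model-free oracle for all of this is the half-maximum crossing width
(`half_max_width()`): linear interpolation of the two crossings of half
the (baseline-subtracted) maximum. On noiseless profiles the fitted and
crossing widths agree to well under 1%.

Bead detection finds local 3D maxima above an intensity floor after light
smoothing. Two design details matter in practice:

* *Matched smoothing.* Shot noise on a broad axial peak fragments one bead
  into two or three nearby local maxima, which the isolation rule would
  then discard as mutually-too-close "beads". When the caller knows the
  expected widths (`smooth_fwhm`), detection smooths with a Gaussian of
  half those widths (a matched filter); otherwise a light 1-2-1 kernel is
  used. Measurement profiles are always taken from the raw stack.
* *Duplicate merging.* Remaining duplicate maxima closer than half the
  isolation distance are merged, keeping the brightest. Two genuine beads
  that close could never pass the isolation rule anyway, so merging cannot
  promote a real pair into one measurement.

Detections closer than `min_separation` to another detection, or closer
than `border_margin` to a stack face, are flagged not isolated and
excluded from measurement.

Per-condition summaries are arithmetic means with s.e.m. =
sd/sqrt(n); a single measurement reports its s.e.m. as `NA` rather than 0.
`expansion_ratio()` forms deep/shallow ratios of mean widths and reports
them at two decimals and at the conventional one-decimal rounding.

## The condition presets and the RI-mismatch model

The package ships a small table of measured effective widths for an
overfilled and an underfilled pupil at 100, 200 and 300 um depth
(`fwhm_presets()`), with the bead counts behind each mean. Depths between
anchors are interpolated linearly; extrapolation beyond the anchored range
must be requested explicitly (`extrapolate = TRUE`) because sub-resolution
beads could not be measured much past 300 um and the linear extension is
untested territory.

These presets are defined as *measured effective widths* — the convolution
of the true focal volume with a 200-nm bead, plus residual motion — not
deconvolved point-spread functions. The generator therefore targets them
directly (below), and no bead-size deconvolution is applied anywhere.
Measurements from 1.0-um beads are relative indicators only: the package
renders and measures them wider than the nominal widths, axially and
laterally, exactly because their size is not negligible.

For immersion indices away from the measurement condition the package
provides a deliberately phenomenological inflation model,

$$ \mathrm{FWHM}_\text{axis}(n, d) = \mathrm{FWHM}^{preset}_\text{axis}(d)
   \cdot \bigl(1 + g_\text{axis}\, d\, (n - n^\ast)^2\bigr), $$

with optimum $n^\ast = 1.355$ (the midpoint of the empirically best 1.35
and 1.36 immersion adjustments) and default gains chosen so the axial
width inflates 1.3-fold at a mismatch of 0.025 and 300 um depth (axial
gain 1.6 um^-1 RI^-2; the lateral gain is one third of that, reflecting
the much weaker lateral sensitivity). This is a simulator device for
generating plausibly-ordered conditions — quadratic in mismatch,
proportional to depth, exact at the optimum — not diffraction physics; no
absolute width away from the preset conditions is claimed. The invariant
the model must satisfy (and the tests assert) is ordinal: over any RI
grid, the axial width is minimised at the grid point nearest the optimum,
for every depth and fill mode.

Pupil geometry uses the standard entrance-pupil relation
$D = 2\,\mathrm{NA}\, f_\mathrm{tube} / M$ with the 180 mm tube-lens
convention; a 17.4 mm beam on a 25x/NA 1.05 objective fills 115.1% of the
pupil (overfill), a 10.8 mm beam 71.4% (underfill).

## The synthetic-data generator

The generator exists to make every pipeline stage testable with known
ground truth. It emulates, per module:

* **Bead stacks** (`generate_bead_stack()`): beads rendered as anisotropic
  Gaussians whose widths equal the requested effective widths; sampling
  defaults 0.05 um/pixel lateral and 0.25 um/plane axial (a 25 um field at
  512 pixels, and the bead-protocol z-step). Beads larger than 200 nm add
  their *excess* second moment, $(d^2 - 0.2^2)/20$ per axis, so 200-nm
  renders match the preset widths exactly while 1.0-um beads render wider.
  Noise is Poisson (shot) on expected photons plus Gaussian read noise;
  motion is a rigid per-plane lateral translation with 0.05 um SD — a
  surrogate for heartbeat and breathing, whose true magnitude is not
  specified anywhere and is a simulator choice. Bead-to-bead width
  dispersion (`fwhm_cv`, default 10%) reproduces the relative spread
  implied by the published per-condition s.e.m. values (s.e.m. times
  sqrt(n) over the mean is 9–15% across conditions); without it the
  recovered s.e.m. would be unrealistically small. Placement is rejection
  sampling with 10 n retries before failing.
* **Structure stacks** (`generate_structure_stack()`): randomly oriented,
  mostly in-plane filaments of ~1 um diameter with 0.5-um spine-like
  protrusions, blurred by a supplied width pair, plus background and
  noise; the blur-free scene is returned as a contrast reference.
* **Calcium movies** (`generate_calcium_movie()`): disc-shaped cells at a
  bright baseline (default 600 counts — a bright genetically encoded
  indicator under slow, 1–6 s/frame scanning), a dark wiggly vessel band
  with no cell signal, exponential-rise/decay transients confined to
  contiguous subregions of at least 21 pixels, and sub-threshold
  distractor events of at most 20 pixels, included by default so the area
  filter is actually exercised.

All randomness flows from a single integer seed; a fixed seed gives
bit-identical output. What the generator does *not* emulate: optical
sectioning physics, scattering, blood flow, realistic astrocyte
morphology, photobleaching. Passing tests therefore demonstrate that the
measurement chain is correct and unbiased under the stated statistical
model of the data — not that it is robust to every artefact of real
recordings.

## Image quality scoring

The background of a stack is the pooled mean of each plane's `k_lowest`
lowest-intensity pixels (default 100), so a 21-plane stack pools exactly
2100 pixels. "The 100 lowest per plane" is the only reading of the
pooling rule consistent with that published pixel count, and is recorded
here as an interpretation. Signal is each plane's mean raw intensity minus
this background (negative values are reported as-is); both quantities are
invariant to adding a constant to the stack.

Contrast uses the Brenner gradient in its classical form: the raw sum of
squared horizontal differences at a two-pixel offset,
$\sum_{x,y} (I(x{+}2,y) - I(x,y))^2$, with no per-pixel normalisation —
the quantity consumed downstream is always a ratio across conditions
(`normalized_contrast()`), so any constant normalisation cancels.

## Calcium activity extraction

The four-step procedure, in order: (1) subtract the scalar mean intensity
of blood-vessel pixels (pooled over frames, clipped at zero); (2) subtract
the per-pixel minimum-intensity projection as the baseline; (3) binarise
the remaining $\Delta F$ per frame with Otsu's threshold (256 bins
over the frame's range, ties to the lowest threshold); (4) keep connected
foreground components larger than 20 pixels (strictly greater, i.e. at
least 21), 8-connectivity, and merge ROIs from different frames whose
pixel sets overlap, keeping the union and the earliest frame.

Design choices where the procedure was genuinely open:

* Otsu per frame versus on an aggregate image: per frame is the default
  because transients are just that — transient; an aggregate threshold is
  available as `mode = "aggregate"`. The choice is recorded in the ROI
  metadata.
* A frame contributes ROIs only when its Otsu foreground covers at most
  10% of the field (`max_foreground`). Otsu always produces *some*
  threshold; on an event-free noisy frame it merely splits the noise
  distribution, producing a "foreground" of a quarter or more of the
  image that percolates into large spurious components. Spontaneous
  transients are spatially sparse, so a dense foreground identifies a
  frame with nothing to segment.
* $\Delta F$ is reported in raw counts (matching the convention of
  reporting $\Delta F$, not $\Delta F/F$); per-ROI baseline F is
  attached when a baseline image is supplied.

A known limitation, shared with any minimum-projection baseline: the
per-pixel temporal minimum sits roughly two noise standard deviations
below the true baseline, so every $\Delta F$ amplitude carries a
small common positive offset. Ratios of amplitudes between conditions are
therefore compressed toward 1 when the weaker condition's amplitude is
not large against the noise; at the default simulation settings (weak
amplitude about 25 shot-noise SDs) a true four-fold pair reads about
3.6–3.9. Amplitudes below roughly 5 noise SDs are outside the validated
regime altogether.

## Statistics

Pairwise width comparisons use Welch's unequal-variance t-test
(Welch–Satterthwaite degrees of freedom, two-sided), with Bonferroni
correction (multiply by the number of comparisons, cap at 1) when several
immersion indices are each compared against the water reference (1.33).

Condition comparisons over a shared stack use the Friedman rank test with
planes as blocks and the tie-corrected statistic
$$ Q = \frac{(k-1)\sum_j (R_j - n(k+1)/2)^2}
            {\sum_{ij} r_{ij}^2 - nk(k+1)^2/4}, $$
which reduces to the classical form without ties and yields statistic 0,
p = 1 on an all-tied design. Post-hoc all-pairs comparisons use the
Dwass–Steel–Critchlow–Fligner procedure: each pair is re-ranked on its own,
the tie-corrected standardised rank-sum statistic $W^*$ is referred to the
studentized-range distribution with $k$ groups and infinite degrees of
freedom, $p = P(Q_{k,\infty} \ge \sqrt{2}\,|W^*|)$, evaluated with R's
`ptukey`. The implementation is validated against a full permutation
enumeration (all 34,650 assignments at k = 3, n = 4), against exact
Wilcoxon ingredients on tie-free pairs, and for rank invariance under
monotone transforms. The studentized-range reference is asymptotic; at
n = 4 it agrees with the exact permutation distribution to about 0.02 on
well-separated data and more loosely for mid-range p-values — post-hoc
p-values at these sample sizes are indicative, not exact.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use single-bead stacks of
48 x 80 x 80 voxels (12 x 4 x 4 um), 15/11/12 beads per recovery
condition (the published per-condition bead counts), 21-plane structure
stacks of 96 x 96 pixels, and 64 x 64 x 40-frame calcium movies — sizes
chosen so a full validation runs in about two minutes on one core while
every estimate keeps the sample sizes of the study design it emulates.
Every simulation accepts an integer seed, and all pipeline randomness
derives deterministically from the single top-level seed, so identical
configuration plus seed reproduces byte-identical tabular outputs
(verified by manifest checksums in the test suite).
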