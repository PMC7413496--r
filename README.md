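# focalmetry

Quantitative evaluation of two-photon microscope focal volumes and image
quality in depth, for microscopists tuning deep-tissue imaging conditions
(immersion refractive index, excitation-beam pupil fill) and for anyone who
needs a tested, reproducible implementation of the underlying measurement
chain.

In vivo two-photon imaging degrades with depth because refractive-index
mismatch between immersion liquid and tissue induces spherical aberration
that stretches the focal volume, mainly along the optical axis. The focal
volume is probed with sub-resolution (200 nm) fluorescent beads: the bead
image's lateral and axial full widths at half maximum (FWHM) are measured
by fitting 1D intensity profiles through the peak with

    I(u) = A exp(-(u - mu)^2 / (2 sigma^2)) + b,    FWHM = 2 sqrt(2 ln 2) sigma

either with a free centre (clean preparations) or with the centre pinned to
the peak voxel (the presumption used for motion-blurred beads in living
tissue). Around that core the package provides:

* **Optics geometry** — entrance-pupil diameter `2 NA f_tube / M`, beam
  fill fractions, per-condition measured FWHM presets with depth
  interpolation, and a phenomenological depth x RI-mismatch inflation
  model for simulation.
* **Synthetic data** — bead stacks, neurite-like structure stacks and
  calcium movies with known ground truth (shot + read noise, per-plane
  motion jitter, bead-to-bead width dispersion), so every stage is
  verifiable without animal data.
* **Image quality** — lowest-pixel background pooling (k lowest per plane,
  pooled across planes), background-subtracted signal, and the Brenner
  gradient contrast metric with condition-normalised ratios.
* **Calcium activity** — vessel-background subtraction, minimum-projection
  baseline, per-frame Otsu binarisation, connected components, and the
  >20-pixel area filter, with per-ROI dF traces and condition fold changes.
* **Statistics** — Welch's t-test with Bonferroni correction, the
  tie-corrected Friedman test, and the Dwass-Steel-Critchlow-Fligner
  (DSCF) all-pairs post-hoc test on the studentized-range reference.

Multi-page TIFF I/O (with a YAML metadata sidecar for physical sampling)
and validated YAML run configurations round out the pipeline. See the
vignette (`vignettes/focal-volume-metrology.Rmd`) for the methods and the
design decisions, including known limitations.

## Worked example

```r
library(focalmetry)

obj <- objective_spec(25, 1.05)           # 25x / NA 1.05, 180 mm tube lens
pupil_diameter(obj)                       # 15.12 (mm)
fill_fraction(beam_config(17.4), obj)     # 1.151 -> 115.1% of the pupil, overfill

# measured preset focal volume, overfilled pupil at 300 um depth
cond <- condition_preset("S", depth = 300)
psf_preset(cond)
#> PSF: FWHM_xy = 0.530 um, FWHM_z = 4.140 um

# simulate one bead stack at that condition and measure it back
p   <- bead_field_params(n_beads = 1, seed = 42)
sim <- generate_bead_stack(p, psf_preset(cond))
det <- detect_beads(sim$stack, smooth_fwhm = psf_preset(cond))
measure_bead(sim$stack, det[which.max(det$peak_intensity), ], "free_center")
#>     fwhm_xy   fwhm_z reliable        mode
#> 1 0.5782237 4.162157     TRUE free_center

# full recovery study at the published bead counts
conds <- data.frame(fill_mode = "overfill", immersion_ri = 1.33,
                    depth = c(100, 300), n_beads = c(15, 11))
ev <- run_psf_evaluation(conds, seed = 1)
ev
#> Focal-volume evaluation (free_center mode, seed 1)
#>  fill_mode immersion_ri depth mean_fwhm_xy sem_fwhm_xy mean_fwhm_z sem_fwhm_z n_beads
#>   overfill         1.33   100    0.4248157 0.008551186    2.144476 0.06724018      15
#>   overfill         1.33   300    0.5165650 0.018913181    4.198190 0.11493191      11

expansion_ratio(ev$summaries[[2]], ev$summaries[[1]])
#> $lateral 1.22  $axial 1.96  (1-decimal: 1.2 / 2.0)
```

The recovered means sit within two standard errors of the generator's
preset widths (2.16 and 4.14 um axially), and the deep/shallow expansion
ratios recovered from simulation agree with the ratios formed directly
from the preset table (1.29 lateral, 1.92 axial; 1.3 and 1.9 after
one-decimal rounding).

`run_quality_comparison()` and `run_activity_analysis()` drive the
contrast and calcium pipelines the same way; a thin command-line wrapper
lives at `inst/scripts/focalmetry.R`.

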