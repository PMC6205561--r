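---
title: "Modeling and analysing single-cone color percepts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and analysing single-cone color percepts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conepercept)
```

## The scientific problem

An individual cone photoreceptor is colorblind: once a photon is absorbed,
its wavelength is gone. Color arises by comparing activity across the L, M
and S cone classes. When an adaptive-optics system confines a flash to a
single cone, that comparison is impossible, and whatever hue the observer
reports must come from prior information the visual system associates with
that receptor. Experiments of this kind therefore ask: do percepts from
individually targeted cones vary with the targeted cone's spectral class,
with stimulus intensity, and with the composition of the cone's
neighborhood?

`conepercept` implements the complete analysis chain for such experiments —
optical light-capture modeling, psychometric fitting, hue-scaling analytics,
variance decomposition, and perceptual cone-type classification — together
with a synthetic observer so the chain can be exercised, validated and
stress-tested end to end without human or instrument data.

## The light-capture model

A flash never lands on exactly one cone. The model quantifies how far from
that ideal a given geometry sits.

1. **PSF.** The incoherent point spread function is |FFT(pupil)|² for a
   circular pupil of diameter 6.5 mm carrying a defocus wavefront
   W(ρ) = (D/2)(aρ)² with D = 0.05 diopters of residual defocus — a
   conservative figure for a well-corrected adaptive-optics system — at
   543 nm. At these values the Airy core (first minimum at
   1.22λ/D ≈ 0.35 arcmin) is visibly broadened: the defocus peak-to-valley
   is about half a wave.
2. **Stimulus profile.** A uniform 3 × 3 px square (≈0.35 arcmin at the
   0.95°/512 px raster scale of ~0.111 arcmin/px) convolved with the PSF,
   normalized to unit energy.
3. **Apertures.** Each cone accepts light under a Gaussian profile with FWHM
   equal to 0.48 of its inner-segment diameter, the classical psychophysical
   estimate; the 0.40–0.56 plausible range is exposed as
   `aperture_fraction`, and capture declines monotonically across it.
4. **Delivery.** The stimulus is re-delivered on each of 15 frames over the
   500 ms flash (30 Hz). Landing positions are modeled i.i.d. isotropic
   Gaussian about the target. The per-trial *delivery error* is the RMS of
   the per-axis standard deviations of those positions (an isotropic
   collapse of the 2-D scatter; the worse-axis alternative is available),
   and trials with error above 0.35 arcmin are discarded.
5. **Shares.** Per trial, each cone's absorption is the profile–aperture
   convolution evaluated at cone-minus-delivery offsets, summed over frames;
   shares are renormalized over the mosaic so they sum to 1.

Numerically, the profile–aperture convolution is precomputed once per
session on the raster pixel grid and interpolated bilinearly; halving the
pixel size changes capture shares by well under 1%.

With spacing 1.05 arcmin (the observed 9–12 px range at ~1.5° eccentricity),
inner segments at 0.9 × spacing, and delivery jitter σ = 0.2 arcmin, the
targeted cone absorbs ≈75% of the light caught by the mosaic and its best
neighbor ≈6%, a ratio above 12. The neighbor share runs a little below
values reported for real retinas (~8%): a jittered-but-regular triangular
lattice with identical apertures concentrates light better than a real
mosaic with irregular spacing and diameter scatter.

## The synthetic observer

The generator's defaults are the study conditions the analyses assume, not
free dials:

* **Session structure.** Each of 4–6 cones is flashed 10 times at each of
  three intensities, plus 10% blank catch trials, all randomly interleaved.
* **Detection.** Seen with probability Φ(x) = 1 − (1 − g)e^(−(kx/t)^b),
  where k = (−log((1 − a)/(1 − g)))^(1/b) makes Φ(0) = g and Φ(t) = a = 0.5.
  Defaults: t = 0.35 au, b = 2.5, g = 0.05. S-cone thresholds are divided by
  a relative sensitivity of 1/300 — a mid-spectrum probe is roughly 300
  times less effective at exciting S cones — so S-cone trials reproduce the
  elevated-threshold phenotype.
* **Brightness.** Ratings follow ψ = κ(I − I_θ)^n plus Gaussian noise,
  rounded and clamped to 0–5 with a floor of 1 on seen trials (so rating 0
  and "unseen" remain synonymous). Defaults κ = 4.5, I_θ = 0.05, n = 0.7 (a
  compressive exponent, the common regime for small-spot brightness; an
  expansive n > 1 observer is equally representable).
* **Hue scaling.** Each cone holds a latent locus in the uniform appearance
  diagram: its type's mean locus plus isotropic Gaussian scatter
  (`locus_sd`), truncated to the diamond |x| + |y| ≤ 1. Five presses are
  i.i.d. multinomial with P(white) = 1 − saturation and chromatic mass split
  over the positive parts of (−y, +y, −x, +x) for (red, green, blue,
  yellow) — the exact inverse of the UAD axis definitions, so a locus at
  (−0.2, 0.2) yields 20% blue, 20% green, 60% white in expectation. The
  multinomial form is this package's choice: trial-to-trial press
  variability has no published generative model.
* **Type loci.** L cones center near hue −35.6°, M cones near +74.5°
  (reddish-yellow vs green/blue), both at city-block saturation 0.4, S
  toward blue-white. The cone-level dispersion default (0.30 UAD units) was
  calibrated once so that within-type overlap produces leave-one-out
  classification agreement near 79% — the empirically observed rate — and
  then frozen.
* **Independence from intensity.** Hue and saturation are independent of
  flash intensity by default (the empirical finding this analysis chain is
  designed to test); `intensity_coupling` injects a controlled dependence so
  the consistency regressions can be shown to detect it.

What the generator does *not* emulate: temporal dynamics within the flash,
adaptation or criterion drift across sessions, irregular cone spacing and
diameter scatter, eccentricity gradients, and optical factors beyond
defocus (chromatic aberration, forward scatter — the photopic background
minimizes the latter's perceptual influence). Passing tests therefore
validate the *analysis chain* under clean assumptions, not claims about any
particular retina.

## Fitting choices

* **Weibull MLE.** Only t and b are free; g is pinned to the blank
  false-alarm rate and a = 0.5. The binomial likelihood is maximized over
  (log t, log b) by Nelder–Mead from a 5 × 5 multistart grid (t across the
  data range, b in [0.5, 8]); ties resolve to the higher likelihood, then
  the shallower slope. All-seen or all-unseen data leave t unidentified and
  are flagged `converged = FALSE` rather than raised as errors. No lapse
  parameter is modeled.
* **Seen criterion.** "Seen" defaults to rating > 0, the rule consistent
  with 0 anchoring the scale as *not seen*; a stricter > 1 variant is
  available because both conventions appear in the field's reports.
* **Stevens fit.** Nonlinear least squares on seen-trial ratings with
  κ > 0, n > 0, 0 ≤ I_θ < min(I) enforced by transform. With exactly three
  intensity levels of mean data, three parameters interpolate exactly; the
  fit is returned but flagged `degenerate`, as identifiability, not fit
  quality, is the issue at the standard session design.
* **Hue averaging.** Per-cone mean hue is the circular mean over hue-defined
  trials, since arithmetic means are wrong at the ±180° cut; pure-white
  trials (hue undefined) are excluded from hue statistics but *included* in
  mean UAD positions and saturation. The arithmetic variant is available
  for comparison.
* **Variance decomposition.** Hue differences in the mean-square-difference
  statistic are wrapped to (−180, 180]. Because circular means do not
  minimize squared wrapped deviations, the percent variance explained can
  be negative in dispersed configurations; it is reported unclipped. Both
  unfiltered and low-saturation-filtered (<0.1 excluded) variants are
  computed.
* **Post hoc comparisons.** One-way ANOVA per UAD dimension with trials
  pooled over intensities, then Tukey–Kramer all-pairs p-values
  (studentized-range with unequal n); the matrix is symmetric with unit
  diagonal.
* **Classifier.** Linear SVM, soft-margin cost 1: the decision rule is a
  single straight line in the UAD, and nothing motivates a nonlinear
  kernel. No class reweighting is applied, so the boundary inherits the
  training L:M ratio (~2:1); behavior under very different ratios is
  unknown. Agreement is reported under both resubstitution and
  leave-one-out, since the headline protocol behind published agreement
  rates is not standardized, with a bootstrap SE over cones and Cohen's κ
  against chance.

## Problem sizes and determinism

The shipped tests and the acceptance script use a 500-trial capture
simulation, sessions of 5 cones × 3 intensities × 10 reps, and an
end-to-end run of 20 sessions (~96 L/M cones) — comparable to one subject's
dataset and comfortably stable for every statistic reported. Every source
of randomness flows from one master seed through named substreams (mosaic,
observer, optics, bootstrap), so adding draws to one stage never perturbs
another, and full runs are byte-reproducible.

## Known limitations

Thresholds, slopes, and loci are homogeneous within type (only loci get
cone-level scatter); capture-informed detection (effective intensity scaled
by the targeted cone's capture fraction) exists but is off by default;
rods are ignored; the mosaic has no eccentricity gradient. The
photon-count-to-Troland helper takes every calibration constant explicitly
and is deliberately not wired into any pipeline stage, because such
conversions are instrument-specific.
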