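# conepercept

Analysis tools for single-cone color psychophysics: experiments in which an
adaptive-optics scanning laser ophthalmoscope (AOSLO) delivers sub-arcminute
543 nm flashes to individual, spectrally classified cone photoreceptors while
an observer rates each flash for brightness (0–5) and scales its hue and
saturation with five button presses over {red, green, blue, yellow, white}.

The package is aimed at vision scientists who want to run, or stress-test,
the full analysis chain for such experiments without instrument data: every
stage is driven by a synthetic cone mosaic and a synthetic observer whose
generative model mirrors the statistical structure the analyses assume.

## What it computes

* **Light capture** (`compute_psf`, `stimulus_profile`, `capture_fractions`,
  `session_capture_summary`): the retinal light profile of a 3×3 px stimulus
  convolved with a defocused pupil-function PSF, integrated under Gaussian
  cone apertures (FWHM = 0.48 × inner-segment diameter) at each per-frame
  delivery position, with trials filtered at a 0.35 arcmin delivery-error
  cutoff. Reports each cone's share of the total absorbed light.
* **Psychometrics** (`fit_weibull`, `fit_stevens`): frequency of seeing fit
  by maximum likelihood with a Weibull

  Φ(x) = 1 − (1 − g)·exp(−(kx/t)^b),  k = (−log((1 − a)/(1 − g)))^(1/b),

  where g is fixed at the blank false-alarm rate and a = 0.5 defines the
  threshold t (so Φ(t) = 0.5 exactly); and brightness fit by Stevens' law
  ψ = κ(I − I_θ)^n.
* **Appearance** (`uad_from_presses`, `summarize_cone`): the uniform
  appearance diagram x = (ȳ − b̄)/T, y = (ḡ − r̄)/T, city-block saturation
  |x| + |y|, hue angle (undefined for pure white), per-cone aggregation with
  circular hue means, and the <0.1 low-saturation exclusion.
* **Inference** (`percent_variance_explained`, `cone_anova_posthoc`,
  `intensity_consistency`, `neighbor_regression`): percent of between-cone
  variance in hue/saturation explained by cone type,

  %variance = 100·(1 − d(X_c, X_type)/d(X_c, X_grand)),  d = mean |Δ|²,

  per-cone one-way ANOVA with Tukey–Kramer post hoc matrices, regressions of
  percepts across intensity levels and on the number of spectrally nonlike
  neighbors.
* **Subjective classification** (`train_classifier`, `predict_types`,
  `agreement`): a linear SVM predicting L/M identity from mean UAD position,
  scored against objective labels by percent agreement and Cohen's κ, with
  resubstitution and leave-one-out protocols.

## Worked example

```r
library(conepercept)

res <- run_pipeline(default_config(seed = 1), n_sessions = 20)
cat(res$log, sep = "\n")
```

which prints (seed 1):

```
seed: 1
mosaic: 216 cones (L=129 M=78 S=9)
trials simulated: 3300 (300 blanks)
trials after 0.35 arcmin delivery filter: 3300 (discarded 0)
capture: targeted 74.8%, nearest neighbor 6.3% (n = 100 trials)
Weibull t: L 0.348, M 0.347; Stevens n: L 0.66, M 0.70
cone summaries: 100 cones, 99 pass the low-saturation filter
variance explained by type: hue 42.1% (filtered 41.9%), saturation 1.3%
classification agreement: resubstitution 82.3% (kappa 0.598), LOO 82.3%
```

Reading the log: the targeted cone absorbs ~75% of the light caught by the
mosaic (its best neighbor ~6%), the recovered Weibull thresholds sit at the
generating value 0.35 au, brightness is compressive (n < 1), cone type
explains a large share of between-cone hue variance but almost none of the
saturation variance, and mean UAD position alone identifies cone type for
roughly four cones in five — the behavioral signature that hue, not
saturation, carries the cone-type signal.

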