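Package: conepercept
Title: Simulation and Analysis of Single-Cone Color Percepts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing psychophysical experiments in which sub-arcminute
    flashes are delivered to individual, spectrally classified cone photoreceptors
    through an adaptive-optics scanning laser ophthalmoscope. Provides a Fourier-optics
    light-capture model (defocused point spread function, Gaussian cone apertures,
    per-trial delivery-error filtering), maximum-likelihood Weibull frequency-of-seeing
    and Stevens power-law brightness fits, uniform-appearance-diagram hue and saturation
    analytics, a percent-variance-explained-by-cone-type statistic with ANOVA and
    Tukey-Kramer post hoc matrices, and linear support-vector classification of cone
    spectral type from mean percepts. A synthetic cone mosaic and observer reproduce
    the statistical structure of real sessions so the full pipeline can be exercised
    and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
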