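Package: visrecov
Title: Analysis of Stimulus-Specific Recovery from Monocular Deprivation in Mouse V1
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing stimulus-specific recovery of visual cortical
    responses after long-term monocular deprivation. Provides synthesis of
    band-limited contrast-modulated noise movies and drifting-grating trial
    protocols; a synthetic-population generator (inhomogeneous-Poisson spiking
    units with orientation, spatial-frequency and contrast tuning, broad/narrow
    waveform classes and treatment-group effects); per-unit response metrics
    (spontaneous and evoked rates, preferred orientation by vector averaging,
    wrapped double-Gaussian tuning fits, OSI, half-width at half-maximum,
    binocular orientation mismatch, difference-of-Gaussians spatial-frequency
    fits, ocular dominance index, F1 response to contrast-modulated noise and
    semi-saturation contrast); Fourier analysis of intrinsic-signal imaging
    movies; an exact earth-mover's-distance correspondence between
    cross-sectional neural populations with flow heat maps and a diagonal-flow
    chi-square contrast; and group-level statistics (bootstrap standard error
    of the median, Kolmogorov-Smirnov comparisons with Bonferroni correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
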