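Package: fpvs
Title: Frequency-Tagging EEG Analysis for Fast Periodic Visual Stimulation
    Oddball Paradigms
Version: 0.1.0
Authors@R:
    person("FPVS", "Maintainers", email = "maintainers@fpvs.dev",
           role = c("aut", "cre"))
Description: Tools for quantifying steady-state and oddball (category-selective)
    responses in frequency-tagging EEG experiments. Covers the full chain from
    raw multichannel recordings (EDF, BrainVision) through filtering,
    resampling, artifact handling, channel interpolation and symmetric average
    re-referencing, to exact-cycle epoching, FFT amplitude spectra,
    neighbor-bin noise correction, spectral Z-scores, harmonic selection and
    summation, region-of-interest quantification, and group statistics
    (repeated-measures ANOVA with Greenhouse-Geisser correction, FDR-corrected
    post-hoc tests, JZS Bayes factors, split-half reliability and dependent
    correlation comparison). Includes a synthetic FPVS-EEG generator with known
    ground truth for validation, adult and infant 10-10 montage presets, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
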