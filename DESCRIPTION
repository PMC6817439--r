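Package: hp13cmri
Title: Multiparametric Hyperpolarized 13C MRI Analysis with a Digital TRAMP Cohort
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for multiparametric
    hyperpolarized (HP) 13C magnetic resonance imaging of murine prostate
    cancer. Provides a seeded digital-cohort generator emulating 2D chemical
    shift imaging (CSI) of the bicarbonate/CO2 pair, 3D pyruvate/lactate
    metabolite volumes, and multi-b-value diffusion stacks; spatial-spectral
    CSI reconstruction with peak integration and robust noise estimation;
    extracellular pH mapping via the excitation-ratio-corrected
    Henderson-Hasselbalch equation with SNR masking; lactate-to-pyruvate
    ratio mapping with slab matching, Fourier regridding and asymmetric SNR
    rules; mono-exponential apparent diffusion coefficient fitting with
    residual and free-water filters; histologic-index grading and per-lesion
    ROI summaries; and the statistical battery (exact Mann-Whitney,
    Spearman, Cohen's d, nested random-intercept mixed-effects model).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    lme4,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'acquisition.R'
    'adc-mapping.R'
    'utils.R'
    'csi-recon.R'
    'hp13cmri-package.R'
    'io.R'
    'metabolite-mapping.R'
    'ph-mapping.R'
    'roi-analysis.R'
    'stats-report.R'
    'synthetic-cohort.R'
    'pipeline.R'
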