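Package: cslight
Title: Circadian Light and Circadian Stimulus Photometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A photometric engine for human circadian phototransduction.
    Computes circadian light (CL_A, in its original 2005 two-state form and
    the revised rod-cone-threshold form CL_A 2.0) and circadian stimulus
    (CS, predicted fractional nocturnal melatonin suppression) from any
    spectral power distribution, including the duration- and spatial
    distribution-augmented quantity CS_t,f. Provides the spectral weighting
    functions (lens-filtered melanopsin templates, S-cone fundamental,
    macular pigment transmittance, photopic and scotopic luminous
    efficiency), generators for standard stimuli (Planckian/Illuminant A,
    narrowband Gaussian, composite LED), constant-criterion spectral
    sensitivity derivation, fixed-shape logistic fitting of melatonin
    suppression data, log-abscissa curve alignment, duration-exponent
    fitting, and a synthetic suppression-data generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
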