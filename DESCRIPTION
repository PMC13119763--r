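Package: thermafoot
Title: Quantitative Clinical Thermography for Low-Cost LWIR Cameras
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end processing of radiometric images from low-cost
    long-wavelength infrared (LWIR) cameras for clinical thermography of
    the diabetic foot. Decodes radiometric camera containers, builds smooth
    multiplicative flat-field gain models and corrects vignetting in the
    radiometric domain, inverts the Planck/atmospheric radiometric chain to
    temperature, detects hybrid visible/thermal registration markers with
    sub-pixel accuracy, matches them across modalities with an
    orientation- and rank-constrained RANSAC, and registers the visible
    image onto the thermal frame. Includes a synthetic-scene simulator with
    full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    jsonlite,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, Visualization, Preprocessing
RoxygenNote: 7.3.3
Collate:
    'thermafoot-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'radiometry.R'
    'vignetting.R'
    'geometry.R'
    'morphology-utils.R'
    'detect-vis.R'
    'detect-lwir.R'
    'assignment.R'
    'matching.R'
    'registration.R'
    'synthetic.R'
    'container.R'
    'flir-io.R'
    'record.R'
    'pipeline.R'
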