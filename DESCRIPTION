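Package: iorgtools
Title: Intensity-Based Optoretinography Analysis of Cone Photoreceptor Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction and summarization of intensity-based optoretinography
    (iORG) signals from registered adaptive-optics scanning light
    ophthalmoscope (AOSLO) video stacks. Provides per-cone reflectance signal
    extraction with standardization, coordinate refinement and exclusion
    rules; population and individual root-mean-square (RMS) response traces
    and amplitudes; log-amplitude distributions and healthy-cone fractions
    against a normative 5th-percentile threshold; cone mosaic bound
    nearest-neighbor distance metrics; outer-segment length from OCT
    longitudinal reflectance profiles; retinal photon-density estimation; and
    cohort-level statistics. A synthetic acquisition generator with
    ground-truth manifests supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
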