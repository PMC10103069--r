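Package: flyretina
Title: Tracking and Analysis of Retinal Movements in Compound Eyes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying movements of the insect retina under the
    fixed lenses of the compound eye. Detects and tracks the deep pseudopupil
    (the virtual image of one ommatidium's photoreceptor array) in infrared
    video with sub-pixel precision, calibrates pixel displacements to visual
    degrees, and analyses the resulting eye-position traces: saccade detection
    and main-sequence fits, optokinetic gain and optomotor indices, binocular
    vergence metrics with event-triggered averaging around gap-crossing
    events, receptive-field mapping and angular shift estimation from
    bar-sweep electrophysiology, and a correlator-based model of spatial
    aliasing in motion vision. A synthetic-data generator produces every
    input with recorded ground truth so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    stats,
    tiff,
    utils,
    yaml,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
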