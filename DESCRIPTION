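Package: btvseg
Title: Automated Biological Target Volume Delineation from FDG-PET/CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Threshold-based automatic delineation of biological target
    volumes (BTV) on SUV-calibrated FDG-PET for radiotherapy planning, and
    the cohort-level agreement analysis against manually contoured gross
    tumour volumes (GTV). Implements fixed-percentage-of-SUVmax segmentation
    (38/42/47/50 percent) and a PERCIST-style background-adaptive threshold
    derived from a 15 ml hepatic reference VOI, nearest-neighbour
    back-projection of PET-defined volumes onto the planning-CT grid,
    conformity-index and inclusion-ratio overlap metrics, paired Wilcoxon
    signed-rank comparison of volumes with exact small-sample p-values, and
    a seeded synthetic PET/CT phantom generator with ground-truth lesions,
    a hepatic background compartment and simulated manual contours.
    Structures can be exchanged as NIfTI masks or DICOM RT structure sets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
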