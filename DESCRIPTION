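Package: epidwatch
Title: Automated In-Vivo EPID Transit-Image Surveillance for Radiotherapy QA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated surveillance of in-vivo electronic portal imaging
    device (EPID) transit images for fraction-by-fraction radiotherapy quality
    assurance. Reads and sorts DICOM RTIMAGE portal images into per-patient
    treatment courses, computes the gradient-dose segmented analysis (GDSA)
    mean difference of each fraction against the first-fraction baseline,
    raises three levels of alert (large single-fraction errors, systematic
    multi-fraction trends, and machine-output drift across clinic days),
    emits flag reports and daily clinic statistics, and evaluates
    replan-trigger threshold rules against physician replan decisions with
    sensitivity and specificity. Includes a synthetic transit-image generator
    (exponentially attenuated open-field fluence through a phantom with
    output drift, anatomy change, pixel noise and injected error scenarios)
    with an analytic ground-truth log for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    EBImage,
    generics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
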