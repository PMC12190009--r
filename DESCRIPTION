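Package: ermechquant
Title: Quantification of ER Mechanics, Morphology and Organelle Contacts
    from Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying endoplasmic-reticulum (ER) mechanobiology
    readouts from fluorescence microscopy and companion assays: biexponential
    fitting of time-correlated single-photon-counting (TCSPC) decay histograms
    to report the lifetime of mechanosensitive membrane probes, Renyi-entropy
    auto-thresholding and ER sheet/tubule morphometry, structure-tensor
    quantification of F-actin orientation and dispersion, Manders
    colocalization and ER-on-mitochondria distribution mapping, membrane
    contact-site extent measurement from digitized membrane traces, 3D puncta
    counting for split-GFP contact-site sensors, and normalizations for
    store-operated calcium entry (SOCE) traces, DNA-normalized metabolic
    readouts and XBP1 splicing ratios. A synthetic-data module generates every
    input modality with known ground truth so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
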