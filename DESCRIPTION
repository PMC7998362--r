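Package: shellraman
Title: Raman Pigment Identification in Mollusc Shell Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for identifying shell pigments from Raman spectra of
    pearl-oyster inner shell. Provides per-window wavenumber calibration
    against mineral reference peaks (calcite, aragonite, carbonate),
    asymmetric-least-squares baseline subtraction and lightweight smoothing,
    peak detection with prominence filtering and a clear/putative/none
    signal-to-noise classification, matching of detected peaks against a
    literature-derived pigment signature database, per-sample and
    per-phenotype evidence summaries, cohort principal component analysis of
    spectra, and a shared-pairwise-DEG rule that associates differentially
    expressed genes with colour phenotypes. A synthetic-spectrum and
    synthetic-DE-table generator with known ground truth supports end-to-end
    testing without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
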