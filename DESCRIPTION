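Package: oleagin
Title: Growth Kinetics and GC-FID Lipid Quantification for Oleaginous Yeasts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative physiology of oleaginous yeasts of the
    Yarrowia clade. Estimates growth parameters (lag phase, maximum specific
    growth rate, maximum cell density, generation time) from OD600 time series
    by sliding-window log-linear regression and tangent intersection; selects
    physiological sampling time points at one fifth, one half and the maximum
    optical density; quantifies fatty-acid methyl esters from GC-FID
    chromatograms by the C17:0 internal-standard method and expresses lipid
    content as percent of cell dry weight; classifies lipid-accumulation
    patterns and oleaginy; summarises carbon-source assimilation phenotype
    matrices; and generates seeded synthetic growth curves, chromatograms and
    full strain scenarios so every stage of the pipeline can be verified
    without instrument data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
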