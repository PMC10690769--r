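Package: oligopore
Title: Digital Nanopore Read-Out of DNA-Barcoded Protein Oligomers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of solid-state nanopore recordings of
    DNA-carrier nanostructures that barcode misfolded protein oligomers.
    Generates synthetic ionic-current traces with full ground truth, detects
    translocation events by thresholded excursion from a robust baseline,
    decodes 5-bit dumbbell barcodes with orientation resolution, detects and
    integrates bound-oligomer spikes (equivalent charge deficit), and computes
    per-sample screening read-outs (fraction bound with bootstrap uncertainty,
    ECD distributions, inhibitor ranking) for multiplexed mixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
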