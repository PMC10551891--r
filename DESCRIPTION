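Package: ppmkit
Title: Normalized Protein Abundance (ppm) Datasets: Quantification,
    Quality Scoring, Integration and Ortholog Amino-Acid Usage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts raw proteomics quantification tables (MaxQuant-style
    protein groups or peptide-level intensities/spectral counts) into
    normalized parts-per-million (ppm) protein abundance datasets, scores
    dataset quality by the abundance consistency of interacting protein
    pairs against a label-shuffled null (interaction z-score), integrates
    multiple datasets per organism or tissue by greedy weighted averaging,
    and quantifies amino-acid usage shifts (e.g. sulfur avoidance) in
    aligned orthologous protein domains as a function of protein
    abundance. Includes a synthetic-data generator emulating all input
    formats so every stage is testable without external downloads, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
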