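Package: smsfx
Title: Small-Molecule Serial Femtosecond Crystallography Data Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for processing sparse serial still-shot diffraction data
    from small-molecule and hybrid-material microcrystals at X-ray free
    electron lasers. Synthesizes sharpened virtual powder patterns from
    per-shot spot lists, ranks candidate unit cells by de Wolff M20, the
    intensity-weighted M* figure of merit and by indexing rate, indexes
    individual sparse stills by a maximum-clique reciprocal-space consistency
    search, and merges per-frame intensities with two-step reference scaling,
    standard-error-of-the-mean uncertainties, indexing-ambiguity resolution
    against a reference, and systematic-absence statistics. Includes a seeded
    forward simulator of still frames so every stage is testable without
    experimental data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
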