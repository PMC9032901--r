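Package: fingernet
Title: Chemotaxonomic Networks from MALDI-ToF Protein and Lipid Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dereplication of microbial isolates from MALDI-ToF MS1
    fingerprints. Reads mzXML profile spectra and MGF peak lists, runs a
    biotyping preprocessing chain (mass-range trim, square-root intensity
    transform, Savitzky-Golay smoothing, SNIP baseline estimation, robust
    signal-to-noise peak picking, TIC normalisation), compares fingerprints
    by greedy-matched cosine scores, builds thresholded mutual-top-k
    similarity networks with a deterministic t-SNE embedding, and reports
    cluster/taxonomy concordance at the order level. A hierarchical
    simulator generates taxon-structured synthetic fingerprints so the
    whole pipeline is testable without external spectra. Includes a
    polyethylene-glycol ladder detector that flags polymer-contaminated
    lipid fingerprints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
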