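Package: ire1rna
Title: Ire1 Substrate Stem-Loops: Structure Probing, Cleavage Rules and
    Splicing-Cassette Engineering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing and engineering RNA substrates of the
    Ire1 endoribonuclease, the sensor of the unfolded protein response.
    Implements constrained minimum-free-energy RNA secondary-structure
    prediction under a nearest-neighbour energy model, normalisation of
    dimethyl-sulfate (DMS) structure-probing signals into folding
    constraints, species-specific classification of Ire1 cleavage sites
    from sequence motifs (CNG|CNGN, CNG|ANGN, UG|C) and stem-loop
    geometry, first-order cleavage-kinetics fitting with a documented
    linear-regime fallback, and in-silico design of non-conventional
    mRNA splicing cassettes with splice-product prediction. A synthetic
    data module generates DMS count profiles, cleavage time courses and
    motif-bearing hairpins with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
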