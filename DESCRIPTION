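Package: minorintron
Title: Discovery and Classification of Minor Spliceosomal (U12-Type) Introns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers introns from EST-to-genome matches and classifies them as
    major (U2-type) or minor (U12-type) spliceosomal introns using position
    weight matrix scoring of 5' splice sites and branch point regions. Two
    complementary scoring schemes are provided: a probability-product scheme
    with z-score normalization against a reference set of known U12 introns,
    and a log-odds scheme with per-class matrices. Additional tools cover the
    relaxed RTATCCTT 5'-terminal consensus rule, construction of U2 branch
    site frequency matrices from best-scoring windows, classification of the
    evolutionary fate of U12 introns between homologous genes, and a
    synthetic genome/EST generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
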