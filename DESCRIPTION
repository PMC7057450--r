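Package: sihgt
Title: Synteny-Index Detection of Horizontal Gene Transfer Between
    Closely Related Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects horizontal gene transfer (HGT) between closely related
    prokaryotic genomes from loss of local gene-order conservation. For each
    core gene it computes the synteny index (SI), the number of genes shared
    between the gene's circular k-neighborhoods in the two genomes, and flags
    genes whose SI falls below a Chernoff-bound threshold for SI arising by
    chance. Suspected genes are then sifted from translocations and
    duplications with a constant-relative-mutability witness test: a witness
    gene and two reference organisms calibrate the expected Jukes-Cantor
    strain distance, and a Chernoff bound on the deviation of the observed
    Hamming distance decides whether vertical descent can be refuted
    (Bonferroni-corrected over witness/reference choices). Includes a
    genome-quartet simulator with block-swap rearrangements and an elevated
    mutation rate for transferred genes, used to evaluate specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
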