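Package: psiquant
Title: Quantitative Pseudouridine Analysis from BID-Seq Deletion Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for quantitative pseudouridine (Psi)
    epitranscriptomics. Calls Psi sites with stoichiometry from BID-seq
    per-position deletion ("gap") pileups via calibration curves and
    binomial P-value filtering; assigns sites to transcript regions and
    builds metagene, density and tissue-sharing summaries; classifies
    cross-species site conservation from Smith-Waterman alignments
    (Classes 1-4); computes transcript- and codon-level translation
    efficiency from ribosome footprints and RNA abundance; and provides
    the correlation and group-comparison statistics linking Psi
    stoichiometry on rRNA, tRNA and mRNA to translation and mRNA
    stability. A synthetic-data module generates every input with planted
    ground truth so each stage is verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
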