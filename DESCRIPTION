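Package: acrmine
Title: Guilt-by-Association Mining of Anti-CRISPR Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering candidate anti-CRISPR (Acr) and
    Acr-associated (Aca) genes in mobile genetic elements by
    guilt-by-association genomic-neighborhood mining. Implements the
    adjacency, orientation, protein-size, DNA-binding-domain and
    association criteria used to designate Acr/Aca candidates, Acr-Aca
    fusion detection, an iterative search-validation marker-expansion
    loop with pluggable validators, Grishin-distance minimum-evolution
    phylogenetics for Acr homolog families, and quantification of
    CRISPR-inhibition assays (colony-forming-unit ratios, T7E1 indel
    conversion, fold regulation, activity classification). A synthetic
    genome simulator with planted ground truth makes the whole pipeline
    testable end to end without any database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
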