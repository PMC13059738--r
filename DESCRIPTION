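Package: phagecode
Title: Alternative Genetic Code Inference and CRISPR Spacer Analysis for
    Phage and Host Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genome-level inference tools for phage-host systems in which the
    host lineage uses an alternative genetic code. Predicts open reading
    frames on linear or circular contigs under configurable NCBI translation
    tables (notably table 25, where TGA encodes glycine), computes the
    internal-stop disruption statistic used to assign a genetic code to a
    phage genome, classifies suppressor tRNAs from annotation tables, checks
    phage/host codon-usage compatibility, reconstructs CRISPR arrays and
    matches spacers to protospacers under an identity/coverage retention
    rule, and scores genome bins for single-copy-marker completeness and
    redundancy. A synthetic-genome generator with full ground truth supports
    end-to-end testing without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
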