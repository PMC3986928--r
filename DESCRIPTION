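Package: contigvar
Title: Quality-Based Cleaning and Mismatch Discovery in 454 Transcriptome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-assembly analysis of pyrosequencing (454) transcriptome
    contigs from pooled diploid genotypes. Reads padded multiple alignments
    (consed ACE dialect) with their base qualities, masks unreliable bases
    (singletons, low-frequency variants, low-quality calls at polymorphic
    sites), removes homopolymer-artefact columns that contain only indels and
    masked bases, edits an IUPAC consensus, and calls candidate variants
    (mismatches) with a binomial false-positive filter based on the expected
    minimum allele frequency in the sequenced gamete pool. Also provides a
    green-plant contaminant screen over blast hit tables, a permutation test
    for organ-level over-expression of gene-ontology contig groups, a
    rarefaction bootstrap (RaBoT) for comparing contig counts between unevenly
    sequenced libraries, and a ground-truth simulator of pooled-gamete 454
    assemblies for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
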