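Package: allotriploid
Title: Subgenome-Resolved Methylation, Dosage and miRNA Analysis for
    Allotriploid Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing an allotriploid hybrid complex (two
    reciprocal triploids and their diploid inbred parents) with the two
    parental genomes used as a combined reference. Covers homoeologous
    gene-pair cataloguing from reciprocal best hits, binomial methylation
    calling against an unmethylated lambda spike-in, binned gene-element and
    transposon methylation profiles, window-based differential methylation,
    promoter methylation-divergence classification and prediction of
    homoeologous recombinant genes, read-depth-ratio detection of unequal
    homoeologous recombination, TMM normalisation with a negative-binomial
    exact test for differential expression, dosage-compensation scaling
    tests, miRNA subgenome copy-number pattern classification, and joint
    expression-methylation quadrant summaries. A synthetic-data generator
    emits a complete labelled in-silico triploid complex so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
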