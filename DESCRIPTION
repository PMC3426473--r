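Package: exonaudit
Title: Gene-Based Quality Assessment of Draft Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Audits draft genome assemblies through the lens of conserved
    gene structure. Ortholog transcript exons are placed onto a draft
    assembly by seeded local alignment and assembled into per-transcript
    exon chains; violations of exon order, orientation and chromosome
    assignment expose misassemblies (split genes, unintegrated contigs,
    inverted contigs, chimeric contigs), while per-exon alignments expose
    sequencing-error effects (frameshifts, premature stop codons, missing
    exons or sub-exon sequence) and annotation artifacts (spurious exons
    invented from intronic sequence, truncated or absent gene models).
    Findings are combined into a six-way gene-model survey classification.
    A synthetic-genome simulator injects every supported defect class with
    a machine-readable ground-truth log so detector sensitivity, precision
    and classification accuracy can be scored end-to-end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
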