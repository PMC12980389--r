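Package: haploproteo
Title: Haplotype-Resolved Proteogenomic Database Construction and Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sample-specific, haplotype-resolved protein search databases
    from a reference genome, coding-transcript annotation, and phased variants,
    and annotates peptide-spectrum-match tables searched against such databases.
    Covers post-call variant filtering with phase-block post-processing that
    guarantees contiguous phasing across coding sequences, projection of phased
    SNVs and indels onto transcript coding sequences with translation and
    protein-effect characterization, database assembly with sequence
    deduplication, contaminant concatenation and reversed-decoy generation,
    peptide classification with direct and phase-linked variant identification,
    greedy set-cover protein inference, peptide-to-genome browser tracks, and
    switch-error-rate phasing evaluation at CDS, transcript, and gene
    resolution. Seeded synthetic-fixture generators provide ground-truth data
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
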