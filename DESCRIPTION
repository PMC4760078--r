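Package: EDCtools
Title: Annotation and Comparative Analysis of Epidermal Differentiation Complex Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and characterizing simple epidermal
    differentiation complex (SEDC) genes in sauropsid genome assemblies.
    Implements de novo prediction of the characteristic two-exon SEDC gene
    structure (TATA box, splice donor/acceptor signals, single coding exon),
    a translated seed-and-extend homology search with iterative query
    expansion, frameshift-aware pseudogene detection, amino-acid composition
    and motif-based classification of EDC protein families (glycine/serine-
    rich, cysteine/proline-rich, aromatic-rich, beta-keratins), locus maps
    with anchor-gene delimitation, synteny and translocation analysis, and a
    distance-based bootstrap phylogeny for beta-keratin core segments. A
    synthetic-genome generator with machine-readable ground truth allows the
    whole pipeline to be exercised and benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
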