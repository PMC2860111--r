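Package: codonbias
Title: Synonymous Codon Usage Analysis for Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Per-gene codon-usage indices (RSCU, effective number of codons,
    GC3s and third-position base composition, codon adaptation index, Fop,
    GRAVY), correspondence analysis of the gene-by-codon usage matrix,
    chi-square detection of translationally optimal codons from extreme
    expression groups, GC-skew based replication origin/terminus location
    with leading/lagging strand classification, and ortholog divergence
    (reciprocal best hits, codon-aware alignment, Nei-Gojobori Ka/Ks).
    Includes a synthetic bacterial genome simulator with ground-truth
    expression, strand and substitution labels for end-to-end recovery
    tests, and the worked codon-count tables for Corynebacterium
    glutamicum extreme expression groups.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
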