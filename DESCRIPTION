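Package: plasmidSV
Title: Insertion-Site Mapping and Structural-Variant Analysis for
    Plasmid Insertional Mutagenesis Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Whole-genome-sequencing analysis of plasmid insertional
    mutants in haploid organisms. Detects plasmid insertion sites from
    discordant read pairs, classifies insertions as two-sided, one-sided
    or complex, sizes junction deletions and duplications from soft-clip
    evidence, calls secondary deletions unassociated with the plasmid
    from gapped reads, spanning pairs and coverage drops, annotates
    disrupted genes against GFF3 gene models, builds population allele
    tables and disruption-frequency rankings, and applies a deterministic
    rule set to curate higher-confidence candidate genes. Ships a
    paired-end insertional-mutagenesis simulator with machine-readable
    truth tables so every stage is testable end-to-end, plus closed-form
    calculators for Poisson gene-hit saturation, tetrad linkage
    resolution and hypergeometric gene-set overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
biocViews: StructuralVariation, Sequencing, Software, GenomeAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
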