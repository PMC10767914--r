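Package: pwmbench
Title: Benchmarking and Selection of Transcription Factor Binding Motifs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for evaluating position weight matrices (PWMs) of
    transcription factor binding sites and assembling best-performing motif
    collections. Implements exact PWM score-distribution P-values by dynamic
    programming, double-stranded sequence scanning, preparation of positive
    and negative sequence sets from ChIP-Seq peak summits and HT-SELEX read
    pools (cycle pooling, singleton removal, 5-mer enrichment ranking against
    a dinucleotide-shuffled background, adapter extension), three in-vivo
    benchmarks (flank-negative auROC/auPRC, pseudo-ROC against Markov
    negatives, motif centrality E-values), an in-vitro read-enrichment
    benchmark, regulatory-SNV benchmarks (differential binding log-P ratios
    against SNP-SELEX measurements and allele-specific binding concordance),
    log-rank aggregation across metrics and datasets, A/B/C/D quality
    ratings, and assembly of core/in-vivo/in-vitro/rSNP subcollections.
    Seeded synthetic-data generators with known ground truth make every
    benchmark testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
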