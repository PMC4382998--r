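Package: chipbs
Title: Joint Occupancy and DNA Methylation Analysis for ChIP-Bisulphite
    Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing ChIP-bisulphite sequencing (ChIP-BS-Seq)
    experiments, in which chromatin-immunoprecipitated DNA is bisulphite
    converted so that protein occupancy and CpG methylation are read from
    the same molecules. The package converts bisulphite alignments into
    per-cytosine methylation calls with multi-mapper weighting and
    spike-in conversion control, calls occupancy-enriched windows and
    regions against an input library under joint Q-value and empirical
    FDR control, tests windows and elements for differential methylation
    between ChIP and input, builds per-base methylation meta-profiles on
    repeat-family consensus coordinates, and compares occupancy and
    methylation across repeat families with Kruskal-Wallis and Dunn
    post-hoc tests. A synthetic-data generator produces toy genomes with
    repeat families of differing CpG density and methylation, occupied
    loci, an unmethylated spike-in contig and bisulphite-converted reads,
    so every stage can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    zoo,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Epigenetics, DNAMethylation, ChIPSeq, Sequencing, Coverage
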