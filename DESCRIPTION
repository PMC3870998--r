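Package: MetaPeaks
Title: Consensus Peak Calling from Multiple ChIP-Seq Peak Finders
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Combines peak lists produced by several ChIP-seq peak finders
    into a single set of consensus peaks. Per-caller peak scores are brought
    onto a common scale by one of five normalization methods (normal,
    naive quantile, average, rank, top rank); the genome is segmented at
    peak boundaries into constant-coverage intervals carrying vote counts
    and aggregated scores; consensus regions are selected by in-degree
    centrality voting, minFP or minFN rules. Per-caller WIG signal tracks
    can be merged into one consensus track with unified step sizes and an
    optional score cut-off. An evaluation module scores outputs against a
    curated true-positive/false-positive truth set and compares
    configurations by Euclidean distance to the perfect corner, combined
    ranking score and average normalized (studentized) distance. A
    simulator generates caller-like BED/WIG outputs with planted binding
    sites for testing without external data.
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
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
biocViews: ChIPSeq, PeakDetection, Epigenetics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'MetaPeaks-package.R'
    'methods.R'
    'consensus-bed.R'
    'normalize.R'
    'consensus-wig.R'
    'evaluate.R'
    'peaks-io.R'
    'run.R'
    'simulate.R'
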