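# Fixture builders shared across test files. Coordinates are given 0-based
# half-open (the BED convention) and converted to GRanges here, so tests read
# like the worked examples.

makeCallerPeaks <- function(id, start, end, score = rep(1, length(start)),
                            chrom = "chr1") {
    CallerPeaks(id, GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = start + 1, end = end), score = score))
}

makeRegions <- function(start, end, chrom = "chr1") {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1,
                                                   end = end))
}

# 0-based (start, end) matrix of a GRanges, for readable comparisons
regionCoords <- function(gr) {
    cbind(start = GenomicRanges::start(gr) - 1, end = GenomicRanges::end(gr))
}

# The five-score worked example shared by all normalization methods
sissrExample <- function(scores = c(2, 4, 4, 8, 12)) {
    makeCallerPeaks("sissr", start = (seq_along(scores) - 1) * 100,
                    end = (seq_along(scores) - 1) * 100 + 50, score = scores)
}

# The four intervals of the published voting example:
# caller 1: [0,7) and [9,15); caller 2: [5,25); caller 3: [10,20)
votingExampleLists <- function(score = c(1, 1, 1, 1)) {
    list(makeCallerPeaks("pf1", c(0, 9), c(7, 15), score[1:2]),
         makeCallerPeaks("pf2", 5, 25, score[3]),
         makeCallerPeaks("pf3", 10, 20, score[4]))
}

# Random multi-caller instance with per-caller disjoint peaks and integer
# scores; returned both as CallerPeaks (implementation input) and as a plain
# data.frame (oracle input).
randomInstance <- function(seed, maxCallers = 5L, maxPeaksTotal = 50L,
                           maxCoord = 10000L) {
    set.seed(seed)
    nCallers <- sample.int(maxCallers, 1L)
    L <- sample(c(200L, 500L, 2000L, maxCoord), 1L,
                prob = c(0.4, 0.3, 0.2, 0.1))
    perCaller <- sample.int(max(1L, maxPeaksTotal %/% nCallers), nCallers,
                            replace = TRUE)
    rows <- list()
    for (ci in seq_len(nCallers)) {
        k <- perCaller[ci]
        pts <- sort(sample.int(L, 2L * k))
        st <- pts[seq(1L, 2L * k, by = 2L)] - 1L   # 0-based
        en <- pts[seq(2L, 2L * k, by = 2L)]
        rows[[ci]] <- data.frame(caller = paste0("c", ci), start = st,
                                 end = en,
                                 score = sample.int(100L, k, replace = TRUE))
    }
    df <- do.call(rbind, rows)
    lists <- lapply(split(df, df$caller), function(d)
        makeCallerPeaks(d$caller[1L], d$start, d$end, d$score))
    list(df = df, lists = unname(lists), L = L, nCallers = nCallers)
}

randomWigTrack <- function(seed, chrom = "chr1",
                           spanChoices = c(5L, 10L, 20L)) {
    set.seed(seed)
    sp <- spanChoices[sample.int(length(spanChoices), 1L)]
    n <- sample.int(20L, 1L)
    starts <- sort(sample.int(100L, n)) * sp   # on the span grid, gappy
    WigTrack(chrom, sp, starts, round(stats::runif(n, 0, 50), 3))
}

trackMass <- function(t) sum(scores(t)) * span(t)
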