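# Configuration gating and the end-to-end file pipeline.

writeExampleInputs <- function(dir, chrom = "chr1") {
    specs <- list(pf1 = list(start = c(0, 9), end = c(7, 15), score = c(5, 5)),
                  pf2 = list(start = 5, end = 25, score = 3),
                  pf3 = list(start = 10, end = 20, score = 4))
    vapply(names(specs), function(id) {
        s <- specs[[id]]
        p <- file.path(dir, paste0(id, ".bed"))
        writeCallerBed(makeCallerPeaks(id, s$start, s$end, s$score, chrom), p)
        p
    }, character(1))
}

test_that("invalid mode/method combinations are rejected before any processing", {
    ins <- c(pf1 = "a.bed")
    expect_error(consensusConfig(ins, mode = "wig", normalize = "rank"),
                 "configuration error.*WIG mode")
    expect_error(consensusConfig(ins, mode = "wig", normalize = "normal"),
                 "configuration error")
    expect_error(consensusConfig(character()), "at least one input")
    expect_error(consensusConfig(c("x.bed")), "caller name")
    expect_error(consensusConfig(c(a = "x.bed", a = "y.bed")), "distinct")
    expect_error(consensusConfig(ins, minRank = 0), "minRank")
    expect_error(consensusConfig(ins, select = "minfp",
                                 normalize = "zscore"),
                 "unknown normalization")
    expect_error(consensusConfig(ins, quantile = 1.5), "quantile")
    expect_warning(cfg <- consensusConfig(ins, select = "voting",
                                          normalize = "rank"),
                   "voting does not use scores")
    expect_identical(cfg$normalize, "none")
    # minFP/minFN default to rank normalization; WIG defaults to average
    expect_identical(consensusConfig(ins, select = "minfp")$normalize, "rank")
    expect_identical(consensusConfig(ins, mode = "wig")$normalize, "average")
})

test_that("the BED pipeline reproduces the voting example end to end", {
    dir <- withr::local_tempdir()
    ins <- writeExampleInputs(dir)
    cfg <- consensusConfig(ins, mode = "bed", select = "voting", minRank = 2,
                           outDir = file.path(dir, "out"))
    res <- runConsensus(cfg)
    expect_true(file.exists(file.path(dir, "out", "consensus.bed")))
    lines <- readLines(file.path(dir, "out", "consensus.bed"))
    expect_identical(sub("\t[^\t]*$", "", lines),
                     c("chr1\t5\t7\tvotes=2", "chr1\t9\t20\tvotes=3"))
    expect_identical(res$counts$consensusRegions, 2L)
})

test_that("keepIndividual stores each caller's normalized list", {
    dir <- withr::local_tempdir()
    ins <- writeExampleInputs(dir)
    cfg <- consensusConfig(ins, select = "minfn", normalize = "rank",
                           minRank = 2, outDir = file.path(dir, "out"),
                           keepIndividual = TRUE)
    runConsensus(cfg)
    for (cl in names(ins)) {
        p <- file.path(dir, "out", paste0(cl, ".normalized.bed"))
        expect_true(file.exists(p))
        x <- readPeakBed(p, cl)
        expect_identical(nPeaks(x), nPeaks(readPeakBed(ins[[cl]], cl)))
    }
    # stored scores are the normalized ones, not the raw input scores
    p1 <- readPeakBed(file.path(dir, "out", "pf1.normalized.bed"), "pf1")
    expect_equal(scores(p1), rankScores(c(5, 5), 2))
})

test_that("per-chromosome processing equals a whole-genome single pass", {
    mk2 <- function(id, sc1, sc2) {
        base <- list(pf1 = list(st = c(0, 9), en = c(7, 15)),
                     pf2 = list(st = 5, en = 25),
                     pf3 = list(st = 10, en = 20))[[id]]
        gr <- suppressWarnings(  # distinct seqlevels are intentional here
            c(GenomicRanges::GRanges("chr1",
                  IRanges::IRanges(base$st + 1, base$en), score = sc1),
              GenomicRanges::GRanges("chr2",
                  IRanges::IRanges(base$st + 31, base$en + 40),
                  score = sc2)))
        CallerPeaks(id, gr)
    }
    lists <- list(mk2("pf1", c(5, 5), c(2, 9)), mk2("pf2", 3, 7),
                  mk2("pf3", 4, 1))
    dir <- withr::local_tempdir()
    ins <- vapply(lists, function(x) {
        p <- file.path(dir, paste0(caller(x), ".bed"))
        writeCallerBed(x, p)
        p
    }, character(1))
    names(ins) <- vapply(lists, caller, character(1))
    # voting: per-chromosome concatenation equals one whole-genome pass
    # (votes are purely local, so the chromosome split cannot matter)
    cfg <- consensusConfig(ins, select = "voting", minRank = 2,
                           outDir = file.path(dir, "out"))
    res <- runConsensus(cfg)
    wholeGenome <- bedConsensus(lists, select = "voting", minRank = 2)
    expect_equal(regionCoords(res$regions),
                 regionCoords(GenomicRanges::sort(wholeGenome$regions)))

    # score-based selection analyzes one chromosome at a time: thresholds
    # (and normalization operands) are per-chromosome by design
    cfgFn <- consensusConfig(ins, select = "minfn", normalize = "average",
                             minRank = 2, outDir = file.path(dir, "out2"))
    resFn <- runConsensus(cfgFn)
    onlyChrom <- function(x, ch) {
        keep <- as.character(GenomicRanges::seqnames(x@peaks)) == ch
        new("CallerPeaks", caller = caller(x), peaks = x@peaks[keep])
    }
    perChrom <- do.call(c, unname(lapply(c("chr1", "chr2"), function(ch)
        bedConsensus(lapply(lists, onlyChrom, ch = ch), select = "minfn",
                     normalize = "average", minRank = 2)$regions)))
    expect_equal(regionCoords(resFn$regions),
                 regionCoords(GenomicRanges::sort(perChrom)))
})

test_that("identical configuration and inputs give byte-identical outputs", {
    dir <- withr::local_tempdir()
    ins <- writeExampleInputs(dir)
    cfg1 <- consensusConfig(ins, select = "minfp", normalize = "top_rank",
                            minRank = 2, outDir = file.path(dir, "o1"))
    cfg2 <- consensusConfig(ins, select = "minfp", normalize = "top_rank",
                            minRank = 2, outDir = file.path(dir, "o2"))
    runConsensus(cfg1)
    runConsensus(cfg2)
    expect_identical(readLines(file.path(dir, "o1", "consensus.bed")),
                     readLines(file.path(dir, "o2", "consensus.bed")))
})

test_that("a chromosome filter absent from the inputs warns and yields empty output", {
    dir <- withr::local_tempdir()
    ins <- writeExampleInputs(dir)
    cfg <- consensusConfig(ins, select = "voting", minRank = 2,
                           chrom = "chr2", outDir = file.path(dir, "out"))
    expect_warning(res <- runConsensus(cfg), "absent from the inputs")
    expect_length(res$regions, 0L)
    expect_identical(readLines(file.path(dir, "out", "consensus.bed")),
                     character())
})

test_that("the WIG pipeline merges tracks from files and can export BED", {
    dir <- withr::local_tempdir()
    wa <- file.path(dir, "a.wig")
    wb <- file.path(dir, "b.wig")
    writeWig(WigTrack("chr1", 20L, c(0L, 20L), c(4, 6)), wa)
    writeWig(WigTrack("chr1", 10L, c(10L, 20L), c(1, 2)), wb)
    cfg <- consensusConfig(c(a = wa, b = wb), mode = "wig",
                           normalize = "none", cutoff = 5,
                           outDir = file.path(dir, "out"),
                           outputFormat = "bed")
    res <- runConsensus(cfg)
    expect_true(file.exists(file.path(dir, "out", "consensus.wig")))
    expect_true(file.exists(file.path(dir, "out", "consensus.bed")))
    expect_equal(scores(res$tracks[[1]]), c(5, 8, 6))
    back <- readWig(file.path(dir, "out", "consensus.wig"))
    expect_equal(scores(back[[1]]), c(5, 8, 6))
})

test_that("the command-line script runs the pipeline and honors exit codes", {
    cli <- system.file("cli", "metapeaks.R", package = "MetaPeaks")
    expect_true(nzchar(cli))
    dir <- withr::local_tempdir()
    ins <- writeExampleInputs(dir)
    rscript <- file.path(R.home("bin"), "Rscript")
    out <- file.path(dir, "out")
    code <- system2(rscript, c(cli, "consensus",
                               paste0("--input=", ins[1], "=pf1"),
                               paste0("--input=", ins[2], "=pf2"),
                               paste0("--input=", ins[3], "=pf3"),
                               "--select=voting", "--min-rank=2",
                               paste0("--out=", out)),
                    stdout = FALSE, stderr = FALSE)
    expect_identical(code, 0L)
    lines <- readLines(file.path(out, "consensus.bed"))
    expect_identical(sub("\t[^\t]*$", "", lines),
                     c("chr1\t5\t7\tvotes=2", "chr1\t9\t20\tvotes=3"))
    # configuration error -> exit code 2
    code <- system2(rscript, c(cli, "consensus",
                               paste0("--input=", ins[1], "=pf1"),
                               "--mode=wig", "--normalize=rank",
                               paste0("--out=", out)),
                    stdout = FALSE, stderr = FALSE)
    expect_identical(code, 2L)
})
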