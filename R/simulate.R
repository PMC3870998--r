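#' @include AllClasses.R methods.R
NULL

## Uniform placement of n non-overlapping intervals with given widths on
## [0, L): distribute the total slack L - sum(w) among the n + 1 gaps by
## sorting n uniform draws (order-statistics construction).
.placeDisjoint <- function(genomeLength, widths) {
    n <- length(widths)
    slack <- genomeLength - sum(widths)
    if (n == 0L) return(integer())
    if (slack < 0)
        stop("cannot pack ", n, " site(s) of total width ", sum(widths),
             " into ", genomeLength, " bp", call. = FALSE)
    cuts <- sort(stats::runif(n, 0, slack))
    as.integer(floor(cuts)) + c(0L, cumsum(widths[-n]))
}

#' Generate a synthetic truth set of planted binding sites
#'
#' Places \code{nSites} non-overlapping true-positive intervals (and
#' optionally \code{nFpSites} decoy false-positive intervals, disjoint from
#' them) uniformly at random on a linear genome. Widths are drawn uniformly
#' from \code{widthRange}. Fully deterministic for a fixed \code{seed}.
#'
#' @param genomeLength genome size in bp.
#' @param nSites number of true sites to plant.
#' @param widthRange integer 2-vector, (min, max) site width in bp.
#' @param seed integer seed.
#' @param nFpSites number of decoy intervals annotated as false positives
#'   (default 0).
#' @param chrom chromosome name for all intervals.
#' @return a \code{\link{TruthSet}}.
#' @examples
#' generateTruth(1e6, 10, c(150, 400), seed = 7)
#' @export
generateTruth <- function(genomeLength, nSites, widthRange = c(150L, 400L),
                          seed = 1L, nFpSites = 0L, chrom = "chr1") {
    stopifnot(genomeLength >= 1, nSites >= 0, nFpSites >= 0,
              length(widthRange) == 2L, widthRange[1L] >= 1,
              widthRange[2L] >= widthRange[1L])
    if ((nSites + nFpSites) * widthRange[2L] >= genomeLength)
        stop("infeasible packing: (nSites + nFpSites) * max width must be ",
             "below genomeLength", call. = FALSE)
    set.seed(seed)
    nTot <- nSites + nFpSites
    wChoices <- seq(widthRange[1L], widthRange[2L])
    widths <- if (nTot)
        as.integer(wChoices[sample.int(length(wChoices), nTot,
                                       replace = TRUE)]) else integer()
    starts <- .placeDisjoint(genomeLength, widths)
    isTP <- if (nTot) sample(rep(c(TRUE, FALSE), c(nSites, nFpSites)))
            else logical()
    gr <- GenomicRanges::GRanges(rep(chrom, nTot),
        IRanges::IRanges(start = starts + 1, width = widths))
    TruthSet(tp = gr[isTP], fp = gr[!isTP])
}

#' Simulate one peak finder's output on a truth set
#'
#' Emulates the behaviour that motivates consensus calling: each true site
#' is reported with probability \code{sensitivity} and jittered boundaries;
#' \code{Poisson(fpCount)} false peaks are added away from all annotated
#' intervals; and scores live on a caller-specific scale
#' (\code{scoreScale}), with true-site peaks drawn from a gamma with a
#' larger shape than false peaks so they score stochastically higher. The
#' output is byte-reproducible for a fixed profile seed.
#'
#' @param truth a \code{\link{TruthSet}}.
#' @param profile a \code{\link{CallerProfile}}.
#' @param genomeLength genome size in bp used for false-peak placement
#'   (default: span of the truth annotations plus a margin).
#' @return a \code{\link{CallerPeaks}}.
#' @export
simulateCaller <- function(truth, profile, genomeLength = NULL) {
    stopifnot(is(truth, "TruthSet"), is(profile, "CallerProfile"))
    tp <- truth@tp
    chrom <- if (length(tp)) as.character(GenomicRanges::seqnames(tp))[1L]
             else "chr1"
    if (is.null(genomeLength)) {
        allAnn <- c(GenomicRanges::granges(tp),
                    GenomicRanges::granges(truth@fp))
        genomeLength <- if (length(allAnn))
            max(GenomicRanges::end(allAnn)) + 10000L else 1000000L
    }
    set.seed(profile@seed)
    keep <- stats::runif(length(tp)) <= profile@sensitivity
    rep0 <- tp[keep]
    st <- GenomicRanges::start(rep0) - 1L
    en <- GenomicRanges::end(rep0)
    if (profile@jitter > 0L && length(rep0)) {
        st <- st + sample(seq(-profile@jitter, profile@jitter),
                          length(rep0), replace = TRUE)
        en <- en + sample(seq(-profile@jitter, profile@jitter),
                          length(rep0), replace = TRUE)
        st <- pmax(st, 0L)
        en <- pmax(en, st + 1L)
    }
    nFalse <- stats::rpois(1L, profile@fpCount)
    avoid <- GenomicRanges::reduce(c(GenomicRanges::granges(tp),
                                     GenomicRanges::granges(truth@fp)))
    wTP <- if (length(tp)) GenomicRanges::width(tp) else 300L
    fpW <- fpSt <- integer()
    if (nFalse > 0L) {
        placed <- 0L
        tries <- 0L
        while (placed < nFalse && tries < 200L * nFalse) {
            w <- as.integer(wTP[sample.int(length(wTP), 1L)])
            s <- as.integer(floor(stats::runif(1L, 0, genomeLength - w)))
            cand <- GenomicRanges::GRanges(chrom,
                IRanges::IRanges(start = s + 1, width = w))
            ok <- !IRanges::overlapsAny(cand, avoid)
            if (length(fpSt))
                ok <- ok && !IRanges::overlapsAny(cand,
                    GenomicRanges::GRanges(chrom,
                        IRanges::IRanges(start = fpSt + 1, width = fpW)))
            if (ok) {
                fpSt <- c(fpSt, s)
                fpW <- c(fpW, w)
                placed <- placed + 1L
            }
            tries <- tries + 1L
        }
    }
    trueScores <- profile@scoreScale *
        stats::rgamma(length(rep0), shape = profile@scoreShape + 2, rate = 1)
    falseScores <- profile@scoreScale *
        stats::rgamma(length(fpSt), shape = profile@scoreShape, rate = 1)
    gr <- c(GenomicRanges::GRanges(rep(chrom, length(st)),
                IRanges::IRanges(start = st + 1, end = en),
                score = trueScores),
            GenomicRanges::GRanges(rep(chrom, length(fpSt)),
                IRanges::IRanges(start = fpSt + 1, width = fpW),
                score = falseScores))
    CallerPeaks(profile@caller, gr)
}

#' Simulate a full multi-caller study
#'
#' Generates one truth set and one \code{\link{CallerPeaks}} per profile,
#' with per-caller seeds derived deterministically from \code{seed}.
#'
#' @param nCallers number of simulated callers.
#' @param nSites number of planted true sites (default 200).
#' @param genomeLength genome size in bp (default 1e6).
#' @param sensitivity per-caller report probability (recycled; default 0.9).
#' @param fpCount expected false peaks per caller (recycled; default
#'   \code{0.3 * nSites}).
#' @param scoreScale per-caller score scale (recycled; default
#'   \code{10^(seq_len(nCallers) - 1)}, i.e. 1, 10, 100, ... -- wildly
#'   different ranges, as real callers produce).
#' @param jitter boundary jitter in bp (default 25).
#' @param widthRange site width range in bp (default 150-400).
#' @param seed master seed; caller i uses \code{seed * 1000 + i}.
#' @return list with elements \code{truth} (a \code{\link{TruthSet}}) and
#'   \code{callers} (list of \code{\link{CallerPeaks}}).
#' @export
simulateStudy <- function(nCallers = 3L, nSites = 200L, genomeLength = 1e6,
                          sensitivity = 0.9, fpCount = 0.3 * nSites,
                          scoreScale = 10^(seq_len(nCallers) - 1),
                          jitter = 25L, widthRange = c(150L, 400L),
                          seed = 1L) {
    seed <- as.integer(seed) %% 2000000L
    truth <- generateTruth(genomeLength, nSites, widthRange,
                           seed = seed * 1000L)
    sensitivity <- rep_len(sensitivity, nCallers)
    fpCount <- rep_len(fpCount, nCallers)
    scoreScale <- rep_len(scoreScale, nCallers)
    callers <- lapply(seq_len(nCallers), function(i) {
        simulateCaller(truth,
            CallerProfile(paste0("caller", i),
                          sensitivity = sensitivity[i],
                          fpCount = fpCount[i],
                          scoreScale = scoreScale[i],
                          jitter = jitter,
                          seed = seed * 1000L + i),
            genomeLength = genomeLength)
    })
    list(truth = truth, callers = callers)
}
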