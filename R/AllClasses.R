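#' Peaks reported by a single peak finder
#'
#' A \code{CallerPeaks} object holds the full output of one ChIP-seq peak
#' finder: a sorted \link[GenomicRanges]{GRanges} of enriched intervals, each
#' carrying a non-negative \code{score}, plus the identity of the caller that
#' produced them. Coordinates are 0-based half-open internally and exposed via
#' GRanges in the usual 1-based closed convention.
#'
#' Peaks from one caller never overlap one another: overlapping intervals are
#' merged at construction (keeping the maximum score), so a caller can cast at
#' most one vote per base during consensus building.
#'
#' @slot caller single string identifying the source peak finder.
#' @slot peaks \code{GRanges} with a numeric \code{score} metadata column,
#'   sorted, intra-caller disjoint, all scores \eqn{\ge 0}.
#'
#' @seealso \code{\link{readPeakBed}}, \code{\link{normalizePeaks}},
#'   \code{\link{segmentPeaks}}
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 50), c(20, 80)),
#'                              score = c(5, 2))
#' CallerPeaks("macs", gr)
#' @aliases CallerPeaks-class
#' @export
setClass("CallerPeaks",
    slots = c(caller = "character", peaks = "GRanges"))

setValidity("CallerPeaks", function(object) {
    msg <- character()
    if (length(object@caller) != 1L || is.na(object@caller) ||
        !nzchar(object@caller))
        msg <- c(msg, "'caller' must be a single non-empty string")
    pk <- object@peaks
    if (!("score" %in% colnames(S4Vectors::mcols(pk))))
        msg <- c(msg, "'peaks' must carry a 'score' metadata column")
    else {
        sc <- S4Vectors::mcols(pk)$score
        if (!is.numeric(sc) || anyNA(sc) || any(sc < 0))
            msg <- c(msg, "peak scores must be non-negative numbers")
    }
    if (length(pk) > 1L) {
        if (S4Vectors::isSorted(pk) == FALSE)
            msg <- c(msg, "'peaks' must be sorted by (chrom, start, end)")
        if (!identical(GenomicRanges::isDisjoint(pk), TRUE))
            msg <- c(msg, "peaks within one caller must not overlap")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn CallerPeaks-class Constructor; merges intra-caller overlapping
#'   intervals (score of a merged peak = max of its members) and sorts.
#' @param caller single string, the peak-finder identifier.
#' @param peaks a \code{GRanges}; a numeric \code{score} column is used if
#'   present, otherwise all scores are set to 0.
#' @export
CallerPeaks <- function(caller, peaks) {
    if (!is(peaks, "GRanges"))
        stop("'peaks' must be a GRanges")
    if (!("score" %in% colnames(S4Vectors::mcols(peaks))))
        S4Vectors::mcols(peaks)$score <- numeric(length(peaks))
    sc <- as.numeric(S4Vectors::mcols(peaks)$score)
    sc[is.na(sc)] <- 0
    S4Vectors::mcols(peaks) <- S4Vectors::DataFrame(score = sc)
    # merge truly overlapping peaks only; abutting peaks stay distinct
    red <- GenomicRanges::reduce(peaks, min.gapwidth = 0L, with.revmap = TRUE)
    mx <- vapply(S4Vectors::mcols(red)$revmap,
                 function(i) max(sc[i]), numeric(1))
    S4Vectors::mcols(red) <- S4Vectors::DataFrame(score = mx)
    new("CallerPeaks", caller = as.character(caller),
        peaks = GenomicRanges::sort(red))
}

#' A piecewise-constant signal track for one chromosome
#'
#' A \code{WigTrack} is the in-memory form of one WIG signal: an ordered set
#' of fixed-width steps, each with one score, on a single chromosome. Step
#' starts are 0-based; serialization to WIG (\code{\link{writeWig}}) is
#' 1-based fixedStep. Gaps between steps are allowed (they become separate
#' fixedStep blocks on output); steps never overlap.
#'
#' @slot chrom single chromosome name.
#' @slot span step width in bp (integer \eqn{\ge 1}).
#' @slot starts integer vector of 0-based step starts, strictly increasing,
#'   consecutive starts at least \code{span} apart.
#' @slot scores numeric vector, one score per step.
#'
#' @seealso \code{\link{readWig}}, \code{\link{mergeTracks}},
#'   \code{\link{unifySteps}}
#' @aliases WigTrack-class
#' @export
setClass("WigTrack",
    slots = c(chrom = "character", span = "integer",
              starts = "integer", scores = "numeric"))

setValidity("WigTrack", function(object) {
    msg <- character()
    if (length(object@chrom) != 1L || !nzchar(object@chrom))
        msg <- c(msg, "'chrom' must be a single non-empty string")
    if (length(object@span) != 1L || is.na(object@span) || object@span < 1L)
        msg <- c(msg, "'span' must be a single integer >= 1")
    if (length(object@starts) != length(object@scores))
        msg <- c(msg, "'starts' and 'scores' must have equal length")
    if (anyNA(object@starts) || anyNA(object@scores))
        msg <- c(msg, "starts and scores must not contain NA")
    if (length(object@starts) > 1L) {
        d <- diff(object@starts)
        if (any(d <= 0L))
            msg <- c(msg, "step starts must be strictly increasing")
        else if (!is.na(object@span) && any(d < object@span))
            msg <- c(msg, "consecutive steps must not overlap (gap < span)")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn WigTrack-class Constructor.
#' @param chrom,span,starts,scores see slots.
#' @export
WigTrack <- function(chrom, span, starts = integer(), scores = numeric()) {
    o <- order(starts)
    new("WigTrack", chrom = as.character(chrom),
        span = as.integer(span),
        starts = as.integer(starts)[o], scores = as.numeric(scores)[o])
}

#' A curated truth annotation for evaluation
#'
#' Holds intervals manually classified as True Positive, False Positive or
#' Ambiguous binding sites. The three sets are pairwise non-overlapping;
#' ambiguous intervals are excluded from both evaluation counts.
#'
#' @slot tp,fp,ambiguous \code{GRanges} of the three annotation classes.
#' @seealso \code{\link{intersectWithTruth}}, \code{\link{readTruthBed}},
#'   \code{\link{generateTruth}}
#' @aliases TruthSet-class
#' @export
setClass("TruthSet",
    slots = c(tp = "GRanges", fp = "GRanges", ambiguous = "GRanges"))

setValidity("TruthSet", function(object) {
    all3 <- c(GenomicRanges::granges(object@tp),
              GenomicRanges::granges(object@fp),
              GenomicRanges::granges(object@ambiguous))
    if (!GenomicRanges::isDisjoint(all3))
        "tp, fp and ambiguous intervals must be pairwise non-overlapping"
    else TRUE
})

#' @describeIn TruthSet-class Constructor.
#' @param tp,fp,ambiguous \code{GRanges} (defaults: empty).
#' @export
TruthSet <- function(tp = GenomicRanges::GRanges(),
                     fp = GenomicRanges::GRanges(),
                     ambiguous = GenomicRanges::GRanges()) {
    new("TruthSet", tp = GenomicRanges::sort(GenomicRanges::granges(tp)),
        fp = GenomicRanges::sort(GenomicRanges::granges(fp)),
        ambiguous = GenomicRanges::sort(GenomicRanges::granges(ambiguous)))
}

#' Constant-coverage segments from multiple peak finders
#'
#' The result of \code{\link{segmentPeaks}}: the union of all callers' peaks,
#' partitioned at every peak boundary into maximal intervals with a constant
#' set of covering peaks. Each segment carries the number of distinct callers
#' covering it (\code{votes}), the sum of normalized scores of the covering
#' peaks (\code{aggScore}) and the set of contributing callers.
#'
#' @slot segments disjoint sorted \code{GRanges} with metadata columns
#'   \code{votes} (integer), \code{aggScore} (numeric) and \code{callers}
#'   (\code{CharacterList}).
#' @slot nCallers number of callers that entered the segmentation.
#' @seealso \code{\link{selectConsensus}}
#' @aliases ConsensusSegments-class
#' @export
setClass("ConsensusSegments",
    slots = c(segments = "GRanges", nCallers = "integer"))

setValidity("ConsensusSegments", function(object) {
    msg <- character()
    gr <- object@segments
    need <- c("votes", "aggScore", "callers")
    if (!all(need %in% colnames(S4Vectors::mcols(gr))))
        return("segments need metadata columns votes, aggScore, callers")
    v <- S4Vectors::mcols(gr)$votes
    cs <- S4Vectors::mcols(gr)$callers
    if (any(v < 1L)) msg <- c(msg, "votes must be >= 1")
    if (!all(v == lengths(cs)))
        msg <- c(msg, "votes must equal the number of distinct callers")
    if (any(v > object@nCallers))
        msg <- c(msg, "votes cannot exceed the number of callers in the run")
    if (any(S4Vectors::mcols(gr)$aggScore < 0))
        msg <- c(msg, "aggScore must be non-negative")
    if (length(gr) > 1L && !GenomicRanges::isDisjoint(gr))
        msg <- c(msg, "segments must be disjoint")
    if (length(msg)) msg else TRUE
})

#' A simulated peak-caller behaviour profile
#'
#' Parameters controlling how \code{\link{simulateCaller}} turns a truth set
#' into a caller-like peak list: per-site report probability, expected count
#' of false peaks, a caller-specific score scale (emulating the wildly
#' different score ranges of real peak finders), a gamma shape for the score
#' distribution, and boundary jitter.
#'
#' @slot caller caller identifier.
#' @slot sensitivity probability in [0,1] that a true site is reported.
#' @slot fpCount expected number of false peaks (Poisson mean).
#' @slot scoreScale multiplier applied to all emitted scores.
#' @slot scoreShape gamma shape of the false-peak score distribution; true
#'   sites use \code{scoreShape + 2} so they score stochastically higher.
#' @slot jitter maximum perturbation (bp) of reported peak boundaries.
#' @slot seed integer seed making the caller's output fully deterministic.
#' @aliases CallerProfile-class
#' @export
setClass("CallerProfile",
    slots = c(caller = "character", sensitivity = "numeric",
              fpCount = "numeric", scoreScale = "numeric",
              scoreShape = "numeric", jitter = "integer", seed = "integer"))

setValidity("CallerProfile", function(object) {
    msg <- character()
    if (object@sensitivity < 0 || object@sensitivity > 1)
        msg <- c(msg, "sensitivity must be in [0, 1]")
    if (object@fpCount < 0) msg <- c(msg, "fpCount must be >= 0")
    if (object@jitter < 0L) msg <- c(msg, "jitter must be >= 0")
    if (object@scoreScale <= 0) msg <- c(msg, "scoreScale must be > 0")
    if (object@scoreShape <= 0) msg <- c(msg, "scoreShape must be > 0")
    if (length(msg)) msg else TRUE
})

#' @describeIn CallerProfile-class Constructor.
#' @param caller,sensitivity,fpCount,scoreScale,scoreShape,jitter,seed see
#'   slots.
#' @export
CallerProfile <- function(caller, sensitivity = 0.9, fpCount = 0,
                          scoreScale = 1, scoreShape = 2, jitter = 25L,
                          seed = 1L) {
    new("CallerProfile", caller = as.character(caller),
        sensitivity = as.numeric(sensitivity), fpCount = as.numeric(fpCount),
        scoreScale = as.numeric(scoreScale),
        scoreShape = as.numeric(scoreShape),
        jitter = as.integer(jitter), seed = as.integer(seed))
}
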