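#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn CallerPeaks-class Caller identifier.
#' @param x a \code{CallerPeaks}.
#' @export
setMethod("caller", "CallerPeaks", function(x) x@caller)

#' @describeIn CallerPeaks-class Number of peaks.
#' @export
setMethod("nPeaks", "CallerPeaks", function(x) length(x@peaks))

#' @describeIn CallerPeaks-class Peak scores, in peak order.
#' @export
setMethod("scores", "CallerPeaks", function(x) S4Vectors::mcols(x@peaks)$score)

#' @describeIn CallerPeaks-class Replace the peak scores (coordinates and
#'   caller are untouched).
#' @param value replacement numeric vector, one score per peak.
#' @export
setReplaceMethod("scores", "CallerPeaks", function(x, value) {
    S4Vectors::mcols(x@peaks)$score <- as.numeric(value)
    methods::validObject(x)
    x
})

#' @describeIn CallerPeaks-class Underlying \code{GRanges} of peaks.
#' @export
setMethod("granges", "CallerPeaks", function(x, use.names = TRUE,
                                             use.mcols = FALSE, ...) {
    if (use.mcols) x@peaks else GenomicRanges::granges(x@peaks)
})

setMethod("show", "CallerPeaks", function(object) {
    cat("CallerPeaks from '", object@caller, "': ",
        length(object@peaks), " peak(s)\n", sep = "")
    if (length(object@peaks)) methods::show(object@peaks)
})

#' @describeIn WigTrack-class Step width in bp.
#' @param x a \code{WigTrack}.
#' @export
setMethod("span", "WigTrack", function(x) x@span)

#' @describeIn WigTrack-class 0-based step starts.
#' @export
setMethod("stepStarts", "WigTrack", function(x) x@starts)

#' @describeIn WigTrack-class Step scores.
#' @export
setMethod("scores", "WigTrack", function(x) x@scores)

#' @describeIn WigTrack-class Number of steps.
#' @export
setMethod("length", "WigTrack", function(x) length(x@starts))

#' Chromosome of a WigTrack
#' @param x a \code{WigTrack}.
#' @export
wigChrom <- function(x) x@chrom

setMethod("show", "WigTrack", function(object) {
    cat("WigTrack on ", object@chrom, ": ", length(object@starts),
        " step(s) of span ", object@span, "\n", sep = "")
    if (length(object@starts)) {
        n <- min(5L, length(object@starts))
        cat("  start ", paste(object@starts[seq_len(n)], collapse = " "),
            if (length(object@starts) > n) " ..." else "", "\n", sep = "")
        cat("  score ", paste(format(object@scores[seq_len(n)]),
                              collapse = " "),
            if (length(object@starts) > n) " ..." else "", "\n", sep = "")
    }
})

#' @describeIn TruthSet-class True-positive intervals.
#' @param x a \code{TruthSet}.
#' @export
setMethod("tpIntervals", "TruthSet", function(x) x@tp)

#' @describeIn TruthSet-class False-positive intervals.
#' @export
setMethod("fpIntervals", "TruthSet", function(x) x@fp)

#' @describeIn TruthSet-class Ambiguous intervals.
#' @export
setMethod("ambiguousIntervals", "TruthSet", function(x) x@ambiguous)

setMethod("show", "TruthSet", function(object) {
    cat("TruthSet: ", length(object@tp), " TP, ", length(object@fp),
        " FP, ", length(object@ambiguous), " ambiguous interval(s)\n",
        sep = "")
})

#' @describeIn ConsensusSegments-class Vote counts per segment.
#' @param x a \code{ConsensusSegments}.
#' @export
setMethod("votes", "ConsensusSegments",
          function(x) S4Vectors::mcols(x@segments)$votes)

#' @describeIn ConsensusSegments-class Aggregated (summed) normalized score
#'   per segment.
#' @export
setMethod("aggScore", "ConsensusSegments",
          function(x) S4Vectors::mcols(x@segments)$aggScore)

#' @describeIn ConsensusSegments-class Contributing callers per segment.
#' @export
setMethod("callerSets", "ConsensusSegments",
          function(x) S4Vectors::mcols(x@segments)$callers)

#' @describeIn ConsensusSegments-class Segments as an annotated
#'   \code{GRanges}.
#' @param use.names,use.mcols,... see \code{GenomicRanges::granges}.
#' @export
setMethod("granges", "ConsensusSegments",
          function(x, use.names = TRUE, use.mcols = FALSE, ...) {
    if (use.mcols) x@segments else GenomicRanges::granges(x@segments)
})

#' @describeIn ConsensusSegments-class Number of segments.
#' @export
setMethod("length", "ConsensusSegments", function(x) length(x@segments))

setMethod("show", "ConsensusSegments", function(object) {
    cat("ConsensusSegments: ", length(object@segments),
        " segment(s) from ", object@nCallers, " caller(s)\n", sep = "")
    if (length(object@segments)) methods::show(object@segments)
})
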