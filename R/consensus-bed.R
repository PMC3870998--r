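#' @include AllClasses.R methods.R
NULL

#' Segment the genome at peak boundaries and count votes
#'
#' Overlays the peak lists of all callers and partitions the covered genome
#' at every peak boundary: each maximal interval with a constant set of
#' covering peaks becomes one segment. A segment records how many distinct
#' callers cover it (its \emph{votes}), the sum of the (normalized) scores of
#' all covering peaks (\code{aggScore}), and which callers contributed.
#' Bases covered by no peak are omitted.
#'
#' @param callerLists non-empty list of \code{\link{CallerPeaks}}, one per
#'   caller; caller identifiers must be distinct.
#' @return a \code{\link{ConsensusSegments}} object.
#' @examples
#' pf <- function(id, st, en, sc) CallerPeaks(id, GenomicRanges::GRanges(
#'     "chr1", IRanges::IRanges(st + 1, en), score = sc))
#' segs <- segmentPeaks(list(pf("pf1", c(0, 9), c(7, 15), c(1, 1)),
#'                           pf("pf2", 5, 25, 1), pf("pf3", 10, 20, 1)))
#' votes(segs)
#' @export
segmentPeaks <- function(callerLists) {
    if (!length(callerLists)) stop("no caller peak lists", call. = FALSE)
    stopifnot(all(vapply(callerLists, is, logical(1), "CallerPeaks")))
    ids <- vapply(callerLists, caller, character(1))
    if (anyDuplicated(ids))
        stop("caller identifiers must be distinct", call. = FALSE)
    all <- do.call(c, unname(lapply(callerLists, function(x) {
        gr <- x@peaks
        S4Vectors::mcols(gr)$caller <- x@caller
        gr
    })))
    if (!length(all))
        return(new("ConsensusSegments",
                   segments = GenomicRanges::GRanges(
                       votes = integer(), aggScore = numeric(),
                       callers = IRanges::CharacterList()),
                   nCallers = length(callerLists)))
    seg <- GenomicRanges::disjoin(all)
    hits <- GenomicRanges::findOverlaps(seg, all)
    qh <- S4Vectors::queryHits(hits)
    sc <- S4Vectors::mcols(all)$score[S4Vectors::subjectHits(hits)]
    cl <- S4Vectors::mcols(all)$caller[S4Vectors::subjectHits(hits)]
    f <- factor(qh, levels = seq_along(seg))
    agg <- as.numeric(rowsum(sc, f))
    callerSets <- IRanges::CharacterList(
        lapply(split(cl, f), function(z) sort(unique(z))))
    S4Vectors::mcols(seg) <- S4Vectors::DataFrame(
        votes = as.integer(lengths(callerSets)), aggScore = agg,
        callers = callerSets)
    new("ConsensusSegments", segments = GenomicRanges::sort(seg),
        nCallers = length(callerLists))
}

## Merge exactly contiguous kept segments (shared boundary only -- 1-bp gaps
## are NOT bridged). Annotation of a merged region: max votes and max score
## over its member segments.
.mergeContiguous <- function(gr) {
    if (!length(gr)) {
        return(GenomicRanges::GRanges(votes = integer(), score = numeric()))
    }
    red <- GenomicRanges::reduce(gr, min.gapwidth = 1L, with.revmap = TRUE)
    rv <- S4Vectors::mcols(red)$revmap
    S4Vectors::mcols(red) <- S4Vectors::DataFrame(
        votes = vapply(rv, function(i)
            max(S4Vectors::mcols(gr)$votes[i]), integer(1)),
        score = vapply(rv, function(i)
            max(S4Vectors::mcols(gr)$aggScore[i]), numeric(1)))
    GenomicRanges::sort(red)
}

.checkSegments <- function(segments, minRank) {
    stopifnot(is(segments, "ConsensusSegments"))
    if (!is.numeric(minRank) || length(minRank) != 1L || is.na(minRank) ||
        minRank < 1 || minRank != floor(minRank))
        stop("'minRank' must be a single integer >= 1", call. = FALSE)
    if (minRank > segments@nCallers)
        warning("minRank (", minRank, ") exceeds the number of callers (",
                segments@nCallers, "); output is empty", call. = FALSE)
}

#' In-degree centrality voting selection
#'
#' The simplest consensus rule: report every segment supported by at least
#' \code{minRank} distinct callers, merging exactly contiguous qualifying
#' segments into single regions. Scores are ignored entirely, so no
#' normalization is required. With the four intervals [0,7), [9,15) (caller
#' 1), [5,25) (caller 2) and [10,20) (caller 3), \code{minRank = 2} reports
#' [5,7) and [9,20); \code{minRank = 3} reports [10,15).
#'
#' @param segments a \code{\link{ConsensusSegments}}.
#' @param minRank minimum number of supporting callers.
#' @return a \code{GRanges} of consensus regions with metadata columns
#'   \code{votes} (max votes among merged member segments) and \code{score}
#'   (max aggregated score).
#' @export
votingSelect <- function(segments, minRank) {
    .checkSegments(segments, minRank)
    .mergeContiguous(segments@segments[votes(segments) >= minRank])
}

#' minFP selection: trade sensitivity for precision
#'
#' \code{MaxP} is the highest aggregated score among segments with fewer
#' than \code{minRank} votes -- i.e. the strongest region that still lacks
#' caller support. Only segments scoring strictly above \code{MaxP} are
#' reported, discarding anything a low-vote region could match. If every
#' segment reaches \code{minRank} votes, everything is reported.
#'
#' @inheritParams votingSelect
#' @return a \code{GRanges} of consensus regions (as \code{votingSelect}).
#' @export
minfpSelect <- function(segments, minRank) {
    .checkSegments(segments, minRank)
    gr <- segments@segments
    v <- votes(segments)
    sc <- aggScore(segments)
    maxP <- if (any(v < minRank)) max(sc[v < minRank]) else -Inf
    .mergeContiguous(gr[sc > maxP])
}

#' minFN selection: trade precision for sensitivity
#'
#' \code{MinP} is the lowest aggregated score among segments with at least
#' \code{minRank} votes -- the weakest well-supported region. Every segment
#' scoring at least \code{MinP} is reported, so no well-supported region is
#' ever lost, at the cost of admitting low-vote segments with high scores.
#' If no segment reaches \code{minRank} votes the output is empty.
#'
#' @inheritParams votingSelect
#' @return a \code{GRanges} of consensus regions (as \code{votingSelect}).
#' @export
minfnSelect <- function(segments, minRank) {
    .checkSegments(segments, minRank)
    gr <- segments@segments
    v <- votes(segments)
    sc <- aggScore(segments)
    if (!any(v >= minRank)) return(.mergeContiguous(gr[integer()]))
    minP <- min(sc[v >= minRank])
    .mergeContiguous(gr[sc >= minP])
}

#' Select consensus regions by the configured rule
#'
#' Dispatcher over \code{\link{votingSelect}}, \code{\link{minfpSelect}} and
#' \code{\link{minfnSelect}}.
#'
#' @inheritParams votingSelect
#' @param method \code{"voting"}, \code{"minfp"} or \code{"minfn"}.
#' @return a \code{GRanges} of consensus regions.
#' @export
selectConsensus <- function(segments, method = c("voting", "minfp", "minfn"),
                            minRank = 2L) {
    method <- match.arg(method)
    switch(method,
           voting = votingSelect(segments, minRank),
           minfp = minfpSelect(segments, minRank),
           minfn = minfnSelect(segments, minRank))
}
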