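#' @include AllClasses.R methods.R normalize.R
NULL

## Per-base score function of a track over [lo, hi): numeric vector with 0
## for uncovered bases. Only used for resampling and by tests' oracles.
.trackBaseScores <- function(track, lo, hi) {
    v <- numeric(hi - lo)
    for (i in seq_along(track@starts)) {
        a <- max(track@starts[i], lo)
        b <- min(track@starts[i] + track@span, hi)
        if (b > a) v[(a - lo + 1):(b - lo)] <- track@scores[i]
    }
    v
}

## Resample one track onto the absolute grid of windows [k*t, (k+1)*t).
## Windows overlapping >= 1 covered base are emitted; the window score is
## the mean over all t bases (uncovered bases count 0), which conserves
## score mass exactly and is the identity for grid-aligned divisible steps.
.regridTrack <- function(track, t) {
    if (!length(track@starts)) return(WigTrack(track@chrom, t))
    if (track@span == t && all(track@starts %% t == 0L))
        return(WigTrack(track@chrom, t, track@starts, track@scores))
    if (track@span %% t == 0L && all(track@starts %% t == 0L)) {
        k <- track@span %/% t
        starts <- rep(track@starts, each = k) +
            rep(seq_len(k) - 1L, times = length(track@starts)) * t
        return(WigTrack(track@chrom, t, starts, rep(track@scores, each = k)))
    }
    lo <- (min(track@starts) %/% t) * t
    hi <- as.integer(ceiling((max(track@starts) + track@span) / t)) * t
    base <- .trackBaseScores(track, lo, hi)
    win <- matrix(base, nrow = t)
    covered <- matrix(.trackBaseScores(
        WigTrack(track@chrom, track@span, track@starts,
                 rep(1, length(track@starts))), lo, hi), nrow = t)
    keep <- colSums(covered) > 0
    WigTrack(track@chrom, t,
             starts = lo + (which(keep) - 1L) * t,
             scores = colMeans(win)[keep])
}

#' Unify WIG step sizes across tracks
#'
#' All step sizes are reduced to the smallest span among the input tracks.
#' Steps whose span is a multiple of the target (and whose starts lie on the
#' target grid) are split exactly into sub-steps carrying the same score;
#' anything else is resampled per base onto the absolute target grid
#' (window score = mean over the window, uncovered bases scoring 0), which
#' conserves total score mass.
#'
#' @param tracks non-empty list of \code{\link{WigTrack}} objects.
#' @return list of \code{WigTrack} objects, all with the same span.
#' @export
unifySteps <- function(tracks) {
    if (!length(tracks)) stop("no WIG tracks", call. = FALSE)
    stopifnot(all(vapply(tracks, is, logical(1), "WigTrack")))
    t <- min(vapply(tracks, span, integer(1)))
    lapply(tracks, .regridTrack, t = t)
}

#' Normalize a WIG track's step scores
#'
#' The step-score multiset of one caller's track plays the role its peak
#' scores play in BED mode; \code{maxSteps} (the largest step count over all
#' tracks in the run) stands in for the largest peak count. Only the two
#' distribution-free methods are meaningful at step level, so
#' \code{"average"} and \code{"naive_quantile"} are the only ones accepted.
#'
#' @param track a \code{\link{WigTrack}}.
#' @param method \code{"average"} or \code{"naive_quantile"}.
#' @param maxSteps largest step count over the tracks in the run (defaults
#'   to the track's own step count).
#' @param quantile quantile for \code{"naive_quantile"} (default 0.75).
#' @return a \code{WigTrack} with transformed scores.
#' @export
normalizeWigTrack <- function(track, method = c("average", "naive_quantile"),
                              maxSteps = length(track@starts),
                              quantile = 0.75) {
    method <- match.arg(method)
    stopifnot(is(track, "WigTrack"))
    if (!length(track@starts)) return(track)
    s <- track@scores
    out <- switch(method,
        average = .averageScores(s, maxSteps),
        naive_quantile = .naiveQuantileScores(s, quantile, maxSteps))
    WigTrack(track@chrom, track@span, track@starts, out)
}

#' Merge unified WIG tracks by positionwise score summation
#'
#' All tracks must be on one chromosome and share one span (run
#' \code{\link{unifySteps}} first). Every step position covered by at least
#' one track appears in the output with the sum of the scores of all tracks
#' at that position.
#'
#' @param tracks non-empty list of \code{\link{WigTrack}} objects with equal
#'   span and chromosome.
#' @return a single merged \code{\link{WigTrack}}.
#' @export
mergeTracks <- function(tracks) {
    if (!length(tracks)) stop("no WIG tracks", call. = FALSE)
    stopifnot(all(vapply(tracks, is, logical(1), "WigTrack")))
    spans <- vapply(tracks, span, integer(1))
    if (length(unique(spans)) != 1L)
        stop("tracks must share one span; run unifySteps() first",
             call. = FALSE)
    chroms <- unique(vapply(tracks, wigChrom, character(1)))
    if (length(chroms) != 1L)
        stop("tracks span multiple chromosomes; merge per chromosome",
             call. = FALSE)
    st <- unlist(lapply(tracks, stepStarts))
    sc <- unlist(lapply(tracks, scores))
    if (!length(st)) return(WigTrack(chroms, spans[1L]))
    tot <- rowsum(sc, st)            # groups sorted by numeric start
    WigTrack(chroms, spans[1L], as.integer(rownames(tot)), as.numeric(tot))
}

#' Drop steps below a score cut-off
#'
#' Keeps steps with score \code{>= cutoff} so the highest-weighted consensus
#' regions can be extracted from a merged track.
#'
#' @param track a \code{\link{WigTrack}}.
#' @param cutoff non-negative score threshold; 0 keeps everything.
#' @return a filtered \code{WigTrack}.
#' @export
applyCutoff <- function(track, cutoff) {
    stopifnot(is(track, "WigTrack"))
    if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
        cutoff < 0)
        stop("'cutoff' must be a single value >= 0", call. = FALSE)
    keep <- track@scores >= cutoff
    WigTrack(track@chrom, track@span, track@starts[keep],
             track@scores[keep])
}

#' Collapse a track's contiguous steps into BED-ready regions
#'
#' Exactly adjacent surviving steps are merged into one interval; the region
#' score is the maximum step score. Useful for exporting above-cutoff runs
#' of a merged consensus track as BED.
#'
#' @param track a \code{\link{WigTrack}}.
#' @return a \code{GRanges} with \code{score} metadata (and \code{votes} set
#'   to \code{NA}, for \code{\link{writeConsensusBed}} compatibility).
#' @export
wigToRegions <- function(track) {
    stopifnot(is(track, "WigTrack"))
    if (!length(track@starts))
        return(GenomicRanges::GRanges(votes = integer(), score = numeric()))
    blk <- cumsum(c(TRUE, diff(track@starts) != track@span))
    idx <- split(seq_along(track@starts), blk)
    GenomicRanges::GRanges(rep(track@chrom, length(idx)),
        IRanges::IRanges(
            start = unname(vapply(idx, function(i) track@starts[i[1L]] + 1L,
                                  numeric(1))),
            end = unname(vapply(idx, function(i)
                track@starts[i[length(i)]] + track@span, numeric(1)))),
        votes = rep(NA_integer_, length(idx)),
        score = unname(vapply(idx, function(i) max(track@scores[i]),
                              numeric(1))))
}

#' Full WIG-mode consensus pipeline
#'
#' Unifies step sizes, normalizes each track's step scores, sums overlapping
#' steps positionwise per chromosome and optionally applies a score cut-off.
#'
#' @param tracks non-empty list of \code{\link{WigTrack}} objects (any mix
#'   of chromosomes).
#' @param normalization \code{"average"}, \code{"naive_quantile"}, or
#'   \code{"none"} to merge raw scores.
#' @param quantile quantile for naive-quantile normalization.
#' @param cutoff optional score threshold applied after merging
#'   (\code{NULL} = keep everything).
#' @return list of merged \code{\link{WigTrack}} objects, one per
#'   chromosome, ordered by chromosome name.
#' @export
wigConsensus <- function(tracks, normalization = c("average",
                                                   "naive_quantile", "none"),
                         quantile = 0.75, cutoff = NULL) {
    normalization <- match.arg(normalization)
    uni <- unifySteps(tracks)
    if (normalization != "none") {
        maxSteps <- max(vapply(uni, length, integer(1)))
        uni <- lapply(uni, function(t) {
            if (!length(t@starts)) return(t)
            normalizeWigTrack(t, normalization, maxSteps = maxSteps,
                              quantile = quantile)
        })
    }
    byChrom <- split(uni, vapply(uni, wigChrom, character(1)))
    merged <- lapply(byChrom, mergeTracks)
    if (!is.null(cutoff))
        merged <- lapply(merged, applyCutoff, cutoff = cutoff)
    unname(merged[order(names(merged))])
}
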