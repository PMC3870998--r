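#' @include AllClasses.R methods.R
NULL

## Score-vector kernels. Each takes the raw score multiset of ONE caller and
## returns transformed scores in input order; normalizePeaks() wraps them for
## CallerPeaks objects. Kept as plain numeric functions so the WIG path can
## reuse them on step scores.

.ceilingScores <- function(x) ceiling(x - 1e-9)

.roundHalfUp <- function(x) floor(x + 0.5)

#' Empirical quantile of a score multiset
#'
#' The quantile definition used by naive-quantile normalization: the element
#' at 1-based index \code{ceiling(q * n)} of the ascending-sorted scores.
#' With \code{q = 0.8} on scores (2, 4, 4, 8, 12) this selects 8.
#'
#' @param scores non-empty numeric vector.
#' @param q quantile in (0, 1].
#' @return a single score value.
#' @export
empiricalQuantile <- function(scores, q) {
    if (!length(scores)) stop("empty score set", call. = FALSE)
    if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q > 1)
        stop("'q' must be a single value in (0, 1]", call. = FALSE)
    sort(scores)[max(1L, as.integer(ceiling(q * length(scores) - 1e-9)))]
}

.normalScores <- function(s, normalShift, maxNoOfPeaks) {
    if (length(s) < 1L) return(s)
    sdv <- stats::sd(s)        # sample sd (n - 1 denominator)
    if (length(s) < 2L || is.na(sdv) || sdv == 0) {
        warning("all scores identical; normal normalization maps every ",
                "score to ceiling(normal_shift * max_no_of_peaks)",
                call. = FALSE)
        return(rep(.ceilingScores(normalShift * maxNoOfPeaks), length(s)))
    }
    v <- .ceilingScores(((s - mean(s)) / sdv + normalShift) * maxNoOfPeaks)
    pmax(v, 0)                 # outliers below -shift sd truncate to 0
}

.naiveQuantileScores <- function(s, quantile, maxNoOfPeaks) {
    qv <- empiricalQuantile(s, quantile)
    if (qv == 0)
        stop("quantile value is 0; cannot divide scores", call. = FALSE)
    .ceilingScores(s / qv * maxNoOfPeaks)
}

.averageScores <- function(s, maxNoOfPeaks) {
    m <- mean(s)
    if (is.na(m) || m == 0)
        stop("mean score is 0; cannot divide scores", call. = FALSE)
    .roundHalfUp(s / m * maxNoOfPeaks)
}

## Shared clustering step for rank / top-rank: peaks with equal raw score
## form one cluster; returns per-input-element cluster index and sizes in
## the requested score order.
.scoreClusters <- function(s, decreasing = FALSE) {
    lev <- sort(unique(s), decreasing = decreasing)
    idx <- match(s, lev)
    list(idx = idx, sizes = tabulate(idx, nbins = length(lev)))
}

#' Rank and top-rank cluster scores
#'
#' Peaks sharing a raw score form a cluster. For \code{rankScores}, clusters
#' are taken ascending and cluster \eqn{i} (0-based) is scored
#' \eqn{(n_i/2 + \sum_{k<i} n_k) \cdot M / N} where \eqn{M} is
#' \code{maxNoOfPeaks} and \eqn{N} the caller's own peak count. For
#' \code{topRankScores}, clusters are taken descending (callers returning few
#' peaks are assumed to return few false positives, so ranks count down from
#' the top) and cluster \eqn{i} is scored
#' \eqn{M - (n_i - 1)/2 - \sum_{k<i} n_k}. Results are rounded up unless
#' \code{rounded = FALSE}, which exposes the raw fractional cluster scores
#' (e.g. the 7.5 assigned to a tied pair).
#'
#' @param s numeric vector of one caller's raw scores.
#' @param maxNoOfPeaks largest peak count over all callers in the run.
#' @param rounded round results up to integers (default)?
#' @return numeric vector of transformed scores, in input order.
#' @examples
#' rankScores(c(2, 4, 4, 8, 12), 10)             # 1 4 4 7 9
#' topRankScores(c(12, 8, 4, 4, 2), 10, FALSE)   # 10 9 7.5 7.5 6
#' @export
rankScores <- function(s, maxNoOfPeaks, rounded = TRUE) {
    if (!length(s)) stop("empty score set", call. = FALSE)
    cl <- .scoreClusters(s, decreasing = FALSE)
    below <- cumsum(c(0, cl$sizes))[seq_along(cl$sizes)]
    clScore <- (cl$sizes / 2 + below) * maxNoOfPeaks / length(s)
    out <- clScore[cl$idx]
    if (rounded) .ceilingScores(out) else out
}

#' @rdname rankScores
#' @export
topRankScores <- function(s, maxNoOfPeaks, rounded = TRUE) {
    if (!length(s)) stop("empty score set", call. = FALSE)
    cl <- .scoreClusters(s, decreasing = TRUE)
    above <- cumsum(c(0, cl$sizes))[seq_along(cl$sizes)]
    clScore <- maxNoOfPeaks - (cl$sizes - 1) / 2 - above
    out <- clScore[cl$idx]
    if (rounded) .ceilingScores(out) else out
}

.normMethods <- c("normal", "naive_quantile", "average", "rank", "top_rank")
.wigNormMethods <- c("average", "naive_quantile")

#' Normalize one caller's peak scores onto the common scale
#'
#' Peak finders score their peaks with unrelated enrichment measures, so raw
#' scores cannot be summed across callers. Each method maps one caller's raw
#' scores onto a scale tied to \code{maxNoOfPeaks}, the largest peak count
#' returned by any caller in the run:
#' \describe{
#'   \item{normal}{standardize to mean \code{normalShift} and unit sample
#'     standard deviation, multiply by \code{maxNoOfPeaks}, round up.
#'     Negative results (outliers more than \code{normalShift} standard
#'     deviations below the mean) are set to 0 but the peaks are kept for
#'     voting. Assumes roughly bell-shaped scores.}
#'   \item{naive_quantile}{divide by the empirical \code{quantile} of the
#'     caller's own scores, multiply by \code{maxNoOfPeaks}, round up.}
#'   \item{average}{divide by the caller's mean score, multiply by
#'     \code{maxNoOfPeaks}, round to the nearest integer.}
#'   \item{rank}{cluster equal scores, rank clusters ascending
#'     (\code{\link{rankScores}}); the top cluster lands near
#'     \code{maxNoOfPeaks}.}
#'   \item{top_rank}{rank clusters descending from \code{maxNoOfPeaks}
#'     (\code{\link{topRankScores}}); callers returning fewer peaks get
#'     systematically higher ranks.}
#' }
#' Only scores change; peak positions, count and caller identity are
#' untouched.
#'
#' @param x a \code{\link{CallerPeaks}}.
#' @param method one of \code{"normal"}, \code{"naive_quantile"},
#'   \code{"average"}, \code{"rank"}, \code{"top_rank"}.
#' @param maxNoOfPeaks largest peak count over all callers in the run; must
#'   be at least \code{nPeaks(x)}.
#' @param normalShift target mean for \code{method = "normal"} (default 3).
#' @param quantile quantile in (0, 1] for \code{method = "naive_quantile"}
#'   (default 0.75).
#' @return a \code{\link{CallerPeaks}} with transformed scores.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(1, 101, 201, 301, 401), width = 50),
#'     score = c(2, 4, 4, 8, 12))
#' x <- CallerPeaks("sissr", gr)
#' scores(normalizePeaks(x, "normal", maxNoOfPeaks = 10))  # 20 25 25 35 45
#' scores(normalizePeaks(x, "rank", maxNoOfPeaks = 10))    # 1 4 4 7 9
#' @export
normalizePeaks <- function(x, method = c("normal", "naive_quantile",
                                         "average", "rank", "top_rank"),
                           maxNoOfPeaks, normalShift = 3, quantile = 0.75) {
    method <- match.arg(method)
    stopifnot(is(x, "CallerPeaks"))
    if (missing(maxNoOfPeaks)) maxNoOfPeaks <- nPeaks(x)
    if (maxNoOfPeaks < nPeaks(x))
        stop("'maxNoOfPeaks' (", maxNoOfPeaks, ") is smaller than the ",
             "caller's own peak count (", nPeaks(x), ")", call. = FALSE)
    if (normalShift <= 0)
        stop("'normalShift' must be > 0", call. = FALSE)
    if (nPeaks(x) == 0L) return(x)
    s <- scores(x)
    scores(x) <- switch(method,
        normal = .normalScores(s, normalShift, maxNoOfPeaks),
        naive_quantile = .naiveQuantileScores(s, quantile, maxNoOfPeaks),
        average = .averageScores(s, maxNoOfPeaks),
        rank = rankScores(s, maxNoOfPeaks),
        top_rank = topRankScores(s, maxNoOfPeaks))
    x
}

#' Largest peak count across callers
#'
#' The common scale factor for all normalization methods: the maximal number
#' of peaks returned by any single caller in the run.
#'
#' @param callerLists list of \code{\link{CallerPeaks}}.
#' @return integer.
#' @export
maxNoOfPeaks <- function(callerLists) {
    if (!length(callerLists)) stop("no caller peak lists", call. = FALSE)
    max(vapply(callerLists, nPeaks, integer(1)))
}
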