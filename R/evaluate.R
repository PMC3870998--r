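#' @include AllClasses.R methods.R
NULL

#' Count true and false positives against a curated truth set
#'
#' True positives are counted at the level of truth intervals: a truth TP
#' interval counts once when at least one called region overlaps it by one
#' or more bases, so fragmented calls over one site earn no extra credit.
#' False positives are counted at the level of called regions: every region
#' overlapping no TP interval counts, except regions whose only annotated
#' overlap is with ambiguous intervals, which are dropped from the analysis
#' entirely.
#'
#' @param regions \code{GRanges} of called (consensus or single-caller)
#'   regions.
#' @param truth a \code{\link{TruthSet}} with at least one annotated
#'   interval.
#' @return list with integer elements \code{tp} and \code{fp}.
#' @export
intersectWithTruth <- function(regions, truth) {
    stopifnot(is(truth, "TruthSet"))
    if (!length(truth@tp) && !length(truth@fp) && !length(truth@ambiguous))
        stop("empty truth set", call. = FALSE)
    tp <- sum(IRanges::overlapsAny(truth@tp, regions))
    hitsTP <- IRanges::overlapsAny(regions, truth@tp)
    hitsFP <- IRanges::overlapsAny(regions, truth@fp)
    hitsAmb <- IRanges::overlapsAny(regions, truth@ambiguous)
    ambOnly <- !hitsTP & !hitsFP & hitsAmb
    list(tp = as.integer(tp), fp = as.integer(sum(!hitsTP & !ambOnly)))
}

#' Performance coordinates and distance to the perfect corner
#'
#' Maps TP/FP counts to a point in the unit square: \code{y} is sensitivity
#' (fraction of truth TP intervals recovered) and \code{x} is the false
#' discovery proportion FP / (TP + FP) (0 when nothing is called). A perfect
#' configuration sits at (0, 1); configurations are compared by their
#' Euclidean distance to that corner.
#'
#' @param tp,fp non-negative counts from \code{\link{intersectWithTruth}}.
#' @param nTruthTP number of TP intervals in the truth set (>= 1).
#' @return one-row \code{data.frame} with columns \code{tp}, \code{fp},
#'   \code{x}, \code{y}, \code{distance}.
#' @examples
#' performancePoint(12, 3, 20)
#' @export
performancePoint <- function(tp, fp, nTruthTP) {
    if (tp < 0 || fp < 0) stop("counts must be non-negative", call. = FALSE)
    if (nTruthTP < 1) stop("'nTruthTP' must be >= 1", call. = FALSE)
    y <- tp / nTruthTP
    x <- if (tp + fp == 0) 0 else fp / (tp + fp)
    data.frame(tp = tp, fp = fp, x = x, y = y,
               distance = sqrt(x^2 + (1 - y)^2))
}

.checkDistTable <- function(distances) {
    d <- as.matrix(distances)
    if (!is.numeric(d) || anyNA(d))
        stop("'distances' must be a complete numeric configurations x ",
             "datasets table", call. = FALSE)
    if (nrow(d) < 1L || ncol(d) < 1L)
        stop("'distances' must have at least one row and column",
             call. = FALSE)
    d
}

#' Combined ranking score across datasets
#'
#' Within each dataset, configurations are ranked ascending by their
#' distance to (0, 1) (ties receive average ranks); a configuration's
#' combined score is the sum of its ranks across datasets. Lower is better.
#' Ranking removes the dominance of the hardest dataset, whose large raw
#' distances would otherwise drown out the others.
#'
#' @param distances numeric matrix or data.frame, configurations in rows,
#'   datasets in columns, no missing cells.
#' @return named numeric vector of combined ranking scores.
#' @examples
#' d <- rbind(A = c(0.1, 0.2, 0.5), B = c(0.3, 0.4, 0.4))
#' combinedRanking(d)  # A 4, B 5
#' @export
combinedRanking <- function(distances) {
    d <- .checkDistTable(distances)
    r <- apply(d, 2L, rank)
    if (is.null(dim(r)))    # single configuration: apply() drops to vector
        r <- matrix(r, nrow = 1L, dimnames = list(rownames(d), NULL))
    rowSums(r)
}

#' Average normalized (studentized) distance
#'
#' Distances are studentized within each dataset (centered by the dataset
#' mean, scaled by the sample standard deviation); a configuration's score
#' is the mean of its studentized values across datasets. Lower is better.
#'
#' @inheritParams combinedRanking
#' @return named numeric vector of average normalized distances.
#' @export
averageNormalizedDistance <- function(distances) {
    d <- .checkDistTable(distances)
    if (nrow(d) < 2L)
        stop("need at least 2 configurations per dataset", call. = FALSE)
    sds <- apply(d, 2L, stats::sd)
    if (any(sds == 0))
        stop("zero within-dataset standard deviation; distances cannot be ",
             "studentized", call. = FALSE)
    z <- scale(d, center = TRUE, scale = sds)
    stats::setNames(rowMeans(z), rownames(d))
}

#' Evaluate several configurations against one or more truth sets
#'
#' Convenience wrapper producing the full comparison table: per dataset the
#' TP/FP counts, coordinates and distance of every configuration, plus the
#' cross-dataset combined ranking score and average normalized distance.
#'
#' @param regionSets named list (configurations) of lists (datasets) of
#'   called-region \code{GRanges}; or, with a single truth set, a named list
#'   of \code{GRanges}.
#' @param truthSets a \code{\link{TruthSet}} or list of them (datasets).
#' @return \code{data.frame} with one row per configuration x dataset and
#'   columns \code{configuration}, \code{dataset}, \code{tp}, \code{fp},
#'   \code{x}, \code{y}, \code{distance}, \code{ranking},
#'   \code{normalizedDistance}; the two cross-dataset scores are repeated on
#'   each dataset row of their configuration.
#' @export
evaluationReport <- function(regionSets, truthSets) {
    if (is(truthSets, "TruthSet")) truthSets <- list(dataset1 = truthSets)
    if (is.null(names(truthSets)))
        names(truthSets) <- paste0("dataset", seq_along(truthSets))
    regionSets <- lapply(regionSets, function(r)
        if (is(r, "GRanges")) rep(list(r), length(truthSets)) else r)
    if (is.null(names(regionSets)))
        names(regionSets) <- paste0("config", seq_along(regionSets))
    rows <- list()
    dist <- matrix(NA_real_, nrow = length(regionSets),
                   ncol = length(truthSets),
                   dimnames = list(names(regionSets), names(truthSets)))
    for (ci in seq_along(regionSets)) {
        for (di in seq_along(truthSets)) {
            tr <- truthSets[[di]]
            cnt <- intersectWithTruth(regionSets[[ci]][[di]], tr)
            pt <- performancePoint(cnt$tp, cnt$fp, length(tr@tp))
            dist[ci, di] <- pt$distance
            rows[[length(rows) + 1L]] <- cbind(
                data.frame(configuration = names(regionSets)[ci],
                           dataset = names(truthSets)[di]), pt)
        }
    }
    out <- do.call(rbind, rows)
    rk <- combinedRanking(dist)
    out$ranking <- rk[out$configuration]
    out$normalizedDistance <- if (nrow(dist) >= 2L)
        averageNormalizedDistance(dist)[out$configuration] else NA_real_
    rownames(out) <- NULL
    out
}
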