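# Independent per-base brute-force consensus, used as the oracle for the
# segmentation + selection pipeline. Works on a plain data.frame of peaks
# (caller, start, end, score; 0-based half-open, one chromosome) with none of
# the GenomicRanges machinery the implementation uses.

# Per-base structures: coverage matrix (bases x peaks), then maximal runs of
# constant covering-peak set become segments.
oracleSegments <- function(df, L) {
    npk <- nrow(df)
    cov <- matrix(FALSE, nrow = L, ncol = max(npk, 1L))
    for (i in seq_len(npk))
        cov[(df$start[i] + 1):df$end[i], i] <- TRUE
    covered <- rowSums(cov) > 0
    key <- do.call(paste0, as.data.frame(1L * cov))
    key[!covered] <- "-"
    r <- rle(key)
    ends <- cumsum(r$lengths)          # 1-based inclusive base index = end
    starts <- ends - r$lengths         # 0-based segment start
    segs <- data.frame(start = starts, end = ends)[r$values != "-", ,
                                                   drop = FALSE]
    segs$votes <- NA_integer_
    segs$agg <- NA_real_
    for (i in seq_len(nrow(segs))) {
        base <- segs$start[i] + 1L      # representative base of the run
        pk <- which(cov[base, ])
        segs$votes[i] <- length(unique(df$caller[pk]))
        segs$agg[i] <- sum(df$score[pk])
    }
    segs
}

# Merge exactly adjacent rows of a (start, end) table
oracleMergeAdjacent <- function(segs) {
    if (!nrow(segs)) return(segs[, c("start", "end")])
    o <- order(segs$start)
    st <- segs$start[o]; en <- segs$end[o]
    keepNew <- c(TRUE, st[-1] != en[-length(en)])
    grp <- factor(cumsum(keepNew), levels = unique(cumsum(keepNew)))
    data.frame(start = as.vector(tapply(st, grp, min)),
               end = as.vector(tapply(en, grp, max)), row.names = NULL)
}

oracleConsensus <- function(df, method, minRank, L) {
    segs <- oracleSegments(df, L)
    kept <- switch(method,
        voting = segs[segs$votes >= minRank, , drop = FALSE],
        minfp = {
            low <- segs$agg[segs$votes < minRank]
            maxP <- if (length(low)) max(low) else -Inf
            segs[segs$agg > maxP, , drop = FALSE]
        },
        minfn = {
            hi <- segs$agg[segs$votes >= minRank]
            if (!length(hi)) segs[integer(), , drop = FALSE]
            else segs[segs$agg >= min(hi), , drop = FALSE]
        })
    oracleMergeAdjacent(kept)
}

# Set of 0-based base positions covered by >= minRank distinct callers
oracleVotedBases <- function(df, minRank, L) {
    votes <- integer(L)
    for (cl in unique(df$caller)) {
        cb <- logical(L)
        d <- df[df$caller == cl, , drop = FALSE]
        for (i in seq_len(nrow(d)))
            cb[(d$start[i] + 1):d$end[i]] <- TRUE
        votes <- votes + cb
    }
    which(votes >= minRank) - 1L
}

# Canonical (start, end) double matrix for comparisons across sources
canonRegions <- function(m) {
    m <- as.matrix(m)
    matrix(as.numeric(m), ncol = 2,
           dimnames = list(NULL, c("start", "end")))
}

# 0-based bases covered by a consensus GRanges
regionBases <- function(gr) {
    if (!length(gr)) return(integer())
    unlist(mapply(seq, GenomicRanges::start(gr) - 1,
                  GenomicRanges::end(gr) - 1, SIMPLIFY = FALSE))
}
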