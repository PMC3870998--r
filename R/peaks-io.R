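#' @include AllClasses.R
NULL

## BED lines use 0-based half-open coordinates; GRanges is 1-based closed.
## All conversion happens here and in writers -- nowhere else.

.bedSkip <- function(lines) {
    grepl("^\\s*$", lines) | grepl("^(track|browser|#)", lines)
}

.parseBedFields <- function(lines, path) {
    keep <- which(!.bedSkip(lines))
    fields <- strsplit(trimws(lines[keep]), "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("malformed BED line ", keep[which(nf < 3L)[1L]], " in '", path,
             "': fewer than 3 fields", call. = FALSE)
    chrom <- vapply(fields, `[`, character(1), 1L)
    start <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
    bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end) | start < 0)
    if (length(bad))
        stop("malformed coordinates on line ", keep[bad[1L]], " in '", path,
             "'", call. = FALSE)
    if (any(end <= start))
        stop("end <= start on line ", keep[which(end <= start)[1L]],
             " in '", path, "'", call. = FALSE)
    name <- ifelse(nf >= 4L, vapply(fields, `[`, character(1), 4L), NA)
    scoreTxt <- ifelse(nf >= 5L, vapply(fields, `[`, character(1), 5L), NA)
    score <- suppressWarnings(as.numeric(scoreTxt))
    badScore <- which(!is.na(scoreTxt) & is.na(score))
    if (length(badScore))
        stop("non-numeric score on line ", keep[badScore[1L]], " in '", path,
             "'", call. = FALSE)
    score[is.na(score)] <- 0
    list(chrom = chrom, start = start, end = end, name = name, score = score)
}

#' Read one peak finder's BED output
#'
#' Parses a BED peak list (3 to 5+ columns; \code{track}/\code{browser}/
#' comment lines skipped) into a \code{\link{CallerPeaks}} object. Peaks
#' without a score column get score 0 -- the voting selection method does not
#' use scores, so score-less callers are still usable. Overlapping peaks from
#' the same caller are merged (score = max), so one caller casts at most one
#' vote per base.
#'
#' @param path path to a BED file.
#' @param caller identifier of the peak finder that produced the file.
#' @return a sorted \code{\link{CallerPeaks}}.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t7\tp1\t5", bed)
#' readPeakBed(bed, "macs")
#' @export
readPeakBed <- function(path, caller) {
    if (!file.exists(path))
        stop("no such file: '", path, "'", call. = FALSE)
    f <- .parseBedFields(readLines(path, warn = FALSE), path)
    gr <- GenomicRanges::GRanges(f$chrom,
        IRanges::IRanges(start = f$start + 1, end = f$end),
        score = f$score)
    CallerPeaks(caller, gr)
}

.fmtNum <- function(x) {
    vapply(x, function(v) {
        if (is.finite(v) && v == floor(v) && abs(v) < 1e15) sprintf("%.0f", v)
        else format(v, scientific = FALSE, trim = TRUE, digits = 15)
    }, character(1))
}

#' Write consensus regions as 5-column BED
#'
#' Serializes scored consensus regions to BED. The name column encodes the
#' vote count as \code{votes=K}; coordinates are written 0-based half-open.
#'
#' @param regions a \code{GRanges} with metadata columns \code{votes}
#'   (integer; missing values written as \code{votes=NA}) and \code{score}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readPeakBed}} for the inverse (scores and coordinates
#'   round-trip exactly).
#' @export
writeConsensusBed <- function(regions, path) {
    mc <- S4Vectors::mcols(regions)
    v <- if ("votes" %in% colnames(mc)) mc$votes else rep(NA, length(regions))
    sc <- if ("score" %in% colnames(mc)) mc$score else numeric(length(regions))
    lines <- if (length(regions)) {
        paste(as.character(GenomicRanges::seqnames(regions)),
              GenomicRanges::start(regions) - 1,
              GenomicRanges::end(regions),
              paste0("votes=", v), .fmtNum(sc), sep = "\t")
    } else character()
    writeLines(lines, path)
    invisible(path)
}

#' Write one caller's peaks as 5-column BED
#'
#' Used by \code{\link{runConsensus}} with \code{keepIndividual = TRUE} to
#' store each caller's (normalized) peak list next to the consensus output.
#'
#' @param x a \code{\link{CallerPeaks}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCallerBed <- function(x, path) {
    gr <- x@peaks
    lines <- if (length(gr)) {
        paste(as.character(GenomicRanges::seqnames(gr)),
              GenomicRanges::start(gr) - 1, GenomicRanges::end(gr),
              paste0(x@caller, "_", seq_along(gr)),
              .fmtNum(S4Vectors::mcols(gr)$score), sep = "\t")
    } else character()
    writeLines(lines, path)
    invisible(path)
}

#' Read a WIG signal file
#'
#' Parses fixedStep and variableStep WIG (with \code{span}) via
#' \code{rtracklayer} and returns one \code{\link{WigTrack}} per
#' (chromosome, span) combination, internally 0-based. Declaration blocks on
#' the same chromosome with the same span are coalesced into one track;
#' \code{\link{writeWig}} re-splits at gaps, so read/write round-trips are
#' identities.
#'
#' @param path path to a WIG file.
#' @return a list of \code{\link{WigTrack}} objects (empty for an empty
#'   file), ordered by chromosome then span.
#' @export
readWig <- function(path) {
    if (!file.exists(path))
        stop("no such file: '", path, "'", call. = FALSE)
    gr <- tryCatch(rtracklayer::import(path, format = "wig"),
                   error = function(e)
                       stop("failed to parse WIG '", path, "': ",
                            conditionMessage(e), call. = FALSE))
    if (!length(gr)) return(list())
    key <- paste(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::width(gr), sep = "\r")
    idx <- split(seq_along(gr), key)
    tracks <- lapply(idx, function(i) {
        WigTrack(chrom = as.character(GenomicRanges::seqnames(gr))[i[1L]],
                 span = GenomicRanges::width(gr)[i[1L]],
                 starts = GenomicRanges::start(gr)[i] - 1L,
                 scores = S4Vectors::mcols(gr)$score[i])
    })
    ord <- order(vapply(tracks, wigChrom, character(1)),
                 vapply(tracks, span, integer(1)))
    unname(tracks[ord])
}

.wigBlockLines <- function(track) {
    st <- track@starts
    newBlock <- c(TRUE, diff(st) != track@span)
    blk <- cumsum(newBlock)
    unlist(lapply(split(seq_along(st), blk), function(i) {
        c(sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                  track@chrom, st[i[1L]] + 1L, track@span, track@span),
          .fmtNum(track@scores[i]))
    }), use.names = FALSE)
}

#' Write WIG tracks as fixedStep blocks
#'
#' Emits 1-based fixedStep declarations with \code{span}; a new block starts
#' wherever consecutive steps are not exactly adjacent.
#'
#' @param track a \code{\link{WigTrack}} or a list of them.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeWig <- function(track, path) {
    if (is(track, "WigTrack")) track <- list(track)
    lines <- unlist(lapply(track, function(t)
        if (length(t@starts)) .wigBlockLines(t) else character()),
        use.names = FALSE)
    writeLines(lines, path)
    invisible(path)
}

#' Read a labelled truth-annotation BED
#'
#' The name column (4th field) classifies each interval as \code{TP},
#' \code{FP} or \code{ambiguous} (case-insensitive).
#'
#' @param path path to the annotation BED.
#' @return a \code{\link{TruthSet}}.
#' @export
readTruthBed <- function(path) {
    if (!file.exists(path))
        stop("no such file: '", path, "'", call. = FALSE)
    f <- .parseBedFields(readLines(path, warn = FALSE), path)
    lab <- tolower(f$name)
    if (anyNA(lab) || !all(lab %in% c("tp", "fp", "ambiguous", "amb")))
        stop("truth BED '", path, "' must label every interval TP, FP or ",
             "ambiguous in column 4", call. = FALSE)
    gr <- GenomicRanges::GRanges(f$chrom,
        IRanges::IRanges(start = f$start + 1, end = f$end))
    TruthSet(tp = gr[lab == "tp"], fp = gr[lab == "fp"],
             ambiguous = gr[lab %in% c("ambiguous", "amb")])
}

#' Write a truth set as a labelled BED
#'
#' @param truth a \code{\link{TruthSet}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTruthBed <- function(truth, path) {
    one <- function(gr, lab) {
        if (!length(gr)) return(character())
        paste(as.character(GenomicRanges::seqnames(gr)),
              GenomicRanges::start(gr) - 1, GenomicRanges::end(gr), lab,
              sep = "\t")
    }
    writeLines(c(one(truth@tp, "TP"), one(truth@fp, "FP"),
                 one(truth@ambiguous, "ambiguous")), path)
    invisible(path)
}
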