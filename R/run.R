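#' @include AllClasses.R peaks-io.R normalize.R consensus-bed.R consensus-wig.R
NULL

#' Configuration for a consensus run
#'
#' Validates a full run configuration up front, before any file is touched.
#' Invalid mode/method combinations are configuration errors: WIG mode has
#' no selection step (no voting on steps) and allows only the two
#' distribution-free normalizations; the voting selection rule does not use
#' scores, so combining it with a normalization method triggers a warning
#' and the normalization is skipped.
#'
#' @param inputs named character vector: \code{c(callerName = path, ...)}.
#' @param mode \code{"bed"} or \code{"wig"}.
#' @param select selection method for BED mode: \code{"voting"},
#'   \code{"minfp"} or \code{"minfn"}.
#' @param normalize normalization method or \code{"none"} (voting default).
#' @param minRank minimum number of supporting callers.
#' @param quantile quantile for naive-quantile normalization.
#' @param normalShift target mean for normal normalization.
#' @param cutoff optional WIG score cut-off (\code{NULL} = none).
#' @param chrom optional chromosome filter (\code{NULL} = all).
#' @param outDir output directory.
#' @param keepIndividual also write each caller's (normalized) peak list?
#' @param outputFormat for WIG mode: \code{"wig"} or \code{"bed"}.
#' @return a validated list of class \code{"ConsensusConfig"}.
#' @export
consensusConfig <- function(inputs, mode = c("bed", "wig"),
                            select = c("voting", "minfp", "minfn"),
                            normalize = NULL, minRank = 2L, quantile = 0.75,
                            normalShift = 3, cutoff = NULL, chrom = NULL,
                            outDir = ".", keepIndividual = FALSE,
                            outputFormat = c("wig", "bed")) {
    mode <- match.arg(mode)
    select <- match.arg(select)
    outputFormat <- match.arg(outputFormat)
    if (!length(inputs))
        stop("configuration error: at least one input is required",
             call. = FALSE)
    if (is.null(names(inputs)) || any(!nzchar(names(inputs))))
        stop("configuration error: every input needs a caller name ",
             "(names(inputs))", call. = FALSE)
    if (anyDuplicated(names(inputs)))
        stop("configuration error: caller names must be distinct",
             call. = FALSE)
    if (mode == "wig") {
        if (is.null(normalize)) normalize <- "average"
        if (!normalize %in% c(.wigNormMethods, "none"))
            stop("configuration error: normalization '", normalize,
                 "' is not available in WIG mode (use average or ",
                 "naive_quantile)", call. = FALSE)
    } else {
        if (select == "voting") {
            if (!is.null(normalize) && normalize != "none")
                warning("voting does not use scores; normalization '",
                        normalize, "' is skipped", call. = FALSE)
            normalize <- "none"
        } else if (is.null(normalize)) {
            normalize <- "rank"
        } else if (!normalize %in% .normMethods) {
            stop("configuration error: unknown normalization '", normalize,
                 "'", call. = FALSE)
        }
    }
    if (minRank < 1 || minRank != floor(minRank))
        stop("configuration error: minRank must be an integer >= 1",
             call. = FALSE)
    if (quantile <= 0 || quantile > 1)
        stop("configuration error: quantile must be in (0, 1]",
             call. = FALSE)
    if (!is.null(cutoff) && cutoff < 0)
        stop("configuration error: cutoff must be >= 0", call. = FALSE)
    structure(list(inputs = inputs, mode = mode, select = select,
                   normalize = normalize, minRank = as.integer(minRank),
                   quantile = quantile, normalShift = normalShift,
                   cutoff = cutoff, chrom = chrom, outDir = outDir,
                   keepIndividual = keepIndividual,
                   outputFormat = outputFormat),
              class = "ConsensusConfig")
}

.filterChrom <- function(x, chrom) {
    gr <- x@peaks
    keep <- as.character(GenomicRanges::seqnames(gr)) %in% chrom
    new("CallerPeaks", caller = x@caller, peaks = gr[keep])
}

#' Consensus peaks from in-memory caller lists (BED mode)
#'
#' The BED-mode engine behind \code{\link{runConsensus}}: normalizes each
#' caller's scores onto the common scale (unless voting), segments the
#' genome at peak boundaries, and applies the selection rule. Chromosomes
#' are processed independently and results concatenated, which is
#' equivalent to one whole-genome pass because segments never span
#' chromosomes.
#'
#' @param callerLists list of \code{\link{CallerPeaks}}.
#' @param select \code{"voting"}, \code{"minfp"} or \code{"minfn"}.
#' @param normalize normalization method, or \code{"none"}.
#' @param minRank minimum number of supporting callers.
#' @param quantile,normalShift normalization parameters.
#' @return list with elements \code{regions} (consensus \code{GRanges}),
#'   \code{segments} (\code{\link{ConsensusSegments}}) and
#'   \code{normalized} (the caller lists actually aggregated).
#' @export
bedConsensus <- function(callerLists, select = c("voting", "minfp", "minfn"),
                         normalize = "none", minRank = 2L, quantile = 0.75,
                         normalShift = 3) {
    select <- match.arg(select)
    if (normalize != "none") {
        m <- maxNoOfPeaks(callerLists)
        callerLists <- lapply(callerLists, normalizePeaks,
                              method = normalize, maxNoOfPeaks = m,
                              normalShift = normalShift, quantile = quantile)
    }
    segs <- segmentPeaks(callerLists)
    list(regions = selectConsensus(segs, select, minRank),
         segments = segs, normalized = callerLists)
}

#' Run the full consensus pipeline from files
#'
#' Reads the per-caller inputs named in the configuration, processes each
#' chromosome independently, concatenates the results and writes them to
#' the output directory: \code{consensus.bed} for BED mode,
#' \code{consensus.wig} (and \code{consensus.bed} when
#' \code{outputFormat = "bed"}) for WIG mode. With
#' \code{keepIndividual = TRUE}, each caller's (normalized) peak list is
#' stored alongside as \code{<caller>.normalized.bed}.
#'
#' @param config a \code{\link{consensusConfig}} object.
#' @return invisibly, a list with the consensus result (\code{regions}
#'   \code{GRanges} or list of \code{\link{WigTrack}}), the per-stage
#'   counts, and the paths written.
#' @export
runConsensus <- function(config) {
    stopifnot(inherits(config, "ConsensusConfig"))
    missing <- config$inputs[!file.exists(config$inputs)]
    if (length(missing))
        stop("input file(s) not found: ",
             paste(missing, collapse = ", "), call. = FALSE)
    if (!dir.exists(config$outDir))
        dir.create(config$outDir, recursive = TRUE)
    paths <- character()
    counts <- list(inputPeaks = integer())
    if (config$mode == "bed") {
        lists <- mapply(readPeakBed, config$inputs, names(config$inputs),
                        SIMPLIFY = FALSE)
        if (!is.null(config$chrom)) {
            have <- unique(unlist(lapply(lists, function(x)
                as.character(GenomicRanges::seqnames(x@peaks)))))
            if (!all(config$chrom %in% have))
                warning("chromosome(s) ",
                        paste(setdiff(config$chrom, have), collapse = ", "),
                        " absent from the inputs; output for them is empty",
                        call. = FALSE)
            lists <- lapply(lists, .filterChrom, chrom = config$chrom)
        }
        counts$inputPeaks <- vapply(lists, nPeaks, integer(1))
        chroms <- sort(unique(unlist(lapply(lists, function(x)
            as.character(GenomicRanges::seqnames(x@peaks))))))
        perChrom <- lapply(chroms, function(ch) {
            bedConsensus(lapply(lists, .filterChrom, chrom = ch),
                         select = config$select,
                         normalize = config$normalize,
                         minRank = config$minRank,
                         quantile = config$quantile,
                         normalShift = config$normalShift)
        })
        regions <- if (length(perChrom))
            GenomicRanges::sort(do.call(c, lapply(perChrom, `[[`,
                                                  "regions")))
        else GenomicRanges::GRanges(votes = integer(), score = numeric())
        counts$segments <- sum(vapply(perChrom, function(p)
            length(p$segments), integer(1)))
        counts$consensusRegions <- length(regions)
        out <- file.path(config$outDir, "consensus.bed")
        writeConsensusBed(regions, out)
        paths <- out
        if (config$keepIndividual) {
            norm <- if (config$normalize == "none") lists else {
                m <- maxNoOfPeaks(lists)
                lapply(lists, normalizePeaks, method = config$normalize,
                       maxNoOfPeaks = m, normalShift = config$normalShift,
                       quantile = config$quantile)
            }
            for (x in norm) {
                p <- file.path(config$outDir,
                               paste0(caller(x), ".normalized.bed"))
                writeCallerBed(x, p)
                paths <- c(paths, p)
            }
        }
        result <- list(regions = regions, counts = counts, paths = paths)
    } else {
        tracks <- unlist(lapply(config$inputs, readWig), use.names = FALSE)
        if (!is.null(config$chrom)) {
            have <- unique(vapply(tracks, wigChrom, character(1)))
            if (!all(config$chrom %in% have))
                warning("chromosome(s) ",
                        paste(setdiff(config$chrom, have), collapse = ", "),
                        " absent from the inputs; output for them is empty",
                        call. = FALSE)
            tracks <- Filter(function(t) wigChrom(t) %in% config$chrom,
                             tracks)
        }
        if (!length(tracks))
            stop("no WIG tracks to merge after filtering", call. = FALSE)
        counts$inputSteps <- vapply(tracks, length, integer(1))
        merged <- wigConsensus(tracks, normalization = config$normalize,
                               quantile = config$quantile,
                               cutoff = config$cutoff)
        counts$mergedSteps <- sum(vapply(merged, length, integer(1)))
        out <- file.path(config$outDir, "consensus.wig")
        writeWig(merged, out)
        paths <- out
        if (config$outputFormat == "bed") {
            regions <- GenomicRanges::sort(
                do.call(c, lapply(merged, wigToRegions)))
            outBed <- file.path(config$outDir, "consensus.bed")
            writeConsensusBed(regions, outBed)
            paths <- c(paths, outBed)
        }
        result <- list(tracks = merged, counts = counts, paths = paths)
    }
    invisible(result)
}
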