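#' @include AllClasses.R
NULL

#' @export
setGeneric("caller", function(x) standardGeneric("caller"))

#' @export
setGeneric("nPeaks", function(x) standardGeneric("nPeaks"))

#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @export
setGeneric("scores<-", function(x, value) standardGeneric("scores<-"))

#' @export
setGeneric("span", function(x) standardGeneric("span"))

#' @export
setGeneric("stepStarts", function(x) standardGeneric("stepStarts"))

#' @export
setGeneric("votes", function(x) standardGeneric("votes"))

#' @export
setGeneric("aggScore", function(x) standardGeneric("aggScore"))

#' @export
setGeneric("callerSets", function(x) standardGeneric("callerSets"))

#' @export
setGeneric("tpIntervals", function(x) standardGeneric("tpIntervals"))

#' @export
setGeneric("fpIntervals", function(x) standardGeneric("fpIntervals"))

#' @export
setGeneric("ambiguousIntervals", function(x) standardGeneric("ambiguousIntervals"))
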