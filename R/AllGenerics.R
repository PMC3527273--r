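#' @include AllGenerics.R
NULL

#' @rdname cellTable
#' @export
setGeneric("cellTable", function(x) standardGeneric("cellTable"))

#' @rdname cellTable
#' @export
setGeneric("sampleTable", function(x) standardGeneric("sampleTable"))

#' @rdname cellTable
#' @export
setGeneric("founderId", function(x) standardGeneric("founderId"))

#' @rdname cellTable
#' @export
setGeneric("inductionTime", function(x) standardGeneric("inductionTime"))

#' @rdname cellTable
#' @export
setGeneric("inductionTime<-", function(x, value) standardGeneric("inductionTime<-"))

#' @rdname cellTable
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname cellTable
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname cellTable
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname cellTable
#' @export
setGeneric("fluorChannels", function(x) standardGeneric("fluorChannels"))

#' @rdname afPoints
#' @export
setGeneric("afPoints", function(x) standardGeneric("afPoints"))

#' @rdname afPoints
#' @export
setGeneric("afHalflife", function(x) standardGeneric("afHalflife"))
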