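#' @rdname accessors
#' @export
setGeneric("timesPs", function(x) standardGeneric("timesPs"))

#' @rdname accessors
#' @export
setGeneric("valuesNm", function(x) standardGeneric("valuesNm"))

#' @rdname accessors
#' @export
setGeneric("seriesLabel", function(x) standardGeneric("seriesLabel"))

#' @rdname accessors
#' @export
setGeneric("meanNm", function(x) standardGeneric("meanNm"))

#' @rdname accessors
#' @export
setGeneric("seNm", function(x) standardGeneric("seNm"))

#' @rdname accessors
#' @export
setGeneric("sdNm", function(x) standardGeneric("sdNm"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("callLabel", function(x) standardGeneric("callLabel"))

#' @rdname accessors
#' @export
setGeneric("onsetPs", function(x) standardGeneric("onsetPs"))

#' @rdname accessors
#' @export
setGeneric("deltaNm", function(x) standardGeneric("deltaNm"))

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname accessors
#' @export
setGeneric("refId", function(x) standardGeneric("refId"))

#' @rdname accessors
#' @export
setGeneric("refId<-", function(x, value) standardGeneric("refId<-"))

#' @rdname accessors
#' @export
setGeneric("conservedFraction", function(x) standardGeneric("conservedFraction"))

#' @rdname accessors
#' @export
setGeneric("mutationTable", function(x) standardGeneric("mutationTable"))
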