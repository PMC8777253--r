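#' @rdname accessors
#' @export
setGeneric("traceMatrix", function(x) standardGeneric("traceMatrix"))

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname accessors
#' @export
setGeneric("backgroundRoi", function(x) standardGeneric("backgroundRoi"))

#' @rdname accessors
#' @export
setGeneric("cellRois", function(x) standardGeneric("cellRois"))

#' @rdname accessors
#' @export
setGeneric("stimulusEventsOf", function(x) standardGeneric("stimulusEventsOf"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("dffMatrix", function(x) standardGeneric("dffMatrix"))

#' @rdname accessors
#' @export
setGeneric("f0Window", function(x) standardGeneric("f0Window"))

#' @rdname accessors
#' @export
setGeneric("f0Values", function(x) standardGeneric("f0Values"))

#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' @rdname accessors
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))

#' @rdname accessors
#' @export
setGeneric("recordingSpan", function(x) standardGeneric("recordingSpan"))

#' @rdname accessors
#' @export
setGeneric("stimulusOnset", function(x) standardGeneric("stimulusOnset"))

#' @rdname accessors
#' @export
setGeneric("binTimes", function(x) standardGeneric("binTimes"))

#' @rdname accessors
#' @export
setGeneric("binRate", function(x) standardGeneric("binRate"))

#' @rdname accessors
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname accessors
#' @export
setGeneric("traceStage", function(x) standardGeneric("traceStage"))

#' @rdname accessors
#' @export
setGeneric("traceLabels", function(x) standardGeneric("traceLabels"))
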