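#' @name coptgak-generics
#' @title Accessor generics
#' @description Accessors for the core S4 containers.
#' @param x object.
#' @param ... further arguments.
NULL

#' @rdname coptgak-generics
#' @export
setGeneric("seqValues", function(x) standardGeneric("seqValues"))

#' @rdname coptgak-generics
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname coptgak-generics
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname coptgak-generics
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))

#' @rdname coptgak-generics
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname coptgak-generics
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname coptgak-generics
#' @export
setGeneric("seqRole", function(x) standardGeneric("seqRole"))

#' @rdname coptgak-generics
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' @rdname coptgak-generics
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname coptgak-generics
#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))

#' @rdname coptgak-generics
#' @export
setGeneric("psdPower", function(x) standardGeneric("psdPower"))

#' @rdname coptgak-generics
#' @export
setGeneric("psdFrequencies", function(x) standardGeneric("psdFrequencies"))

#' @rdname coptgak-generics
#' @export
setGeneric("sigmaOpt", function(x) standardGeneric("sigmaOpt"))

#' @rdname coptgak-generics
#' @export
setGeneric("acceptanceRange", function(x) standardGeneric("acceptanceRange"))

#' @rdname coptgak-generics
#' @export
setGeneric("sweepCurve", function(x) standardGeneric("sweepCurve"))

#' @rdname coptgak-generics
#' @export
setGeneric("checkpoints", function(x) standardGeneric("checkpoints"))

#' @rdname coptgak-generics
#' @export
setGeneric("stopStep", function(x) standardGeneric("stopStep"))

#' @rdname coptgak-generics
#' @export
setGeneric("bestStep", function(x) standardGeneric("bestStep"))

#' @rdname coptgak-generics
#' @export
setGeneric("stopReason", function(x) standardGeneric("stopReason"))
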