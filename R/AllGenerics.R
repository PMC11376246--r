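#' @rdname MovieStack-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname MovieStack-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname MovieStack-class
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname MovieStack-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname FlowField-class
#' @export
setGeneric("speeds", function(x) standardGeneric("speeds"))

#' @rdname FlowField-class
#' @export
setGeneric("displacements", function(x) standardGeneric("displacements"))

#' @rdname TrackSet-class
#' @export
setGeneric("tracks", function(x) standardGeneric("tracks"))

#' @rdname TrackSet-class
#' @export
setGeneric("nTracks", function(x) standardGeneric("nTracks"))
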