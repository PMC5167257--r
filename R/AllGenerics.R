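#' Accessors for KymoTrack classes
#'
#' Small accessor generics so user code never reaches into slots directly.
#'
#' @param x a KymoTrack object.
#' @param i track identifier (for \code{trackNodes}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("frameData", function(x) standardGeneric("frameData"))

#' @rdname accessors
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname accessors
#' @export
setGeneric("kymoValues", function(x) standardGeneric("kymoValues"))

#' @rdname accessors
#' @export
setGeneric("frameIndices", function(x) standardGeneric("frameIndices"))

#' @rdname accessors
#' @export
setGeneric("sampleCoords", function(x) standardGeneric("sampleCoords"))

#' @rdname accessors
#' @export
setGeneric("loiVertices", function(x) standardGeneric("loiVertices"))

#' @rdname accessors
#' @export
setGeneric("loiWidth", function(x) standardGeneric("loiWidth"))

#' @rdname accessors
#' @export
setGeneric("trackNodes", function(x, i) standardGeneric("trackNodes"))

#' @rdname accessors
#' @export
setGeneric("trackIds", function(x) standardGeneric("trackIds"))

#' @rdname accessors
#' @export
setGeneric("nTracks", function(x) standardGeneric("nTracks"))

#' @rdname accessors
#' @export
setGeneric("branchEvents", function(x) standardGeneric("branchEvents"))

#' @rdname accessors
#' @export
setGeneric("runParams", function(x) standardGeneric("runParams"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("sceneStack", function(x) standardGeneric("sceneStack"))

#' @rdname accessors
#' @export
setMethod("nFrames", "KymoStack", function(x) length(x@frames))

#' @rdname accessors
#' @export
setMethod("frameData", "KymoStack", function(x) x@frames)

#' @rdname accessors
#' @export
setMethod("bitDepth", "KymoStack", function(x) x@bitDepth)

#' @rdname accessors
#' @export
setMethod("bitDepth", "Kymograph", function(x) x@bitDepth)

#' @rdname accessors
#' @export
setMethod("pixelSize", "KymoStack", function(x) x@pxSize)

#' @rdname accessors
#' @export
setMethod("pixelSize", "Kymograph", function(x) x@pxSize)

#' @rdname accessors
#' @export
setMethod("frameInterval", "KymoStack", function(x) x@dt)

#' @rdname accessors
#' @export
setMethod("frameInterval", "Kymograph", function(x) x@dt)

#' @rdname accessors
#' @export
setMethod("kymoValues", "Kymograph", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("frameIndices", "Kymograph", function(x) x@frameIndices)

#' @rdname accessors
#' @export
setMethod("sampleCoords", "Kymograph", function(x) x@sampleCoords)

#' @rdname accessors
#' @export
setMethod("loiVertices", "LineOfInterest", function(x) x@vertices)

#' @rdname accessors
#' @export
setMethod("loiWidth", "LineOfInterest", function(x) x@width)

#' @rdname accessors
#' @export
setMethod("trackNodes", "TrackSet", function(x, i) {
  if (missing(i)) return(x@nodes)
  x@nodes[x@nodes$track == i, , drop = FALSE]
})

#' @rdname accessors
#' @export
setMethod("trackIds", "TrackSet", function(x) sort(unique(x@nodes$track)))

#' @rdname accessors
#' @export
setMethod("nTracks", "TrackSet", function(x) length(unique(x@nodes$track)))

#' @rdname accessors
#' @export
setMethod("branchEvents", "TrackSet", function(x) x@branches)

#' @rdname accessors
#' @export
setMethod("runParams", "TrackSet", function(x) x@params)

#' @rdname accessors
#' @export
setMethod("groundTruth", "SyntheticScene", function(x) x@truth)

#' @rdname accessors
#' @export
setMethod("sceneStack", "SyntheticScene", function(x) x@stack)
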