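#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers. Slots are never
#' reached into directly by user code.
#'
#' @param x An object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname accessors
#' @export
setGeneric("nPhases", function(x) standardGeneric("nPhases"))

#' @rdname accessors
#' @export
setGeneric("expIndex", function(x) standardGeneric("expIndex"))

#' @rdname accessors
#' @export
setGeneric("inspIndex", function(x) standardGeneric("inspIndex"))

#' @rdname accessors
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))

#' @rdname accessors
#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("parenchymaMask", function(x) standardGeneric("parenchymaMask"))

#' @rdname accessors
#' @export
setGeneric("vesselMask", function(x) standardGeneric("vesselMask"))

#' @rdname accessors
#' @export
setGeneric("analysisMask", function(x) standardGeneric("analysisMask"))

#' @rdname accessors
#' @export
setGeneric("navigator", function(x) standardGeneric("navigator"))
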