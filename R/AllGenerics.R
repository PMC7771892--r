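#' @import methods
NULL

#' Generics for fpmsda classes
#'
#' Accessor and computation generics shared across the package's S4
#' classes. See the class pages for method-specific details.
#'
#' @param object,x an fpmsda S4 object
#' @param ... further arguments passed to methods
#' @name fpmsda-generics
NULL

#' @rdname fpmsda-generics
#' @export
setGeneric("amplitude", function(object, ...) standardGeneric("amplitude"))

#' @rdname fpmsda-generics
#' @export
setGeneric("phase", function(object, ...) standardGeneric("phase"))

#' @rdname fpmsda-generics
#' @export
setGeneric("pixelSize", function(object, ...) standardGeneric("pixelSize"))

#' @rdname fpmsda-generics
#' @export
setGeneric("objectMetadata", function(object, ...) standardGeneric("objectMetadata"))

#' @rdname fpmsda-generics
#' @export
setGeneric("illuminationNA", function(object, ...) standardGeneric("illuminationNA"))

#' @rdname fpmsda-generics
#' @export
setGeneric("waveVectors", function(object, ...) standardGeneric("waveVectors"))

#' @rdname fpmsda-generics
#' @export
setGeneric("frameLabels", function(object, ...) standardGeneric("frameLabels"))

#' @rdname fpmsda-generics
#' @export
setGeneric("frames", function(object, ...) standardGeneric("frames"))

#' @rdname fpmsda-generics
#' @export
setGeneric("nFrames", function(object, ...) standardGeneric("nFrames"))

#' @rdname fpmsda-generics
#' @export
setGeneric("stackRole", function(object, ...) standardGeneric("stackRole"))

#' @rdname fpmsda-generics
#' @export
setGeneric("ledIndex", function(object, ...) standardGeneric("ledIndex"))

#' @rdname fpmsda-generics
#' @export
setGeneric("backgroundMask", function(object, ...) standardGeneric("backgroundMask"))

#' @rdname fpmsda-generics
#' @export
setGeneric("objectMap", function(object, ...) standardGeneric("objectMap"))

#' @rdname fpmsda-generics
#' @export
setGeneric("amplificationMap", function(object, ...) standardGeneric("amplificationMap"))

#' @rdname fpmsda-generics
#' @export
setGeneric("sbr", function(object, ...) standardGeneric("sbr"))

#' @rdname fpmsda-generics
#' @export
setGeneric("reconField", function(object, ...) standardGeneric("reconField"))

#' @rdname fpmsda-generics
#' @export
setGeneric("syntheticNA", function(object, ...) standardGeneric("syntheticNA"))
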