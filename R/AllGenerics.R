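#' Accessor generics
#'
#' Small accessor generics used across the package's S4 classes.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("clipDuration", function(x) standardGeneric("clipDuration"))

#' Root-mean-square amplitude
#'
#' @param x an [AudioClip-class] or numeric vector.
#' @return scalar RMS (linear amplitude).
#' @export
setGeneric("rms", function(x) standardGeneric("rms"))

#' @rdname accessors
#' @export
setGeneric("templateName", function(x) standardGeneric("templateName"))

#' @rdname accessors
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @rdname accessors
#' @export
setGeneric("period", function(x) standardGeneric("period"))

#' @rdname accessors
#' @export
setGeneric("peakWidth", function(x) standardGeneric("peakWidth"))

#' @rdname accessors
#' @export
setGeneric("isMatch", function(x) standardGeneric("isMatch"))

#' @rdname accessors
#' @export
setGeneric("failureStage", function(x) standardGeneric("failureStage"))

#' @rdname accessors
#' @export
setGeneric("templateNames", function(x) standardGeneric("templateNames"))
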