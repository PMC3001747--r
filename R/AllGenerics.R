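#' @rdname AnnotatedAlignment-class
#' @param x,object an object.
#' @export
setGeneric("alignmentId", function(x) standardGeneric("alignmentId"))

#' @rdname AnnotatedAlignment-class
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname AnnotatedAlignment-class
#' @export
setGeneric("nSeqs", function(x) standardGeneric("nSeqs"))

#' @rdname AnnotatedAlignment-class
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' @rdname AnnotatedAlignment-class
#' @export
setGeneric("residueMatrix", function(x) standardGeneric("residueMatrix"))

#' @rdname AnnotatedAlignment-class
#' @export
setGeneric("ssMatrix", function(x) standardGeneric("ssMatrix"))

#' @rdname AnnotatedAlignment-class
#' @export
setGeneric("rsaMatrix", function(x) standardGeneric("rsaMatrix"))

#' @rdname AnnotatedAlignment-class
#' @export
setGeneric("groupCodes", function(x) standardGeneric("groupCodes"))

#' @rdname AnnotatedAlignment-class
#' @export
setGeneric("strata", function(x) standardGeneric("strata"))

#' @rdname AnnotatedAlignment-class
#' @export
setGeneric("siteIndex", function(x) standardGeneric("siteIndex"))

#' @rdname AnnotatedAlignment-class
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname SPMatrix-class
#' @param x an object.
#' @export
setGeneric("spCounts", function(x) standardGeneric("spCounts"))

#' @rdname SPMatrix-class
#' @export
setGeneric("spKind", function(x) standardGeneric("spKind"))

#' @rdname PropertyScale-class
#' @param x an object.
#' @export
setGeneric("scaleValues", function(x) standardGeneric("scaleValues"))

#' @rdname PropertyScale-class
#' @export
setGeneric("scaleName", function(x) standardGeneric("scaleName"))
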