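#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small family of accessor generics used across the package's S4 classes.
#' Accessors are preferred over direct slot access.
#'
#' @param object an evomorph S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fluorChannel", function(object) standardGeneric("fluorChannel"))

#' @rdname accessors
#' @export
setGeneric("maskChannel", function(object) standardGeneric("maskChannel"))

#' @rdname accessors
#' @export
setGeneric("pixelArea", function(object) standardGeneric("pixelArea"))

#' @rdname accessors
#' @export
setGeneric("eventLabel", function(object) standardGeneric("eventLabel"))

#' @rdname accessors
#' @export
setGeneric("inFocus", function(object) standardGeneric("inFocus"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("events", function(object) standardGeneric("events"))

#' @rdname accessors
#' @export
setGeneric("lineage", function(object) standardGeneric("lineage"))

#' @rdname accessors
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))

#' @rdname accessors
#' @export
setGeneric("records", function(object) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("curveTimes", function(object) standardGeneric("curveTimes"))

#' @rdname accessors
#' @export
setGeneric("densities", function(object) standardGeneric("densities"))

#' @rdname accessors
#' @export
setGeneric("carbonSource", function(object) standardGeneric("carbonSource"))

#' @rdname accessors
#' @export
setGeneric("carbonConc", function(object) standardGeneric("carbonConc"))
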