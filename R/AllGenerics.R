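#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: trial tables and
#' schedule metadata, image data with its affine and repetition time, and
#' the components of first-level, group and reliability maps.
#'
#' @param x An object of one of the package's S4 classes.
#' @return The slot value named by the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))
#' @rdname accessors
#' @export
setGeneric("scheduleVariant", function(x) standardGeneric("scheduleVariant"))
#' @rdname accessors
#' @export
setGeneric("scheduleOrder", function(x) standardGeneric("scheduleOrder"))
#' @rdname accessors
#' @export
setGeneric("runDuration", function(x) standardGeneric("runDuration"))
#' @rdname accessors
#' @export
setGeneric("boldData", function(x) standardGeneric("boldData"))
#' @rdname accessors
#' @export
setGeneric("voxelAffine", function(x) standardGeneric("voxelAffine"))
#' @rdname accessors
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))
#' @rdname accessors
#' @export
setGeneric("conditionNames", function(x) standardGeneric("conditionNames"))
#' @rdname accessors
#' @export
setGeneric("effectMap", function(x, condition) standardGeneric("effectMap"))
#' @rdname accessors
#' @export
setGeneric("varianceMap", function(x, condition) standardGeneric("varianceMap"))
#' @rdname accessors
#' @export
setGeneric("zMap", function(x, ...) standardGeneric("zMap"))
#' @rdname accessors
#' @export
setGeneric("iccValues", function(x) standardGeneric("iccValues"))
#' @rdname accessors
#' @export
setGeneric("sigMask", function(x) standardGeneric("sigMask"))
#' @rdname accessors
#' @export
setGeneric("maskedIcc", function(x) standardGeneric("maskedIcc"))
#' @rdname accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))
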