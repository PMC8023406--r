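#' @title Generics for flowCulture classes
#' @name flowCulture-generics
#' @description Accessor and analysis generics. Most have a single method;
#'   see the class pages for slot semantics.
#' @keywords internal
NULL

#' @rdname flowCulture-generics
#' @param object,x an object.
#' @export
setGeneric("eventMatrix", function(object) standardGeneric("eventMatrix"))

#' @rdname flowCulture-generics
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname flowCulture-generics
#' @export
setGeneric("nEvents", function(object) standardGeneric("nEvents"))

#' @rdname flowCulture-generics
#' @export
setGeneric("acquiredVolume", function(object) standardGeneric("acquiredVolume"))

#' @rdname flowCulture-generics
#' @export
setGeneric("dilutionFactor", function(object) standardGeneric("dilutionFactor"))

#' @rdname flowCulture-generics
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname flowCulture-generics
#' @export
setGeneric("sampleTimestamp", function(object) standardGeneric("sampleTimestamp"))

#' @rdname flowCulture-generics
#' @export
setGeneric("isTransformed", function(object) standardGeneric("isTransformed"))

#' @rdname flowCulture-generics
#' @export
setGeneric("elapsedHours", function(object) standardGeneric("elapsedHours"))

#' @rdname flowCulture-generics
#' @export
setGeneric("gateCounts", function(object) standardGeneric("gateCounts"))

#' @rdname flowCulture-generics
#' @export
setGeneric("gateConcentrations", function(object) standardGeneric("gateConcentrations"))

#' @rdname flowCulture-generics
#' @export
setGeneric("fingerprintValues", function(object) standardGeneric("fingerprintValues"))

#' @rdname flowCulture-generics
#' @export
setGeneric("d2Mean", function(object) standardGeneric("d2Mean"))

#' @rdname flowCulture-generics
#' @export
setGeneric("d2Sd", function(object) standardGeneric("d2Sd"))
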