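## Generics for accessors shared across classes.

#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @export
setGeneric("gainValues", function(object) standardGeneric("gainValues"))

#' @export
setGeneric("tempValues", function(object) standardGeneric("tempValues"))

#' @export
setGeneric("epoch", function(object) standardGeneric("epoch"))

#' @export
setGeneric("frameDim", function(object) standardGeneric("frameDim"))

#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @export
setGeneric("artifacts", function(object) standardGeneric("artifacts"))

#' @export
setGeneric("matchedPairs", function(object) standardGeneric("matchedPairs"))

#' @export
setGeneric("mapPoints", function(transform, pts) standardGeneric("mapPoints"))
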