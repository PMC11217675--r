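#' @name ucnescan-generics
#' @title Accessor generics
#' @description Accessors for the S4 result classes. Slot access by users is
#'   discouraged; use these instead.
#' @param object an S4 object from this package.
#' @keywords internal
NULL

#' @rdname ucnescan-generics
#' @export
setGeneric("spacingCounts", function(object) standardGeneric("spacingCounts"))

#' @rdname ucnescan-generics
#' @export
setGeneric("spacingFrequencies", function(object) standardGeneric("spacingFrequencies"))

#' @rdname ucnescan-generics
#' @export
setGeneric("spacingSigma", function(object) standardGeneric("spacingSigma"))

#' @rdname ucnescan-generics
#' @export
setGeneric("spacingBand", function(object) standardGeneric("spacingBand"))

#' @rdname ucnescan-generics
#' @export
setGeneric("motifs", function(object) standardGeneric("motifs"))

#' @rdname ucnescan-generics
#' @export
setGeneric("transitionProbs", function(object) standardGeneric("transitionProbs"))

#' @rdname ucnescan-generics
#' @export
setGeneric("stationaryProbs", function(object) standardGeneric("stationaryProbs"))

#' @rdname ucnescan-generics
#' @export
setGeneric("positives", function(object) standardGeneric("positives"))

#' @rdname ucnescan-generics
#' @export
setGeneric("negatives", function(object) standardGeneric("negatives"))

#' @rdname ucnescan-generics
#' @export
setGeneric("metrics", function(object) standardGeneric("metrics"))

#' @rdname ucnescan-generics
#' @export
setGeneric("confusion", function(object) standardGeneric("confusion"))

#' @rdname ucnescan-generics
#' @export
setGeneric("rocPoints", function(object) standardGeneric("rocPoints"))

#' @rdname ucnescan-generics
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))

#' @rdname ucnescan-generics
#' @export
setGeneric("predictions", function(object) standardGeneric("predictions"))

#' @rdname ucnescan-generics
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname ucnescan-generics
#' @export
setGeneric("nullMeans", function(object) standardGeneric("nullMeans"))

#' @rdname ucnescan-generics
#' @export
setGeneric("maskedFraction", function(object) standardGeneric("maskedFraction"))
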