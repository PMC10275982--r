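#' Channel names of an event table
#' @param x an [EventTable-class].
#' @return character vector of channel names in column order.
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' Intensity matrix of an event table
#' @param x an [EventTable-class].
#' @return numeric matrix, events in rows, channels in columns.
#' @export
setGeneric("exprs", function(x) standardGeneric("exprs"))

#' Sample identifier
#' @param x an [EventTable-class].
#' @return single character.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' Number of events
#' @param x an [EventTable-class] or [GateResult-class].
#' @return integer event count.
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' Fraction of events called transfected by a gate
#' @param x a [GateResult-class].
#' @return numeric in [0, 1].
#' @export
setGeneric("gatedFraction", function(x) standardGeneric("gatedFraction"))

#' Logical transfected-cell flags of a gate result
#' @param x a [GateResult-class].
#' @return logical vector, one element per event.
#' @export
setGeneric("gateFlags", function(x) standardGeneric("gateFlags"))
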