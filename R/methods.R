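#' Construct an EventTable
#'
#' @param sampleId sample identifier.
#' @param exprs numeric matrix (events x channels) or data.frame of finite
#'   intensities with unique column names.
#' @return an [EventTable-class].
#' @examples
#' et <- eventTable("s1", cbind(EGFP = c(10, 20), mKATE = c(5, 6)))
#' channels(et)
#' @export
eventTable <- function(sampleId, exprs) {
  if (is.data.frame(exprs)) exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  new("EventTable", sampleId = as.character(sampleId), exprs = exprs)
}

#' @rdname channels
#' @export
setMethod("channels", "EventTable", function(x) colnames(x@exprs))

#' @rdname exprs
#' @export
setMethod("exprs", "EventTable", function(x) x@exprs)

#' @rdname sampleId
#' @export
setMethod("sampleId", "EventTable", function(x) x@sampleId)

#' @rdname nEvents
#' @export
setMethod("nEvents", "EventTable", function(x) nrow(x@exprs))

#' @rdname nEvents
#' @export
setMethod("nEvents", "GateResult", function(x) length(x@flag))

#' @rdname gatedFraction
#' @export
setMethod("gatedFraction", "GateResult", function(x) mean(x@flag))

#' @rdname gateFlags
#' @export
setMethod("gateFlags", "GateResult", function(x) x@flag)

setMethod("show", "EventTable", function(object) {
  cat(sprintf("EventTable '%s': %d events x %d channels (%s)\n",
              object@sampleId, nrow(object@exprs), ncol(object@exprs),
              paste(colnames(object@exprs), collapse = ", ")))
})

setMethod("show", "ControlModel", function(object) {
  cat(sprintf("ControlModel fitted on %d events (q = %.4g, k = %g)\n",
              object@nEvents, object@quantile, object@scaleDivisor))
  print(data.frame(channel = names(object@location),
                   location = unname(object@location),
                   scale = unname(object@scale), row.names = NULL))
})

setMethod("show", "GateResult", function(object) {
  cat(sprintf(
    "GateResult: %d events, %d gated (%.1f%%) at threshold %.2f on %s\n",
    length(object@flag), sum(object@flag), 100 * mean(object@flag),
    object@threshold, paste(colnames(object@membership), collapse = " OR ")))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    paste0("SimConfig: %d events/sample, f_transfected = %.2f, rho = %.2f\n",
           "  transcription pool %g (kappa %g)%s; translation pool %g",
           " (kappa %g)\n  measurement noise sd %.2f (log scale)\n"),
    object@nEvents, object@fTransfected, object@uptakeCorrelation,
    object@poolT, object@kappaT,
    if (object@mrnaMode) " [bypassed: mRNA mode]" else "",
    object@poolL, object@kappaL, object@noiseSd))
})
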