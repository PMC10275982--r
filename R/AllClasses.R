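#' @import methods
NULL

#' Per-cell fluorescence events for one acquired sample
#'
#' An \code{EventTable} holds the raw per-event fluorescence intensities of a
#' single flow-cytometry acquisition on the linear (instrument-arbitrary RFU)
#' scale: one row per recorded event, one column per named channel. No
#' transformation, compensation or background subtraction is applied; means
#' downstream are arithmetic means of these values.
#'
#' @slot sampleId single character, the sample identifier.
#' @slot exprs numeric matrix of intensities, events in rows, channels in
#'   named columns. All values must be finite.
#'
#' @seealso [readEventsFCS()], [readEventsCSV()], [gateTransfected()]
#' @export
setClass("EventTable",
  representation(sampleId = "character", exprs = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@sampleId) != 1L || is.na(object@sampleId))
      msg <- c(msg, "sampleId must be a single non-NA string")
    if (!is.numeric(object@exprs))
      msg <- c(msg, "exprs must be a numeric matrix")
    if (nrow(object@exprs) < 1L)
      msg <- c(msg, "event table must contain at least one event")
    if (is.null(colnames(object@exprs)) ||
        anyDuplicated(colnames(object@exprs)))
      msg <- c(msg, "channels must be uniquely named")
    if (is.numeric(object@exprs) && !all(is.finite(object@exprs)))
      msg <- c(msg, "all intensities must be finite")
    if (length(msg)) msg else TRUE
  }
)

#' Fuzzy gate reference fitted on a negative (untransfected) control
#'
#' Per channel, the model stores a location (a high quantile of the
#' negative-control intensity) and a positive scale (the spread of the
#' control's upper tail). Event membership in the transfected population is a
#' logistic function of distance from the location in units of the scale; see
#' [membership()].
#'
#' @slot location named numeric, per-channel location in RFU.
#' @slot scale named numeric, per-channel scale in RFU, strictly positive.
#' @slot quantile the control quantile used for the location.
#' @slot scaleDivisor divisor k applied to the (location - median) spread.
#' @slot nEvents number of control events the model was fitted on.
#'
#' @seealso [fitControl()]
#' @export
setClass("ControlModel",
  representation(location = "numeric", scale = "numeric",
                 quantile = "numeric", scaleDivisor = "numeric",
                 nEvents = "integer"),
  validity = function(object) {
    msg <- character()
    if (!identical(names(object@location), names(object@scale)))
      msg <- c(msg, "location and scale must cover the same channels")
    if (any(object@scale <= 0))
      msg <- c(msg, "scale must be strictly positive for every channel")
    if (length(msg)) msg else TRUE
  }
)

#' Result of fuzzy OR gating of an event table
#'
#' @slot membership numeric matrix in [0,1]: per-event, per-channel fuzzy
#'   membership in the transfected population.
#' @slot combined numeric vector, the fuzzy OR (rowwise maximum) of the
#'   channel memberships.
#' @slot flag logical vector, \code{combined >= threshold}.
#' @slot threshold the decision threshold applied to the combined membership.
#'
#' @seealso [gateTransfected()], [gatedFraction()]
#' @export
setClass("GateResult",
  representation(membership = "matrix", combined = "numeric",
                 flag = "logical", threshold = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@membership)
    if (length(object@combined) != n || length(object@flag) != n)
      msg <- c(msg, "membership, combined and flag must agree in length")
    if (any(object@membership < 0 | object@membership > 1))
      msg <- c(msg, "memberships must lie in [0, 1]")
    if (!isTRUE(all.equal(object@combined,
                          apply(object@membership, 1L, max),
                          check.attributes = FALSE)))
      msg <- c(msg, "combined membership must be the rowwise maximum")
    if (!identical(object@flag, unname(object@combined >= object@threshold)))
      msg <- c(msg, "flag must equal combined >= threshold")
    if (length(msg)) msg else TRUE
  }
)

#' Configuration of the shared-resource co-transfection simulator
#'
#' Parameters of the generative model behind [simulateSample()] and
#' [simulateLibrary()]. Cells take up co-delivered plasmids with correlated
#' log-normal copy numbers; transcription of all cassettes draws on one
#' saturating resource pool (size \code{poolT}, half-saturation
#' \code{kappaT}), translation on a second, weakly limiting pool
#' (\code{poolL}, \code{kappaL}). Channel readouts add log-normal
#' autofluorescence and multiplicative measurement noise.
#'
#' @slot nEvents events per simulated sample.
#' @slot fTransfected fraction of events that received plasmids, in [0,1].
#' @slot uptakeLogMean,uptakeLogSd log-scale mean and sd of per-plasmid
#'   copy number.
#' @slot uptakeCorrelation correlation rho in [0,1] of log copy numbers
#'   between co-delivered plasmids.
#' @slot poolT,kappaT transcriptional resource pool and saturation constant.
#' @slot poolL,kappaL translational resource pool and saturation constant.
#' @slot hillBasal,hillEC50,hillH doxycycline dose response of the TET
#'   promoter: strength multiplier basal + (1-basal) d^h / (d^h + EC50^h).
#' @slot autofluorLogMean,autofluorLogSd named per-channel log-normal
#'   autofluorescence parameters.
#' @slot noiseSd log-scale sd of multiplicative measurement noise.
#' @slot mrnaMode if TRUE, cassette loads are delivered mRNA amounts and the
#'   transcriptional pool is bypassed (mRNA co-transfection mode).
#'
#' @seealso [simConfig()], [expectedOutputs()]
#' @export
setClass("SimConfig",
  representation(nEvents = "integer", fTransfected = "numeric",
                 uptakeLogMean = "numeric", uptakeLogSd = "numeric",
                 uptakeCorrelation = "numeric",
                 poolT = "numeric", kappaT = "numeric",
                 poolL = "numeric", kappaL = "numeric",
                 hillBasal = "numeric", hillEC50 = "numeric",
                 hillH = "numeric",
                 autofluorLogMean = "numeric", autofluorLogSd = "numeric",
                 noiseSd = "numeric", mrnaMode = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@nEvents < 1L) msg <- c(msg, "nEvents must be >= 1")
    if (object@fTransfected < 0 || object@fTransfected > 1)
      msg <- c(msg, "fTransfected must lie in [0, 1]")
    if (object@uptakeCorrelation < 0 || object@uptakeCorrelation > 1)
      msg <- c(msg, "uptakeCorrelation must lie in [0, 1]")
    pos <- c(poolT = object@poolT, kappaT = object@kappaT,
             poolL = object@poolL, kappaL = object@kappaL)
    if (any(pos <= 0))
      msg <- c(msg, paste("resource pools and saturation constants must be",
                          "strictly positive"))
    if (object@noiseSd < 0 || object@uptakeLogSd < 0)
      msg <- c(msg, "noise and uptake sd must be non-negative")
    if (object@hillBasal < 0 || object@hillBasal > 1 ||
        object@hillEC50 <= 0 || object@hillH <= 0)
      msg <- c(msg, "invalid dox Hill parameters")
    if (!identical(names(object@autofluorLogMean),
                   names(object@autofluorLogSd)))
      msg <- c(msg, "autofluorescence parameters must name the same channels")
    if (any(object@autofluorLogSd < 0))
      msg <- c(msg, "autofluorescence log-sd must be non-negative")
    if (length(msg)) msg else TRUE
  }
)
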