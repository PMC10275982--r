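#' Fit a fuzzy-gate reference on a negative (untransfected) control
#'
#' Per channel, the location is a high quantile (default the 99.9th
#' percentile) of the negative control's intensity, and the scale is the
#' spread of the control's upper tail, \code{(location - median) /
#' scaleDivisor}. Degenerate controls (zero spread) have the scale floored
#' at \code{sqrt(.Machine$double.eps) * max(1, location)}, which makes the
#' membership function effectively crisp at the location.
#'
#' @param control an [EventTable-class] of negative-control events (>= 100).
#' @param channels channels to model; default all channels of the control.
#' @param quantile control quantile defining the location.
#' @param scaleDivisor divisor applied to the upper-tail spread.
#' @return a [ControlModel-class].
#' @export
fitControl <- function(control, channels = NULL, quantile = 0.999,
                       scaleDivisor = 6) {
  stopifnot(is(control, "EventTable"))
  if (is.null(channels)) channels <- channels(control)
  missing <- setdiff(channels, channels(control))
  if (length(missing))
    stop(sprintf("control lacks channel(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (nEvents(control) < 100L)
    stop(sprintf("control has %d events; at least 100 are required to fit",
                 nEvents(control)), call. = FALSE)
  x <- exprs(control)[, channels, drop = FALSE]
  loc <- apply(x, 2L, stats::quantile, probs = quantile, type = 7,
               names = FALSE)
  med <- apply(x, 2L, stats::median)
  sc <- (loc - med) / scaleDivisor
  floorAt <- sqrt(.Machine$double.eps) * pmax(1, abs(loc))
  sc <- pmax(sc, floorAt)
  new("ControlModel", location = stats::setNames(loc, channels),
      scale = stats::setNames(sc, channels), quantile = quantile,
      scaleDivisor = scaleDivisor, nEvents = nEvents(control))
}

#' Fuzzy membership of an intensity in the transfected population
#'
#' Logistic membership \code{1 / (1 + exp(-(x - location) / scale))}:
#' monotone non-decreasing in the intensity, 0.5 exactly at the control
#' location, approaching 0 far below it and 1 far above it.
#'
#' @param x numeric intensities (RFU).
#' @param model a [ControlModel-class].
#' @param channel channel name; must be covered by the model.
#' @return numeric memberships in [0, 1].
#' @export
membership <- function(x, model, channel) {
  stopifnot(is(model, "ControlModel"))
  if (!channel %in% names(model@location))
    stop(sprintf("control model has no channel '%s'", channel),
         call. = FALSE)
  stats::plogis(x, location = model@location[[channel]],
                scale = model@scale[[channel]])
}

#' Select transfected cells by fuzzy OR gating
#'
#' Combines the per-channel logistic memberships with a fuzzy OR (the
#' rowwise maximum) and flags events whose combined membership reaches the
#' threshold. A cell is called transfected when it is bright in \emph{any}
#' of the gated channels; with co-delivered plasmids entering cells
#' together, this recovers the co-transfected population.
#'
#' @param events an [EventTable-class].
#' @param model a [ControlModel-class] fitted on the same channels.
#' @param channels channels entering the OR; default all model channels.
#' @param threshold decision threshold on the combined membership.
#' @return a [GateResult-class].
#' @export
gateTransfected <- function(events, model, channels = NULL,
                            threshold = 0.5) {
  stopifnot(is(events, "EventTable"), is(model, "ControlModel"))
  if (is.null(channels)) channels <- names(model@location)
  if (length(channels) == 0L)
    stop("at least one channel is required for gating", call. = FALSE)
  missing <- setdiff(channels, channels(events))
  if (length(missing))
    stop(sprintf("event table lacks gated channel(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  memb <- vapply(channels, function(ch)
    membership(exprs(events)[, ch], model, ch),
    numeric(nEvents(events)))
  if (nEvents(events) == 1L)
    memb <- matrix(memb, nrow = 1L, dimnames = list(NULL, channels))
  combined <- apply(memb, 1L, max)
  new("GateResult", membership = memb, combined = unname(combined),
      flag = unname(combined >= threshold), threshold = threshold)
}

#' Export a gate result as a tidy data.frame
#'
#' @param gate a [GateResult-class].
#' @return data.frame with the event index, per-channel memberships, the
#'   combined membership and the transfected flag.
#' @export
gateAsTable <- function(gate) {
  stopifnot(is(gate, "GateResult"))
  df <- data.frame(event = seq_len(nEvents(gate)))
  for (ch in colnames(gate@membership))
    df[[paste0("membership_", ch)]] <- gate@membership[, ch]
  df$combined <- gate@combined
  df$transfected <- gate@flag
  df
}
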