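#' Normalise western-blot EBNA1 densitometry within one blot
#'
#' Lane-specific loading normalisation followed by inter-blot scaling: each
#' lane's Vinculin (loading control) signal is divided by the strongest
#' Vinculin signal on the blot to give a per-lane factor; the factor
#' multiplies the lane's EBNA1 signal; and the normalised values are divided
#' by their mean over the non-control lanes. The negative-control lane
#' participates in the Vinculin maximum but is excluded from that mean, so
#' the non-control final values average to exactly 1 within every blot.
#'
#' @param lanes data.frame with columns \code{lane_id}, \code{ebna1}
#'   (densitometry units, >= 0), \code{vinculin} (> 0 for non-control
#'   lanes) and logical \code{is_negative_control}.
#' @return the input with added columns \code{factor}, \code{normalized}
#'   and \code{final}.
#' @examples
#' normalizeEbna1(data.frame(lane_id = c("a", "b"),
#'   ebna1 = c(200, 200), vinculin = c(100, 50),
#'   is_negative_control = FALSE))$final  # 4/3, 2/3
#' @export
normalizeEbna1 <- function(lanes) {
  need <- c("lane_id", "ebna1", "vinculin", "is_negative_control")
  missing <- setdiff(need, names(lanes))
  if (length(missing))
    stop(sprintf("lane table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (all(lanes$is_negative_control))
    stop("at least one non-control lane is required", call. = FALSE)
  if (any(lanes$ebna1 < 0))
    stop("EBNA1 signals must be non-negative", call. = FALSE)
  if (any(lanes$vinculin[!lanes$is_negative_control] <= 0))
    stop("Vinculin signal must be positive for non-control lanes",
         call. = FALSE)
  vmax <- max(lanes$vinculin)
  if (vmax <= 0)
    stop("maximum Vinculin signal must be positive", call. = FALSE)
  lanes$factor <- lanes$vinculin / vmax
  lanes$normalized <- lanes$factor * lanes$ebna1
  lanes$final <- lanes$normalized /
    mean(lanes$normalized[!lanes$is_negative_control])
  lanes
}
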