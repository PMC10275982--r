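#' Summarise the gated population of one sample
#'
#' Arithmetic mean and population standard deviation (divisor n) of each
#' channel over gated events, on the linear RFU scale with no background
#' subtraction. If the gate retains no events the summary is returned with
#' NA statistics and \code{excluded = TRUE}, with a warning, so downstream
#' stages can drop the sample explicitly.
#'
#' @param events an [EventTable-class].
#' @param gate the [GateResult-class] computed on the same table.
#' @param channels channels to summarise; default all channels.
#' @return data.frame with one row per channel: \code{sample_id},
#'   \code{channel}, \code{mean_rfu}, \code{sd_rfu}, \code{n_events},
#'   \code{n_gated}, \code{excluded}.
#' @export
summarizeSample <- function(events, gate, channels = NULL) {
  stopifnot(is(events, "EventTable"), is(gate, "GateResult"))
  if (nEvents(events) != nEvents(gate))
    stop("gate result does not match the event table", call. = FALSE)
  if (is.null(channels)) channels <- channels(events)
  keep <- gateFlags(gate)
  n <- nEvents(events)
  if (!any(keep)) {
    warning(sprintf("sample '%s': no events pass the gate; excluded",
                    sampleId(events)), call. = FALSE)
    return(data.frame(sample_id = sampleId(events), channel = channels,
                      mean_rfu = NA_real_, sd_rfu = NA_real_,
                      n_events = n, n_gated = 0L, excluded = TRUE))
  }
  x <- exprs(events)[keep, channels, drop = FALSE]
  mu <- colMeans(x)
  sdPop <- sqrt(colMeans(sweep(x, 2L, mu)^2))  # population sd, divisor n
  data.frame(sample_id = sampleId(events), channel = channels,
             mean_rfu = unname(mu), sd_rfu = unname(sdPop),
             n_events = n, n_gated = sum(keep), excluded = FALSE)
}

#' Tukey-fence outlier exclusion for replicate values
#'
#' Quartiles are computed by linear interpolation of the order statistics;
#' values strictly below \code{Q1 - 1.5 IQR} or strictly above
#' \code{Q3 + 1.5 IQR} are removed. The filter is applied exactly once (no
#' re-iteration on the kept values). Fewer than three values are returned
#' unfiltered with a warning.
#'
#' @param x numeric replicate values (typically one gated mean per
#'   biological repeat).
#' @return list with \code{kept} and \code{removed}; a disjoint partition
#'   of the input.
#' @examples
#' tukeyFilter(c(1, 2, 3, 4, 100))$removed
#' @export
tukeyFilter <- function(x) {
  stopifnot(is.numeric(x), !anyNA(x))
  if (length(x) < 3L) {
    warning("fewer than 3 values; returned unfiltered", call. = FALSE)
    return(list(kept = x, removed = numeric()))
  }
  qs <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- qs[2] - qs[1]
  lower <- qs[1] - 1.5 * iqr
  upper <- qs[2] + 1.5 * iqr
  out <- x < lower | x > upper
  list(kept = x[!out], removed = x[out])
}

#' Remaining capacity as a percentage of the empty-vector control
#'
#' The capacity left to the cell by a test construct is the mean of its
#' replicate monitor means expressed as a percentage of the mean of the
#' empty-control replicate monitor means (the no-competition baseline). The
#' error bar combines the two replicate-level relative errors (sample sd of
#' the replicate means, divisor n-1) in quadrature:
#' \code{error = capacity * sqrt((sd_t/mean_t)^2 + (sd_e/mean_e)^2)}.
#'
#' @param testMeans replicate monitor means of the test condition (RFU),
#'   already outlier-filtered with [tukeyFilter()].
#' @param emptyMeans replicate monitor means of the empty-vector control.
#' @return list with \code{capacity} (percent), \code{error} (plus/minus
#'   percentage points; NA when either side has a single replicate),
#'   \code{nTest}, \code{nEmpty}.
#' @examples
#' capacityPercent(c(480, 480), c(1000, 1000))$capacity  # 48
#' @export
capacityPercent <- function(testMeans, emptyMeans) {
  stopifnot(is.numeric(testMeans), is.numeric(emptyMeans),
            length(testMeans) >= 1L, length(emptyMeans) >= 1L,
            !anyNA(testMeans), !anyNA(emptyMeans))
  me <- mean(emptyMeans)
  if (me <= 0)
    stop("empty-control monitor mean must be positive", call. = FALSE)
  mt <- mean(testMeans)
  capacity <- 100 * mt / me
  err <- NA_real_
  if (length(testMeans) > 1L && length(emptyMeans) > 1L && mt > 0)
    err <- capacity * sqrt((stats::sd(testMeans) / mt)^2 +
                           (stats::sd(emptyMeans) / me)^2)
  list(capacity = capacity, error = err,
       nTest = length(testMeans), nEmpty = length(emptyMeans))
}

#' Induction fold change
#'
#' Ratio of the induced to the uninduced test-reporter mean.
#'
#' @param inducedMean,uninducedMean gated test-reporter means (RFU).
#' @return the dimensionless ratio.
#' @export
foldChange <- function(inducedMean, uninducedMean) {
  stopifnot(is.numeric(inducedMean), is.numeric(uninducedMean))
  if (uninducedMean <= 0)
    stop("uninduced mean must be positive for a fold change", call. = FALSE)
  inducedMean / uninducedMean
}

# Null distribution of U by full enumeration of rank subsets (tie-free).
exactUCdf <- function(n, m, uObs) {
  subsets <- utils::combn(n + m, n)
  u <- colSums(matrix(seq_len(n + m)[subsets], nrow = n)) -
    n * (n + 1) / 2
  mean(u <= uObs)
}

#' Exact two-sided Mann-Whitney U test
#'
#' U statistics are computed with mid-rank assignment. The two-sided p-value
#' is exact — doubled lower-tail probability of the smaller U under full
#' enumeration of all \code{choose(n+m, n)} group assignments — whenever
#' \code{n + m <= 16} and the pooled values are tie-free; otherwise the
#' normal approximation with tie correction and a 0.5 continuity correction
#' is used. p is clipped to (0, 1].
#'
#' @param x,y numeric samples, each non-empty.
#' @return list with \code{U1}, \code{U2} (U of \code{x} and of \code{y};
#'   always \code{U1 + U2 = length(x) * length(y)}), \code{p} and
#'   \code{method} ("exact" or "normal-approximation").
#' @examples
#' mannWhitneyTwoSided(c(1, 2, 3), c(4, 5, 6))$p  # 0.1
#' @export
mannWhitneyTwoSided <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L)
    stop("both samples must be non-empty", call. = FALSE)
  stopifnot(is.numeric(x), is.numeric(y), !anyNA(x), !anyNA(y))
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))  # mid-ranks
  u1 <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  u2 <- n * m - u1
  hasTies <- anyDuplicated(c(x, y)) > 0L
  if (N <= 16L && !hasTies) {
    p <- min(1, 2 * exactUCdf(n, m, min(u1, u2)))
    method <- "exact"
  } else {
    ties <- table(c(x, y))
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(0, abs(u1 - n * m / 2) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "normal-approximation"
  }
  list(U1 = u1, U2 = u2, p = max(p, .Machine$double.xmin), method = method)
}

#' Significance stars for a p-value
#'
#' The conventional four-level annotation: **** below 1e-4, *** below 5e-4,
#' ** below 5e-3, * below 0.05, "ns" otherwise.
#'
#' @param p numeric p-values in [0, 1].
#' @return character vector of annotations.
#' @export
significanceStars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.005] <- "**"
  out[p < 0.0005] <- "***"
  out[p < 0.0001] <- "****"
  out[is.na(p)] <- NA_character_
  out
}
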