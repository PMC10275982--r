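designLabel <- function(df)
  paste(df$promoter, df$kozak, df$polyA, sep = "|")

#' Enumerate single-factor construct pairs
#'
#' For the chosen design element (promoter, Kozak or polyA), forms every
#' unordered pair of constructs that share the other two elements (and cell
#' line, if present). Each pair is oriented so that the test-reporter
#' difference is non-negative, \code{delta_egfp = EGFP(high) - EGFP(low) >=
#' 0}; exact EGFP ties are oriented by the lexicographic order of the design
#' labels, making the enumeration deterministic. Incomplete grids are fine:
#' pairs involving a missing combination are simply absent.
#'
#' @param summaries data.frame with one row per design: columns
#'   \code{promoter}, \code{kozak}, \code{polyA}, optionally
#'   \code{cell_line}, and the replicate-averaged gated means \code{egfp}
#'   and \code{mkate} (RFU).
#' @param element one of "promoter", "kozak", "polyA".
#' @return data.frame of pairs: \code{element}, \code{design_low},
#'   \code{design_high}, the shared context columns, \code{delta_egfp}
#'   (>= 0) and the signed \code{delta_mkate}.
#' @export
enumerateSingleFactorPairs <- function(summaries,
                                       element = c("promoter", "kozak",
                                                   "polyA")) {
  element <- match.arg(element)
  need <- c("promoter", "kozak", "polyA", "egfp", "mkate")
  missing <- setdiff(need, names(summaries))
  if (length(missing))
    stop(sprintf("summaries lack column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  keyCols <- c("promoter", "kozak", "polyA",
               intersect("cell_line", names(summaries)))
  key <- do.call(paste, c(summaries[keyCols], sep = "|"))
  if (anyDuplicated(key))
    stop("duplicate design keys; average replicates before pairing",
         call. = FALSE)
  context <- setdiff(keyCols, element)
  ctx <- do.call(paste, c(summaries[context], sep = "|"))
  out <- list()
  for (g in unique(ctx)) {
    grp <- summaries[ctx == g, , drop = FALSE]
    L <- nrow(grp)
    if (L < 2L) next
    for (i in seq_len(L - 1L)) for (j in seq(i + 1L, L)) {
      a <- grp[i, ]; b <- grp[j, ]
      swap <- if (a$egfp != b$egfp) a$egfp > b$egfp else
        designLabel(a) > designLabel(b)
      if (swap) { tmp <- a; a <- b; b <- tmp }
      row <- data.frame(element = element,
                        design_low = designLabel(a),
                        design_high = designLabel(b),
                        delta_egfp = b$egfp - a$egfp,
                        delta_mkate = b$mkate - a$mkate)
      for (cc in context) row[[cc]] <- a[[cc]]
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out))
    return(data.frame(element = character(), design_low = character(),
                      design_high = character(), delta_egfp = numeric(),
                      delta_mkate = numeric()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Quartile attribution of monitor change to a design element
#'
#' Groups an element's single-factor pairs into quartiles of their
#' test-reporter difference and reports the mean signed monitor difference
#' per quartile: how much capacity a given gain in output costs when
#' achieved through that element. Quartile boundaries are computed on the
#' element's own delta distribution by linear interpolation; intervals are
#' right-closed, so a pair sitting exactly on a boundary falls in the lower
#' quartile. Fewer than four pairs collapse to a single bin with a warning.
#'
#' @param pairs data.frame from [enumerateSingleFactorPairs()]; may contain
#'   several elements, which are binned separately.
#' @return data.frame with \code{element}, \code{quartile} (1-4, or NA for
#'   the single-bin fallback), \code{mean_delta_mkate} and \code{n_pairs}.
#' @export
quartileAttribution <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("element", "delta_egfp", "delta_mkate") %in% names(pairs)))
  out <- list()
  for (el in unique(pairs$element)) {
    p <- pairs[pairs$element == el, ]
    if (nrow(p) < 4L) {
      warning(sprintf(
        "element '%s' has %d pair(s); single-bin fallback", el, nrow(p)),
        call. = FALSE)
      out[[el]] <- data.frame(element = el, quartile = NA_integer_,
                              mean_delta_mkate = mean(p$delta_mkate),
                              n_pairs = nrow(p))
      next
    }
    qs <- stats::quantile(p$delta_egfp, c(0.25, 0.5, 0.75), type = 7,
                          names = FALSE)
    quart <- 1L + (p$delta_egfp > qs[1]) + (p$delta_egfp > qs[2]) +
      (p$delta_egfp > qs[3])
    out[[el]] <- data.frame(
      element = el, quartile = 1:4,
      mean_delta_mkate = vapply(1:4, function(k)
        mean(p$delta_mkate[quart == k]), numeric(1)),
      n_pairs = vapply(1:4, function(k) sum(quart == k), integer(1)))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Pareto front of the construct library landscape
#'
#' The designs for which no other design is at least as good in both the
#' test-reporter output and the remaining monitor expression and strictly
#' better in one: the set formalising the region where co-expression of
#' both cassettes can be optimised. Duplicated identical points are all
#' retained (non-strict dominance does not eliminate exact ties).
#'
#' @param summaries data.frame with one row per design and numeric columns
#'   \code{egfp} and \code{mkate}.
#' @return the subset of rows forming the front, in the input row order.
#' @export
paretoFront <- function(summaries) {
  stopifnot(is.data.frame(summaries),
            all(c("egfp", "mkate") %in% names(summaries)))
  n <- nrow(summaries)
  if (n == 0L) return(summaries)
  ord <- order(-summaries$egfp, -summaries$mkate)
  e <- summaries$egfp[ord]; m <- summaries$mkate[ord]
  keep <- logical(n)
  bestM <- -Inf
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && e[j + 1L] == e[i]) j <- j + 1L
    groupMax <- m[i]  # sorted descending within equal egfp
    if (groupMax > bestM) {
      keep[i:j][m[i:j] == groupMax] <- TRUE
      bestM <- groupMax
    }
    i <- j + 1L
  }
  summaries[sort(ord[keep]), , drop = FALSE]
}

#' Library landscape scatter plot
#'
#' Test-reporter output against monitor expression, one point per design,
#' with the Pareto front highlighted.
#'
#' @param summaries design summaries with \code{egfp} and \code{mkate}.
#' @param front optional precomputed [paretoFront()] subset.
#' @return a ggplot object.
#' @export
plotLibraryLandscape <- function(summaries, front = paretoFront(summaries)) {
  ggplot2::ggplot(summaries, ggplot2::aes(x = egfp, y = mkate)) +
    ggplot2::geom_point(colour = "grey40") +
    ggplot2::geom_point(data = front, colour = "firebrick", size = 2.5) +
    ggplot2::labs(x = "EGFP mean RFU", y = "mKATE mean RFU (monitor)") +
    ggplot2::theme_bw()
}

#' Quartile attribution bar plot
#'
#' @param bars data.frame from [quartileAttribution()].
#' @return a ggplot object.
#' @export
plotQuartileBars <- function(bars) {
  bars$quartile <- factor(bars$quartile, levels = 1:4)
  ggplot2::ggplot(bars, ggplot2::aes(x = quartile,
                                     y = mean_delta_mkate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~element) +
    ggplot2::labs(x = expression(Delta * "EGFP quartile"),
                  y = expression("mean " * Delta * "mKATE (RFU)")) +
    ggplot2::theme_bw()
}
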