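# Minimal FCS 3.0/3.1 list-mode reader. Supports float (F), double (D) and
# uniform-width integer (I) data segments, both byte orders, and $PnE log
# amplification; spillover/compensation keywords are ignored by design.

fcsReadText <- function(raw, beg, end) {
  delim <- rawToChar(raw[beg])
  txt <- rawToChar(raw[(beg + 1L):end])
  # split on the delimiter; FCS escapes a literal delimiter by doubling it,
  # which is rare in practice and unsupported here
  parts <- strsplit(txt, delim, fixed = TRUE)[[1]]
  if (length(parts) < 2L)
    stop("invalid FCS file: empty TEXT segment", call. = FALSE)
  if (length(parts) %% 2L == 1L)
    parts <- c(parts, "")
  keys <- toupper(trimws(parts[seq(1L, length(parts), by = 2L)]))
  vals <- trimws(parts[seq(2L, length(parts), by = 2L)])
  stats::setNames(as.list(vals), keys)
}

fcsKeyword <- function(kw, key, required = TRUE) {
  v <- kw[[toupper(key)]]
  if (is.null(v) || !nzchar(v)) {
    if (required)
      stop(sprintf("invalid FCS file: missing required keyword %s", key),
           call. = FALSE)
    return(NULL)
  }
  v
}

#' Read a flow-cytometry FCS file into an EventTable
#'
#' Parses an FCS 3.0 or 3.1 list-mode file and returns the stored per-event
#' channel intensities in acquisition order, on the linear scale. Channels
#' acquired with log amplification (a non-zero \code{$PnE} keyword) are
#' linearized as \code{10^(f1 * x / $PnR) * f2} per the FCS standard; no
#' other transformation, and no compensation, is applied.
#'
#' @param path path to the FCS file.
#' @param channelMap named character vector mapping logical roles to
#'   instrument channel names, as built by [channelMap()]. Every mapped
#'   channel must be present in the file.
#' @param sampleIdName sample identifier for the returned table; defaults to
#'   the file name without extension.
#' @return an [EventTable-class] with all channels stored in the file.
#' @examples
#' \dontrun{
#' cm <- channelMap(test_reporter = "BL1-A", monitor = "YL2-A")
#' et <- readEventsFCS("sample.fcs", cm)
#' }
#' @export
readEventsFCS <- function(path, channelMap,
                          sampleIdName = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path))
    stop(sprintf("FCS file not found: %s", path), call. = FALSE)
  raw <- readBin(path, what = "raw", n = file.size(path))
  if (length(raw) < 58L)
    stop("invalid FCS file: shorter than the 58-byte header", call. = FALSE)
  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop(sprintf("unsupported FCS version '%s' (FCS 3.0/3.1 only)", version),
         call. = FALSE)
  off <- function(i, j) {
    v <- suppressWarnings(as.integer(trimws(rawToChar(raw[i:j]))))
    if (is.na(v)) stop("invalid FCS file: malformed header offsets",
                       call. = FALSE)
    v
  }
  textBeg <- off(11L, 18L); textEnd <- off(19L, 26L)
  dataBeg <- off(27L, 34L); dataEnd <- off(35L, 42L)
  if (textBeg <= 0L || textEnd <= textBeg || textEnd > length(raw))
    stop("invalid FCS file: TEXT segment offsets out of range", call. = FALSE)
  kw <- fcsReadText(raw, textBeg + 1L, textEnd + 1L)

  if (toupper(fcsKeyword(kw, "$MODE")) != "L")
    stop("unsupported FCS file: only list mode ($MODE L) is supported",
         call. = FALSE)
  dtype <- toupper(fcsKeyword(kw, "$DATATYPE"))
  byteord <- fcsKeyword(kw, "$BYTEORD")
  endian <- switch(byteord,
    "1,2,3,4" = "little", "1,2" = "little",
    "4,3,2,1" = "big", "2,1" = "big",
    stop(sprintf("unsupported FCS byte order '%s'", byteord), call. = FALSE))
  nPar <- as.integer(fcsKeyword(kw, "$PAR"))
  nTot <- as.integer(fcsKeyword(kw, "$TOT"))
  if (is.na(nPar) || is.na(nTot) || nPar < 1L || nTot < 1L)
    stop("invalid FCS file: bad $PAR or $TOT", call. = FALSE)

  if (dataBeg == 0L) {  # FCS 3.1 style: offsets only in TEXT
    dataBeg <- as.integer(fcsKeyword(kw, "$BEGINDATA"))
    dataEnd <- as.integer(fcsKeyword(kw, "$ENDDATA"))
  }
  if (is.na(dataBeg) || is.na(dataEnd) || dataBeg <= 0L ||
      dataEnd < dataBeg || dataEnd > length(raw))
    stop("invalid FCS file: DATA segment offsets out of range", call. = FALSE)
  dataRaw <- raw[(dataBeg + 1L):(dataEnd + 1L)]

  chan <- vapply(seq_len(nPar), function(i)
    fcsKeyword(kw, sprintf("$P%dN", i)), character(1))
  bits <- vapply(seq_len(nPar), function(i)
    as.integer(fcsKeyword(kw, sprintf("$P%dB", i))), integer(1))

  n <- nPar * nTot
  values <- switch(dtype,
    F = {
      if (any(bits != 32L))
        stop("invalid FCS file: $DATATYPE F requires 32-bit parameters",
             call. = FALSE)
      readBin(dataRaw, "double", n = n, size = 4L, endian = endian)
    },
    D = readBin(dataRaw, "double", n = n, size = 8L, endian = endian),
    I = {
      b <- unique(bits)
      if (length(b) != 1L || !b %in% c(8L, 16L, 32L))
        stop(paste("unsupported FCS file: integer data requires a uniform",
                   "parameter width of 8, 16 or 32 bits"), call. = FALSE)
      readBin(dataRaw, "integer", n = n, size = b %/% 8L,
              signed = b == 32L, endian = endian)
    },
    stop(sprintf("unsupported FCS $DATATYPE '%s'", dtype), call. = FALSE))
  if (length(values) < n)
    stop("invalid FCS file: truncated DATA segment", call. = FALSE)
  mat <- matrix(as.double(values), nrow = nTot, ncol = nPar, byrow = TRUE,
                dimnames = list(NULL, chan))

  # linearize log-amplified parameters
  for (i in seq_len(nPar)) {
    pe <- fcsKeyword(kw, sprintf("$P%dE", i), required = FALSE)
    if (is.null(pe)) next
    f <- suppressWarnings(as.numeric(strsplit(pe, ",", fixed = TRUE)[[1]]))
    if (length(f) == 2L && !anyNA(f) && f[1] > 0) {
      r <- as.numeric(fcsKeyword(kw, sprintf("$P%dR", i)))
      mat[, i] <- 10^(f[1] * mat[, i] / r) * max(f[2], 1)
    }
  }

  assertMappedChannels(channelMap, chan, path)
  eventTable(sampleIdName, mat)
}

assertMappedChannels <- function(channelMap, present, where) {
  missing <- setdiff(unname(channelMap), present)
  if (length(missing))
    stop(sprintf(
      "channel map names channel(s) %s absent from %s (present: %s)",
      paste(sQuote(missing), collapse = ", "), where,
      paste(sQuote(present), collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
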