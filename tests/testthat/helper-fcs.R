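# Programmatic FCS 3.0 writer for fixtures: list mode, float (F), double
# (D) or 16-bit integer (I) data, either byte order, optional $PnE log
# amplification keywords. Only what the reader tests need.
writeFixtureFCS <- function(path, mat, datatype = "D", endian = "little",
                            pne = NULL, pnr = NULL) {
  stopifnot(is.matrix(mat), !is.null(colnames(mat)))
  nPar <- ncol(mat); nTot <- nrow(mat)
  byteord <- if (endian == "little") "1,2,3,4" else "4,3,2,1"
  bits <- switch(datatype, F = 32L, D = 64L, I = 16L)
  if (is.null(pnr)) pnr <- rep(262144, nPar)
  if (is.null(pne)) pne <- rep("0,0", nPar)
  kw <- c("$MODE", "L", "$DATATYPE", datatype, "$BYTEORD", byteord,
          "$PAR", nPar, "$TOT", nTot, "$NEXTDATA", 0)
  for (i in seq_len(nPar))
    kw <- c(kw, sprintf("$P%dN", i), colnames(mat)[i],
            sprintf("$P%dB", i), bits,
            sprintf("$P%dE", i), pne[i],
            sprintf("$P%dR", i), format(pnr[i], scientific = FALSE))
  nBytes <- nPar * nTot * (bits %/% 8L)
  textStart <- 58L
  # data offsets are fixed-width, so the text length is stable across the
  # two passes used to resolve the self-reference
  mkText <- function(beg, end)
    paste0("/", paste(c(kw, "$BEGINDATA", sprintf("%010d", beg),
                        "$ENDDATA", sprintf("%010d", end)),
                      collapse = "/"), "/")
  textLen <- nchar(mkText(0L, 0L))
  dataStart <- textStart + textLen
  dataEnd <- dataStart + nBytes - 1L
  text <- mkText(dataStart, dataEnd)
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    textStart, textStart + textLen - 1L,
                    dataStart, dataEnd, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  values <- as.vector(t(mat))
  if (datatype == "I")
    writeBin(as.integer(values), con, size = 2L, endian = endian)
  else
    writeBin(as.double(values), con, size = bits %/% 8L, endian = endian)
  invisible(path)
}
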