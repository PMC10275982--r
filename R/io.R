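#' Map logical channel roles to instrument channel names
#'
#' The analysis refers to channels by role: the test construct's reporter
#' (EGFP), the capacity monitor (mKATE), an optional second reporter (EBFP)
#' and optional forward/side scatter. Instrument channel naming is
#' site-specific, so the mapping is always explicit and never guessed from
#' FCS labels.
#'
#' @param test_reporter,monitor instrument channel names (required).
#' @param second_reporter,scatter_fw,scatter_ss optional channel names.
#' @return named character vector of roles to channel names.
#' @examples
#' channelMap(test_reporter = "EGFP", monitor = "mKATE")
#' @export
channelMap <- function(test_reporter, monitor, second_reporter = NULL,
                       scatter_fw = NULL, scatter_ss = NULL) {
  if (missing(test_reporter) || missing(monitor))
    stop("channel map must assign both test_reporter and monitor",
         call. = FALSE)
  cm <- c(test_reporter = test_reporter, monitor = monitor,
          second_reporter = second_reporter,
          scatter_fw = scatter_fw, scatter_ss = scatter_ss)
  if (!is.character(cm) || anyNA(cm) || any(!nzchar(cm)))
    stop("channel names must be non-empty strings", call. = FALSE)
  cm
}

#' Read a CSV event table
#'
#' CSV fallback for event data (one row per event, header row of channel
#' names, dot-decimal numbers). Only the channels named in the map are
#' returned; extra columns are ignored. Events are never reordered or
#' dropped.
#'
#' @inheritParams readEventsFCS
#' @return an [EventTable-class] with the mapped channels.
#' @export
readEventsCSV <- function(path, channelMap,
                          sampleIdName = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path))
    stop(sprintf("event CSV not found: %s", path), call. = FALSE)
  if (file.size(path) == 0L)
    stop(sprintf("invalid event CSV %s: file is empty", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L)
    stop(sprintf("invalid event CSV %s: no event rows", path), call. = FALSE)
  assertMappedChannels(channelMap, names(df), path)
  wanted <- unique(unname(channelMap))
  mat <- vapply(wanted, function(ch) {
    v <- suppressWarnings(as.numeric(df[[ch]]))
    bad <- which(is.na(v) & !df[[ch]] %in% c("NA", ""))
    if (length(bad))
      stop(sprintf("invalid event CSV %s: non-numeric value '%s' in column %s, row %d",
                   path, df[[ch]][bad[1]], ch, bad[1]), call. = FALSE)
    if (anyNA(v))
      stop(sprintf("invalid event CSV %s: missing value in column %s, row %d",
                   path, ch, which(is.na(v))[1]), call. = FALSE)
    v
  }, numeric(nrow(df)))
  if (nrow(df) == 1L) mat <- matrix(mat, nrow = 1L,
                                    dimnames = list(NULL, wanted))
  eventTable(sampleIdName, mat)
}

# accepted spellings for sample roles, matched after trimming whitespace and
# lowercasing; the canonical names are the first of each row
roleSpellings <- list(
  test             = c("test", "sample"),
  empty_control    = c("empty_control", "empty", "pempty", "empty control"),
  negative_control = c("negative_control", "negative", "untransfected",
                       "negative control", "neg"),
  monitor_only     = c("monitor_only", "monitor", "monitor only")
)

normalizeRole <- function(role) {
  key <- tolower(trimws(role))
  out <- rep(NA_character_, length(key))
  for (canon in names(roleSpellings))
    out[key %in% roleSpellings[[canon]]] <- canon
  out
}

#' Read and validate a sample sheet
#'
#' The sample sheet annotates each event file with its construct design and
#' experimental condition. Required columns: \code{sample_id}, \code{file},
#' \code{cell_line}, \code{role}, \code{promoter}, \code{kozak},
#' \code{polyA}, \code{arrangement}, \code{dox}, \code{replicate}. Roles are
#' normalized case- and whitespace-insensitively (e.g. \code{"Test "},
#' \code{"pEmpty"}, \code{"untransfected"} are accepted).
#'
#' @param path path to the sample sheet CSV.
#' @return a data.frame of validated sample records.
#' @export
readSampleSheet <- function(path) {
  if (!file.exists(path))
    stop(sprintf("sample sheet not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  validateSampleSheet(df)
}

#' Validate a sample-sheet data.frame
#'
#' @param df data.frame with the sample-sheet columns (see
#'   [readSampleSheet()]).
#' @return the validated data.frame with normalized roles.
#' @export
validateSampleSheet <- function(df) {
  required <- c("sample_id", "file", "cell_line", "role", "promoter",
                "kozak", "polyA", "arrangement", "dox", "replicate")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("sample sheet lacks required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  problems <- character()
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    problems <- c(problems, sprintf("duplicate sample_id: %s",
                                    paste(dup, collapse = ", ")))
  role <- normalizeRole(df$role)
  if (anyNA(role))
    problems <- c(problems, sprintf(
      "unknown role in row(s) %s: %s",
      paste(which(is.na(role)), collapse = ", "),
      paste(unique(df$role[is.na(role)]), collapse = ", ")))
  dox <- suppressWarnings(as.numeric(df$dox))
  if (any(is.na(dox) | dox < 0))
    problems <- c(problems, sprintf("negative or non-numeric dox in row(s) %s",
      paste(which(is.na(dox) | dox < 0), collapse = ", ")))
  repl <- suppressWarnings(as.integer(df$replicate))
  if (any(is.na(repl) | repl < 1L))
    problems <- c(problems, sprintf("replicate must be an integer >= 1 (row(s) %s)",
      paste(which(is.na(repl) | repl < 1L), collapse = ", ")))
  arr <- c("single_TU", "two_TU", "IRES", "P2A", "T2A", "other")
  if (any(!df$arrangement %in% arr))
    problems <- c(problems, sprintf("unknown arrangement in row(s) %s",
      paste(which(!df$arrangement %in% arr), collapse = ", ")))
  if (length(problems))
    stop(paste0("invalid sample sheet:\n  ",
                paste(problems, collapse = "\n  ")), call. = FALSE)
  df$role <- role
  df$dox <- dox
  df$replicate <- repl
  df
}

#' Write pipeline result tables as tidy CSV files
#'
#' One CSV per table, with a stable column order. Real values round-trip to
#' at least 12 significant digits, integers bit-exactly.
#'
#' @param tables named list of data.frames.
#' @param outDir output directory, created if necessary.
#' @return invisibly, the named character vector of paths written.
#' @export
writeTidyResults <- function(tables, outDir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables),
            all(nzchar(names(tables))))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir))
    stop(sprintf("cannot create output directory %s", outDir), call. = FALSE)
  paths <- vapply(names(tables), function(nm) {
    df <- tables[[nm]]
    if (!is.data.frame(df))
      stop(sprintf("table '%s' is not a data.frame", nm), call. = FALSE)
    for (col in names(df)) {
      v <- df[[col]]
      if (!is.atomic(v) || is.matrix(v))
        stop(sprintf("table '%s' column '%s' is not an atomic vector",
                     nm, col), call. = FALSE)
      if (is.double(v)) df[[col]] <- formatC(v, digits = 15, format = "g")
    }
    p <- file.path(outDir, paste0(nm, ".csv"))
    ok <- tryCatch({
      utils::write.csv(df, p, row.names = FALSE, quote = TRUE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop(sprintf("cannot write %s", p), call. = FALSE)
    p
  }, character(1))
  invisible(paths)
}
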