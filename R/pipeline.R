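# FNV-1a 32-bit hash over a string; used to fingerprint configs in the run
# manifest without an external digest dependency.
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  # 32-bit arithmetic on doubles: split the multiply to stay within 2^53
  mul32 <- function(h, p) {
    lo <- h %% 65536; hi <- h %/% 65536
    (lo * p + ((hi * p) %% 65536) * 65536) %% 2^32
  }
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)  # xor touches the low byte only
    h <- mul32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

defaultRunConfig <- function() {
  list(
    sample_sheet = NULL, data_dir = NULL, out_dir = NULL,
    channels = list(test_reporter = "EGFP", monitor = "mKATE",
                    second_reporter = NULL),
    gate = list(quantile = 0.999, scale_divisor = 6, threshold = 0.5),
    seed = 1L,
    simulate = NULL
  )
}

mergeConfig <- function(config) {
  base <- defaultRunConfig()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  for (nm in names(config)) {
    if (is.list(base[[nm]]) && is.list(config[[nm]])) {
      sub <- setdiff(names(config[[nm]]), names(base[[nm]]))
      if (length(sub))
        stop(sprintf("unknown config key(s) under %s: %s", nm,
                     paste(sub, collapse = ", ")), call. = FALSE)
      base[[nm]][names(config[[nm]])] <- config[[nm]]
    } else {
      base[[nm]] <- config[[nm]]
    }
  }
  base
}

readEventsAuto <- function(path, cm, sid) {
  if (grepl("\\.fcs$", path, ignore.case = TRUE))
    readEventsFCS(path, cm, sampleIdName = sid)
  else readEventsCSV(path, cm, sampleIdName = sid)
}

wideSampleMeans <- function(summaries, sheet, cm) {
  tr <- cm[["test_reporter"]]; mon <- cm[["monitor"]]
  pick <- function(sid, ch) {
    v <- summaries$mean_rfu[summaries$sample_id == sid &
                            summaries$channel == ch]
    if (length(v)) v else NA_real_
  }
  sheet$egfp <- vapply(sheet$sample_id, pick, numeric(1), ch = tr)
  sheet$mkate <- vapply(sheet$sample_id, pick, numeric(1), ch = mon)
  sheet
}

designKey <- function(df)
  paste(df$cell_line, df$role, df$promoter, df$kozak, df$polyA,
        df$arrangement, df$dox, sep = "|")

# replicate-filtered means per design; one row per design key
aggregateDesigns <- function(wide) {
  keys <- designKey(wide)
  out <- list()
  for (k in unique(keys)) {
    rows <- wide[keys == k & !is.na(wide$mkate), , drop = FALSE]
    if (!nrow(rows)) next
    fm <- tukeyFilterQuiet(rows$mkate)
    fe <- tukeyFilterQuiet(rows$egfp)
    first <- rows[1L, c("cell_line", "role", "promoter", "kozak", "polyA",
                        "arrangement", "dox")]
    first$egfp <- mean(fe$kept)
    first$mkate <- mean(fm$kept)
    first$n_replicates <- nrow(rows)
    first$n_kept_monitor <- length(fm$kept)
    first$monitor_reps <- I(list(fm$kept))
    first$egfp_reps <- I(list(fe$kept))
    out[[k]] <- first
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

tukeyFilterQuiet <- function(x) {
  if (length(x) < 3L) return(list(kept = x, removed = numeric()))
  tukeyFilter(x)
}

#' Run the full resource-load analysis pipeline
#'
#' Orchestrates, deterministically for a given config and seed: optional
#' library simulation, event reading (FCS or CSV), control fitting, fuzzy
#' OR gating, per-sample summaries, replicate-level outlier exclusion,
#' remaining-capacity percentages with Mann-Whitney significance against
#' the empty-vector control, induction fold changes, single-factor pair
#' attribution with quartile bars, and the Pareto front of the library
#' landscape. All result tables are written as tidy CSV together with a
#' JSON run manifest; any stage failure aborts, naming the offending
#' sample, without leaving partial outputs.
#'
#' @param config named list (or path to a YAML file) with keys
#'   \code{sample_sheet} (path or data.frame), \code{data_dir} (where the
#'   sheet's \code{file} entries live; defaults to the sheet's directory),
#'   \code{out_dir}, \code{channels} (\code{test_reporter}, \code{monitor},
#'   optional \code{second_reporter}: instrument channel names),
#'   \code{gate} (\code{quantile}, \code{scale_divisor}, \code{threshold}),
#'   \code{seed}, and optional \code{simulate} (designs are generated with
#'   [designGrid()]/[simulateLibrary()]: keys \code{promoters},
#'   \code{kozaks}, \code{polyAs}, \code{cell_line}, \code{dox},
#'   \code{n_replicates}, \code{n_events}). Unknown keys are rejected.
#' @return invisibly, the named list of result tables (also written to
#'   \code{out_dir}): \code{summaries}, \code{samples}, \code{designs},
#'   \code{capacity}, \code{fold_change}, \code{pairs},
#'   \code{quartile_bars}, \code{pareto_front}.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- mergeConfig(config)
  if (is.null(cfg$out_dir)) stop("config needs out_dir", call. = FALSE)

  if (!is.null(cfg$simulate)) {
    simKeys <- c("promoters", "kozaks", "polyAs", "cell_line", "dox",
                 "n_replicates", "n_events")
    unknown <- setdiff(names(cfg$simulate), simKeys)
    if (length(unknown))
      stop(sprintf("unknown config key(s) under simulate: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    s <- cfg$simulate
    designs <- designGrid(
      promoters = s$promoters %||% names(defaultParts()$promoters),
      kozaks = s$kozaks %||% "Kz1",
      polyAs = s$polyAs %||% "SV40pA",
      cellLine = s$cell_line %||% "HEK293T",
      dox = s$dox %||% 1)
    simDir <- file.path(cfg$out_dir, "simulated")
    sc <- simConfig(nEvents = s$n_events %||% 10000L)
    simulateLibrary(designs, sc, seed = cfg$seed,
                    nReplicates = s$n_replicates %||% 3L, outDir = simDir)
    cfg$sample_sheet <- file.path(simDir, "sample_sheet.csv")
    cfg$data_dir <- simDir
  }

  sheet <- if (is.data.frame(cfg$sample_sheet))
    validateSampleSheet(cfg$sample_sheet)
  else readSampleSheet(cfg$sample_sheet)
  dataDir <- cfg$data_dir %||%
    (if (is.character(cfg$sample_sheet)) dirname(cfg$sample_sheet) else ".")

  paths <- file.path(dataDir, sheet$file)
  absent <- !file.exists(paths)
  if (any(absent))
    stop(sprintf("event file(s) missing for sample(s) %s: %s",
                 paste(sheet$sample_id[absent], collapse = ", "),
                 paste(paths[absent], collapse = ", ")), call. = FALSE)

  cm <- channelMap(test_reporter = cfg$channels$test_reporter,
                   monitor = cfg$channels$monitor,
                   second_reporter = cfg$channels$second_reporter)
  events <- Map(function(p, sid) readEventsAuto(p, cm, sid),
                paths, sheet$sample_id)
  names(events) <- sheet$sample_id

  gateChannels <- unname(cm[c("test_reporter", "monitor")])
  summaries <- list(); nGated <- integer(nrow(sheet))
  for (cl in unique(sheet$cell_line)) {
    negIds <- sheet$sample_id[sheet$cell_line == cl &
                              sheet$role == "negative_control"]
    if (!length(negIds))
      stop(sprintf("cell line %s has no negative_control sample to fit the gate",
                   cl), call. = FALSE)
    negMat <- do.call(rbind, lapply(events[negIds], exprs))
    control <- eventTable(paste0(cl, "_negative"), negMat)
    model <- fitControl(control, gateChannels,
                        quantile = cfg$gate$quantile,
                        scaleDivisor = cfg$gate$scale_divisor)
    for (i in which(sheet$cell_line == cl)) {
      sid <- sheet$sample_id[i]
      gate <- gateTransfected(events[[sid]], model, gateChannels,
                              threshold = cfg$gate$threshold)
      nGated[i] <- sum(gateFlags(gate))
      summaries[[sid]] <- withCallingHandlers(
        summarizeSample(events[[sid]], gate),
        warning = function(w) {
          message(sprintf("[%s] %s", sid, conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
    }
  }
  summaries <- do.call(rbind, c(summaries, list(make.row.names = FALSE)))

  wide <- wideSampleMeans(summaries, sheet, cm)
  designs <- aggregateDesigns(wide[wide$role != "negative_control", ,
                                   drop = FALSE])

  capacity <- list(); fold <- list()
  for (cl in unique(designs$cell_line)) {
    d <- designs[designs$cell_line == cl, , drop = FALSE]
    empty <- d[d$role == "empty_control", , drop = FALSE]
    if (nrow(empty) != 1L)
      stop(sprintf("cell line %s needs exactly one empty_control condition",
                   cl), call. = FALSE)
    emptyReps <- empty$monitor_reps[[1]]
    for (i in seq_len(nrow(d))) {
      reps <- d$monitor_reps[[i]]
      cp <- capacityPercent(reps, emptyReps)
      mw <- if (identical(reps, emptyReps))
        list(U1 = NA_real_, U2 = NA_real_, p = NA_real_, method = "none")
      else mannWhitneyTwoSided(reps, emptyReps)
      capacity[[length(capacity) + 1L]] <- data.frame(
        d[i, c("cell_line", "role", "promoter", "kozak", "polyA",
               "arrangement", "dox")],
        capacity = cp$capacity, error = cp$error,
        n_test = cp$nTest, n_empty = cp$nEmpty,
        U1 = mw$U1, U2 = mw$U2, p = mw$p, method = mw$method,
        stars = if (is.na(mw$p)) NA_character_ else significanceStars(mw$p))
    }
    # induction fold change: same construct with and without dox
    tst <- d[d$role == "test", , drop = FALSE]
    base <- paste(tst$promoter, tst$kozak, tst$polyA, tst$arrangement,
                  sep = "|")
    for (b in unique(base[duplicated(base)])) {
      grp <- tst[base == b, , drop = FALSE]
      un <- grp[grp$dox == 0, , drop = FALSE]
      if (nrow(un) != 1L || un$egfp <= 0) next
      for (j in which(grp$dox > 0))
        fold[[length(fold) + 1L]] <- data.frame(
          grp[j, c("cell_line", "promoter", "kozak", "polyA",
                   "arrangement", "dox")],
          fold_change = foldChange(grp$egfp[j], un$egfp))
    }
  }
  capacity <- do.call(rbind, c(capacity, list(make.row.names = FALSE)))
  foldTab <- if (length(fold))
    do.call(rbind, c(fold, list(make.row.names = FALSE)))
  else data.frame(cell_line = character(), promoter = character(),
                  kozak = character(), polyA = character(),
                  arrangement = character(), dox = numeric(),
                  fold_change = numeric())

  # single-factor attribution on the single-TU test library
  attrib <- designs[designs$role == "test" &
                    designs$arrangement == "single_TU", , drop = FALSE]
  # a TET design present both uninduced and induced enters at its highest dox
  pairs <- list(); bars <- NULL; front <- NULL
  if (nrow(attrib)) {
    key <- paste(attrib$cell_line, attrib$promoter, attrib$kozak,
                 attrib$polyA, sep = "|")
    attrib <- attrib[order(key, -attrib$dox), , drop = FALSE]
    attrib <- attrib[!duplicated(paste(attrib$cell_line, attrib$promoter,
                                       attrib$kozak, attrib$polyA,
                                       sep = "|")), , drop = FALSE]
    attribCols <- attrib[, c("cell_line", "promoter", "kozak", "polyA",
                             "egfp", "mkate")]
    for (el in c("promoter", "kozak", "polyA")) {
      p <- enumerateSingleFactorPairs(attribCols, el)
      if (nrow(p)) pairs[[el]] <- p
    }
    pairs <- if (length(pairs))
      do.call(rbind, c(pairs, list(make.row.names = FALSE)))
    else NULL
    if (!is.null(pairs) && nrow(pairs) >= 4L)
      bars <- quartileAttribution(pairs)
    front <- paretoFront(attribCols)
  }
  emptyPairs <- data.frame(element = character(), design_low = character(),
                           design_high = character(),
                           delta_egfp = numeric(), delta_mkate = numeric())

  tables <- list(
    summaries = summaries,
    samples = wide[, c("sample_id", "cell_line", "role", "promoter",
                       "kozak", "polyA", "arrangement", "dox", "replicate",
                       "egfp", "mkate")],
    designs = designs[, setdiff(names(designs),
                                c("monitor_reps", "egfp_reps"))],
    capacity = capacity,
    fold_change = foldTab,
    pairs = pairs %||% emptyPairs,
    quartile_bars = bars %||% data.frame(element = character(),
                                         quartile = integer(),
                                         mean_delta_mkate = numeric(),
                                         n_pairs = integer()),
    pareto_front = front %||% data.frame()
  )

  written <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  written <- writeTidyResults(tables, cfg$out_dir)
  manifest <- list(
    config_hash = fnv1a(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                         null = "null")),
    package = "flowCapacity",
    version = as.character(utils::packageVersion("flowCapacity")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    samples = data.frame(sample_id = sheet$sample_id,
                         n_events = vapply(events, nEvents, integer(1)),
                         n_gated = nGated))
  manifestPath <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  written <- c(written, manifestPath)
  ok <- TRUE
  invisible(tables)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
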