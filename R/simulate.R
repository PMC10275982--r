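#' Build a simulator configuration
#'
#' Defaults describe a transient co-transfection of a test plasmid and the
#' capacity monitor in an adherent mammalian line: 10000 recorded events per
#' sample, about half of the cells transfected, broadly log-normal plasmid
#' uptake strongly correlated between co-delivered plasmids, a
#' transcriptional resource pool that typical construct demand saturates
#' (kappaT well below demand) and a translational pool far from saturation
#' (kappaL >= 100x maximal demand), moderate autofluorescence and
#' multiplicative measurement noise.
#'
#' @param nEvents events per sample.
#' @param fTransfected transfected fraction in [0, 1].
#' @param uptakeLogMean,uptakeLogSd log-scale plasmid copy-number
#'   distribution.
#' @param uptakeCorrelation correlation of log copies between co-delivered
#'   plasmids.
#' @param poolT,kappaT transcriptional pool size and half-saturation.
#' @param poolL,kappaL translational pool size and half-saturation.
#' @param hillBasal,hillEC50,hillH TET promoter dox response (leak fraction,
#'   EC50 in ng/uL, Hill exponent).
#' @param autofluorLogMean,autofluorLogSd named per-channel log-normal
#'   autofluorescence parameters.
#' @param noiseSd log-scale sd of multiplicative measurement noise.
#' @param mrnaMode bypass the transcriptional pool (mRNA co-transfection).
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(nEvents = 10000L, fTransfected = 0.5,
                      uptakeLogMean = log(100), uptakeLogSd = 0.8,
                      uptakeCorrelation = 0.8,
                      poolT = 2e5, kappaT = 50,
                      poolL = 4e7, kappaL = 4e7,
                      hillBasal = 0.02, hillEC50 = 0.1, hillH = 2,
                      autofluorLogMean = c(EGFP = log(80), mKATE = log(80),
                                           EBFP = log(80)),
                      autofluorLogSd = c(EGFP = 0.5, mKATE = 0.5,
                                         EBFP = 0.5),
                      noiseSd = 0.25, mrnaMode = FALSE) {
  new("SimConfig", nEvents = as.integer(nEvents),
      fTransfected = fTransfected, uptakeLogMean = uptakeLogMean,
      uptakeLogSd = uptakeLogSd, uptakeCorrelation = uptakeCorrelation,
      poolT = poolT, kappaT = kappaT, poolL = poolL, kappaL = kappaL,
      hillBasal = hillBasal, hillEC50 = hillEC50, hillH = hillH,
      autofluorLogMean = autofluorLogMean, autofluorLogSd = autofluorLogSd,
      noiseSd = noiseSd, mrnaMode = mrnaMode)
}

# Core resource-allocation model, vectorized over events.
# loads: events x TU matrix of A*P*c transcriptional demands.
# Returns list(m = events x TU mRNA outputs, given interference weights wTu).
allocateTranscription <- function(loads, wTu, config) {
  if (config@mrnaMode) {
    m <- loads  # delivered mRNA: no transcriptional competition
  } else {
    total <- rowSums(loads)
    m <- loads * config@poolT / (config@kappaT + total)
  }
  if (any(wTu > 0)) {
    # each TU's interference factor damps all *other* TUs' mRNA output
    fac <- 1 + sweep(loads, 2L, wTu, `*`)
    allFac <- apply(fac, 1L, prod)
    m <- m * fac / allFac
  }
  m
}

allocateTranslation <- function(m, cassettes, config) {
  demand <- sweep(m[, cassettes$tu, drop = FALSE], 2L, cassettes$K, `*`)
  demTot <- rowSums(demand)
  demand * config@poolL / (config@kappaL + demTot)
}

#' Noiseless cassette outputs for given plasmid copy numbers
#'
#' Closed form of the shared-resource expression model. Per transcriptional
#' unit j with stability A, promoter strength P and plasmid copies c, the
#' transcriptional demand is \code{A*P*c}; mRNA output is the proportional
#' share of a saturating pool, \code{m_j = A_j P_j c_j poolT / (kappaT +
#' sum_k A_k P_k c_k)}, optionally damped by competitor polyA interference
#' factors \code{1 / (1 + w_k A_k P_k c_k)}. Protein output divides a second
#' saturating pool by translational demand: \code{q_j = K_j m_j poolL /
#' (kappaL + sum_k K_k m_k)}. In \code{mrnaMode} the transcriptional pool is
#' bypassed and \code{m_j = A_j P_j c_j} is the delivered mRNA itself.
#'
#' @param cassettes cassette table as from [cassettesForDesign()].
#' @param copies named numeric vector (or matrix, one row per event) of
#'   copy numbers per plasmid; all values must be >= 0.
#' @param config a [SimConfig-class].
#' @return list with \code{m} (mRNA per TU), \code{q} (protein per cassette
#'   row) and \code{channel} (protein summed per channel), each a matrix
#'   with one row per event.
#' @examples
#' cfg <- simConfig()
#' cas <- cassettesForDesign(list(role = "test", promoter = "CMVp",
#'   kozak = "Kz1", polyA = "SV40pA", arrangement = "single_TU", dox = 0),
#'   cfg)
#' expectedOutputs(cas, c(test = 100, monitor = 25), cfg)$channel
#' @export
expectedOutputs <- function(cassettes, copies, config) {
  if (is.null(dim(copies)))
    copies <- matrix(copies, nrow = 1L,
                     dimnames = list(NULL, names(copies)))
  if (any(copies < 0))
    stop("plasmid copy numbers must be non-negative", call. = FALSE)
  if (nrow(cassettes) == 0L)
    return(list(m = matrix(0, nrow(copies), 0L),
                q = matrix(0, nrow(copies), 0L),
                channel = matrix(0, nrow(copies), 0L)))
  missing <- setdiff(cassettes$plasmid, colnames(copies))
  if (length(missing))
    stop(sprintf("no copy numbers for plasmid(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)

  tus <- unique(cassettes$tu)
  tuDef <- cassettes[!duplicated(cassettes$tu), , drop = FALSE]
  tuDef <- tuDef[match(tus, tuDef$tu), , drop = FALSE]
  loads <- copies[, tuDef$plasmid, drop = FALSE] *
    rep(tuDef$A * tuDef$P, each = nrow(copies))
  colnames(loads) <- tus
  m <- allocateTranscription(loads, tuDef$w, config)
  q <- allocateTranslation(m, cassettes, config)
  colnames(q) <- rownames(cassettes) <- NULL
  chans <- unique(cassettes$channel)
  channel <- vapply(chans, function(ch)
    rowSums(q[, cassettes$channel == ch, drop = FALSE]),
    numeric(nrow(q)))
  if (nrow(q) == 1L)
    channel <- matrix(channel, nrow = 1L, dimnames = list(NULL, chans))
  list(m = m, q = q, channel = channel)
}

drawCopies <- function(n, plasmids, config) {
  p <- length(plasmids)
  z <- matrix(stats::rnorm(n * p), n, p)
  if (p > 1L) {
    rho <- config@uptakeCorrelation
    sigma <- matrix(rho, p, p); diag(sigma) <- 1
    z <- z %*% chol(sigma)
  }
  copies <- exp(config@uptakeLogMean + config@uptakeLogSd * z)
  colnames(copies) <- plasmids
  copies
}

#' Simulate one co-transfection flow-cytometry sample
#'
#' Each event is untransfected with probability \code{1 - fTransfected}
#' (autofluorescence only); otherwise plasmid copy numbers are drawn from a
#' correlated log-normal, noiseless outputs follow [expectedOutputs()], and
#' measured intensities are \code{q * exp(N(0, noiseSd^2))} plus log-normal
#' autofluorescence. The monitor plasmid's copies are scaled by the
#' transfection mass ratio \code{parts$monitorCopyFraction}.
#'
#' @param design design fields as for [cassettesForDesign()]; a
#'   \code{negative_control} role yields autofluorescence-only events.
#' @param config a [SimConfig-class].
#' @param seed integer seed; the draw is fully reproducible given it.
#' @param parts part parameters, see [defaultParts()].
#' @param sampleIdName sample identifier for the event table.
#' @return list with \code{events} (an [EventTable-class] over the channels
#'   named in the autofluorescence model) and \code{truth} (data.frame of
#'   per-event ground truth: transfected flag, per-plasmid copies,
#'   noiseless per-channel outputs).
#' @export
simulateSample <- function(design, config, seed, parts = defaultParts(),
                           sampleIdName = "sim") {
  cassettes <- cassettesForDesign(design, config, parts)
  set.seed(as.integer(seed))
  n <- config@nEvents
  chans <- names(config@autofluorLogMean)
  f <- if (nrow(cassettes) == 0L) 0 else config@fTransfected
  transfected <- stats::runif(n) < f

  plasmids <- unique(cassettes$plasmid)
  copies <- matrix(0, n, length(plasmids),
                   dimnames = list(NULL, plasmids))
  if (any(transfected) && length(plasmids)) {
    drawn <- drawCopies(sum(transfected), plasmids, config)
    if ("monitor" %in% plasmids)
      drawn[, "monitor"] <- drawn[, "monitor"] * parts$monitorCopyFraction
    copies[transfected, ] <- drawn
  }

  qChan <- matrix(0, n, length(chans), dimnames = list(NULL, chans))
  if (length(plasmids)) {
    out <- expectedOutputs(cassettes, copies, config)$channel
    qChan[, colnames(out)] <- out
  }

  measured <- qChan
  for (ch in chans) {
    noise <- exp(stats::rnorm(n, 0, config@noiseSd))
    auto <- stats::rlnorm(n, config@autofluorLogMean[[ch]],
                          config@autofluorLogSd[[ch]])
    measured[, ch] <- qChan[, ch] * noise + auto
  }

  truth <- data.frame(event = seq_len(n), transfected = transfected)
  for (pl in plasmids) truth[[paste0("copies_", pl)]] <- copies[, pl]
  for (ch in chans) truth[[paste0("q_", ch)]] <- qChan[, ch]
  list(events = eventTable(sampleIdName, measured), truth = truth)
}

# Counter-based per-sample seed scheme: sample i of a run seeded with s gets
# (s mod 1e5) * 10007 + i * 7919, which stays far below 2^31 and never
# collides within a run.
sampleSeed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 1e5) * 10007 + i * 7919)
}

#' Simulate a construct library with its sample sheet and ground truth
#'
#' One sample per design x replicate, each with an independently derived,
#' reproducible seed. Designs must include one empty-vector control and one
#' untransfected negative control per cell line.
#'
#' @param designs data.frame with columns \code{cell_line}, \code{role},
#'   \code{promoter}, \code{kozak}, \code{polyA}, \code{arrangement},
#'   \code{dox} (one row per design; control rows may leave part fields
#'   empty).
#' @param config a [SimConfig-class].
#' @param seed integer master seed.
#' @param nReplicates biological replicates per design.
#' @param parts part parameters, see [defaultParts()].
#' @param outDir if non-NULL, event tables, ground truth and the sample
#'   sheet are written there as CSV and the sheet's \code{file} column
#'   points at the event files.
#' @return list with \code{sheet} (sample-sheet data.frame), \code{events}
#'   (named list of [EventTable-class]) and \code{truth} (named list of
#'   ground-truth data.frames).
#' @export
simulateLibrary <- function(designs, config, seed, nReplicates = 3L,
                            parts = defaultParts(), outDir = NULL) {
  stopifnot(is.data.frame(designs), nReplicates >= 1L)
  for (cl in unique(designs$cell_line)) {
    roles <- designs$role[designs$cell_line == cl]
    if (sum(roles == "empty_control") != 1L)
      stop(sprintf("cell line %s needs exactly one empty_control design", cl),
           call. = FALSE)
    if (sum(roles == "negative_control") != 1L)
      stop(sprintf("cell line %s needs exactly one negative_control design",
                   cl), call. = FALSE)
  }
  events <- list(); truth <- list(); rows <- list()
  counter <- 0L
  for (d in seq_len(nrow(designs))) {
    design <- as.list(designs[d, ])
    nRep <- if (design$role == "negative_control") 1L else nReplicates
    for (r in seq_len(nRep)) {
      counter <- counter + 1L
      sid <- sprintf("s%03d_%s_r%d", d, design$role, r)
      sim <- simulateSample(design, config, sampleSeed(seed, counter),
                            parts, sampleIdName = sid)
      events[[sid]] <- sim$events
      truth[[sid]] <- sim$truth
      rows[[sid]] <- data.frame(
        sample_id = sid, file = paste0(sid, ".csv"),
        cell_line = design$cell_line, role = design$role,
        promoter = design$promoter, kozak = design$kozak,
        polyA = design$polyA, arrangement = design$arrangement,
        dox = design$dox, replicate = r)
    }
  }
  sheet <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (sid in names(events)) {
      utils::write.csv(as.data.frame(exprs(events[[sid]])),
                       file.path(outDir, paste0(sid, ".csv")),
                       row.names = FALSE)
      utils::write.csv(truth[[sid]],
                       file.path(outDir, paste0(sid, "_truth.csv")),
                       row.names = FALSE)
    }
    utils::write.csv(sheet, file.path(outDir, "sample_sheet.csv"),
                     row.names = FALSE)
  }
  list(sheet = sheet, events = events, truth = truth)
}

#' Factorial design grid with its controls
#'
#' Convenience builder: the full promoter x Kozak x polyA grid of single-TU
#' test designs for one cell line, plus the empty-vector and untransfected
#' controls capacity normalization and gating require.
#'
#' @param promoters,kozaks,polyAs character vectors of part names.
#' @param cellLine cell line label.
#' @param dox doxycycline concentration applied to TET-promoter designs.
#' @return designs data.frame for [simulateLibrary()].
#' @export
designGrid <- function(promoters, kozaks, polyAs, cellLine = "HEK293T",
                       dox = 1) {
  grid <- expand.grid(promoter = promoters, kozak = kozaks, polyA = polyAs,
                      stringsAsFactors = FALSE)
  rbind(
    data.frame(cell_line = cellLine, role = "test", grid,
               arrangement = "single_TU",
               dox = ifelse(grid$promoter == "TETp", dox, 0)),
    data.frame(cell_line = cellLine, role = c("empty_control",
                                              "negative_control"),
               promoter = "none", kozak = "none", polyA = "none",
               arrangement = "single_TU", dox = 0))
}
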