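# Default genetic-part parameter tables for the simulator. Strengths and
# efficiencies are relative units on an arbitrary scale; they encode the
# qualitative ordering the analysis is designed to detect (a wide dynamic
# range of promoter strengths, one weak Kozak among near-equivalent ones,
# polyA variants differing in stability with two interference-prone ones),
# not any measured value.

#' Default part parameters for the co-transfection simulator
#'
#' @return a list with components \code{promoters} (named strengths, the TET
#'   promoter value being its fully induced strength), \code{kozaks} (named
#'   translation-initiation efficiencies), \code{polyAs} (data.frame with
#'   per-polyA mRNA stability \code{A} and interference weight \code{w}),
#'   \code{monitor} (the capacity-monitor cassette: promoter strength, Kozak
#'   efficiency, polyA stability, interference weight) and
#'   \code{monitorCopyFraction} (monitor plasmid transfection mass relative
#'   to the test plasmid), plus bicistronic second-cistron efficiencies
#'   \code{iresEff}, \code{p2aEff}, \code{t2aEff}.
#' @export
defaultParts <- function() {
  list(
    promoters = c(SV40p = 0.25, UBp = 0.5, PGKp = 1, hACTBp = 2,
                  EF1ap = 4, CAGp = 8, CMVp = 16, TETp = 32),
    kozaks = c(Kz1 = 1.0, Kz2 = 0.3, Kz3 = 0.9),
    polyAs = data.frame(
      polyA = c("SV40pA", "SV40pA_rv", "PGKpA", "BGHpA", "RBpA", "HGHpA"),
      A = c(1.0, 0.4, 0.8, 1.2, 1.5, 1.3),
      w = c(0, 3e-4, 3e-4, 0, 0, 0)),
    monitor = list(P = 16, K = 1.0, A = 1.0, w = 0),
    monitorCopyFraction = 0.25,
    iresEff = 0.35, p2aEff = 0.8, t2aEff = 0.7
  )
}

#' Doxycycline dose response of the TET promoter
#'
#' Hill multiplier applied to the TET promoter's fully induced strength:
#' \code{basal + (1 - basal) * d^h / (d^h + EC50^h)}.
#'
#' @param dox doxycycline concentration, ng/uL (>= 0).
#' @param config a [SimConfig-class] holding \code{hillBasal},
#'   \code{hillEC50} and \code{hillH}.
#' @return multiplier in (0, 1].
#' @export
doxResponse <- function(dox, config) {
  stopifnot(all(dox >= 0))
  config@hillBasal + (1 - config@hillBasal) *
    dox^config@hillH / (dox^config@hillH + config@hillEC50^config@hillH)
}

lookupPart <- function(table, name, kind) {
  if (!name %in% names(table))
    stop(sprintf("unknown %s '%s' (known: %s)", kind, name,
                 paste(names(table), collapse = ", ")), call. = FALSE)
  unname(table[[name]])
}

#' Cassette table for one construct design
#'
#' Expands a sample-sheet-style design (promoter, kozak, polyA, arrangement,
#' role, dox) into the simulator's cassette table: one row per protein
#' output, grouped into transcriptional units (TUs) carried on plasmids. The
#' capacity monitor (a constitutive mKATE TU on its own plasmid) is added to
#' every transfected design; an empty-vector control contributes no test
#' cassette but still carries the empty plasmid.
#'
#' @param design list or one-row data.frame with fields \code{role},
#'   \code{promoter}, \code{kozak}, \code{polyA}, \code{arrangement},
#'   \code{dox}.
#' @param config a [SimConfig-class] (for the dox response).
#' @param parts part parameter list, see [defaultParts()].
#' @return data.frame with columns \code{plasmid}, \code{tu}, \code{channel},
#'   \code{P}, \code{K}, \code{A}, \code{w}; zero rows for a negative
#'   (untransfected) control.
#' @export
cassettesForDesign <- function(design, config, parts = defaultParts()) {
  role <- design$role
  if (role == "negative_control")
    return(data.frame(plasmid = character(), tu = character(),
                      channel = character(), P = numeric(), K = numeric(),
                      A = numeric(), w = numeric()))
  mon <- with(parts$monitor, data.frame(
    plasmid = "monitor", tu = "mon", channel = "mKATE",
    P = P, K = K, A = A, w = w))
  if (role %in% c("empty_control", "monitor_only"))
    return(mon)

  P <- lookupPart(parts$promoters, design$promoter, "promoter")
  if (design$promoter == "TETp") P <- P * doxResponse(design$dox, config)
  K <- lookupPart(parts$kozaks, design$kozak, "kozak")
  pa <- parts$polyAs[parts$polyAs$polyA == design$polyA, ]
  if (nrow(pa) != 1L)
    stop(sprintf("unknown polyA '%s'", design$polyA), call. = FALSE)

  test <- switch(design$arrangement,
    single_TU = data.frame(plasmid = "test", tu = "t1", channel = "EGFP",
                           P = P, K = K, A = pa$A, w = pa$w),
    two_TU = data.frame(plasmid = "test", tu = c("t1", "t2"),
                        channel = c("EGFP", "EBFP"),
                        P = P, K = K, A = pa$A, w = pa$w),
    IRES = data.frame(plasmid = "test", tu = "t1",
                      channel = c("EGFP", "EBFP"),
                      P = P, K = c(K, K * parts$iresEff),
                      A = pa$A, w = pa$w),
    P2A = data.frame(plasmid = "test", tu = "t1",
                     channel = c("EGFP", "EBFP"),
                     P = P, K = c(K, K * parts$p2aEff),
                     A = pa$A, w = pa$w),
    T2A = data.frame(plasmid = "test", tu = "t1",
                     channel = c("EGFP", "EBFP"),
                     P = P, K = c(K, K * parts$t2aEff),
                     A = pa$A, w = pa$w),
    stop(sprintf("unsupported arrangement '%s'", design$arrangement),
         call. = FALSE))
  rbind(test, mon)
}
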