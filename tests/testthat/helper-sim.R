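# Shared fixture builders used across test files.

# A GateResult taking exactly the events whose `keep` flag is TRUE, for
# testing summaries independently of the gating stage.
manualGate <- function(keep, channels = "ch") {
  memb <- matrix(as.numeric(keep), ncol = length(channels),
                 nrow = length(keep), dimnames = list(NULL, channels))
  new("GateResult", membership = memb, combined = as.numeric(keep),
      flag = as.logical(keep), threshold = 0.5)
}

testDesign <- function(promoter = "CMVp", kozak = "Kz1", polyA = "SV40pA",
                       arrangement = "single_TU", dox = 0,
                       role = "test")
  list(role = role, promoter = promoter, kozak = kozak, polyA = polyA,
       arrangement = arrangement, dox = dox)

# small, fast simulator configuration for unit tests
smallConfig <- function(...) simConfig(nEvents = 2000L, ...)

# brute-force two-sided Mann-Whitney p by enumeration of all label
# assignments; independent of the package's implementation (counts
# assignments at least as extreme as the observed smaller U)
bruteMWp <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  uOf <- function(idx) sum(r[idx]) - n * (n + 1) / 2
  uObs <- min(uOf(seq_len(n)), n * m - uOf(seq_len(n)))
  sets <- utils::combn(n + m, n)
  us <- apply(sets, 2L, uOf)
  mean(pmin(us, n * m - us) <= uObs)
}

# brute-force O(n^2) Pareto dominance check
brutePareto <- function(df) {
  keep <- vapply(seq_len(nrow(df)), function(i) {
    e <- df$egfp[i]; m <- df$mkate[i]
    !any(df$egfp >= e & df$mkate >= m & (df$egfp > e | df$mkate > m))
  }, logical(1))
  df[keep, , drop = FALSE]
}
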