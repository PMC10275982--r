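test_that("expectedOutputs obeys its closed-form limiting cases", {
  cfg <- simConfig()
  cas <- cassettesForDesign(testDesign(), cfg)

  # no template, no output
  zero <- expectedOutputs(cas, c(test = 0, monitor = 0), cfg)
  expect_true(all(zero$q == 0))

  # competition-free limit: kappaT -> Inf with poolT/kappaT = 1 gives
  # m = A*P*c (and a vast translational pool passes it through as K*m)
  big <- simConfig(poolT = 1e12, kappaT = 1e12, poolL = 1e18, kappaL = 1e18)
  one <- data.frame(plasmid = "test", tu = "t1", channel = "EGFP",
                    P = 3, K = 1, A = 2, w = 0)
  out <- expectedOutputs(one, c(test = 10), big)
  expect_equal(unname(out$m[1, 1]), 2 * 3 * 10, tolerance = 1e-6)

  # symmetry: identical cassettes with equal copies express equally
  twin <- data.frame(plasmid = c("a", "b"), tu = c("t1", "t2"),
                     channel = c("EGFP", "EBFP"), P = 5, K = 1, A = 1,
                     w = 1e-4)
  o <- expectedOutputs(twin, c(a = 50, b = 50), cfg)
  expect_equal(o$q[1, 1], o$q[1, 2])

  expect_error(expectedOutputs(one, c(test = -1), big), "non-negative")
  expect_error(simConfig(poolT = -1), "positive")
})

test_that("monitor output is non-increasing in any competitor load (grid)", {
  cfg <- simConfig()
  for (ap in c(0.5, 2, 8, 32, 128)) {
    prev <- Inf
    for (c_test in c(0, 10, 50, 200, 1000)) {
      cas <- data.frame(plasmid = c("test", "monitor"),
                        tu = c("t1", "mon"), channel = c("EGFP", "mKATE"),
                        P = c(ap, 16), K = 1, A = 1, w = 0)
      q <- expectedOutputs(cas, c(test = c_test, monitor = 25),
                           cfg)$channel[1, "mKATE"]
      expect_lte(q, prev + 1e-9)
      prev <- q
    }
  }
})

test_that("fTransfected = 0 yields autofluorescence-only events", {
  sim <- simulateSample(testDesign(), smallConfig(fTransfected = 0), 5)
  expect_false(any(sim$truth$transfected))
  expect_true(all(sim$truth$q_EGFP == 0))
  # pure autofluorescence: a decade below typical transfected signal
  expect_lt(mean(exprs(sim$events)[, "EGFP"]), 500)
})

test_that("noiseless simulation with fixed copies equals the closed form", {
  cfg <- smallConfig(noiseSd = 0, uptakeLogSd = 0, fTransfected = 1,
                     autofluorLogMean = c(EGFP = -Inf, mKATE = -Inf,
                                          EBFP = -Inf),
                     autofluorLogSd = c(EGFP = 0, mKATE = 0, EBFP = 0))
  design <- testDesign("EF1ap", "Kz2", "BGHpA")
  sim <- simulateSample(design, cfg, 3)
  parts <- defaultParts()
  cas <- cassettesForDesign(design, cfg, parts)
  copies <- c(test = exp(cfg@uptakeLogMean),
              monitor = exp(cfg@uptakeLogMean) * parts$monitorCopyFraction)
  want <- expectedOutputs(cas, copies, cfg)$channel
  expect_equal(unname(exprs(sim$events)[1, c("EGFP", "mKATE")]),
               unname(want[1, c("EGFP", "mKATE")]))
  expect_equal(max(exprs(sim$events)[, "EGFP"]),
               min(exprs(sim$events)[, "EGFP"]))  # all events identical
})

test_that("simulated monitor mean matches a brute-force copy-number average", {
  cfg <- simConfig(nEvents = 50000L)
  design <- testDesign("CMVp", "Kz1", "SV40pA")
  sim <- simulateSample(design, cfg, 21)
  tr <- sim$truth$transfected
  measured <- exprs(sim$events)[tr, "mKATE"]

  # independent oracle: integrate the two-cassette allocation formula over
  # 1e6 correlated log-normal copy draws, written out longhand
  set.seed(99)
  nD <- 1e6
  z1 <- rnorm(nD); z2 <- rnorm(nD)
  rho <- cfg@uptakeCorrelation
  cT <- exp(cfg@uptakeLogMean + cfg@uptakeLogSd * z1)
  cM <- exp(cfg@uptakeLogMean + cfg@uptakeLogSd *
              (rho * z1 + sqrt(1 - rho^2) * z2)) * 0.25
  pts <- defaultParts()
  loadT <- pts$polyAs$A[pts$polyAs$polyA == "SV40pA"] *
    pts$promoters[["CMVp"]] * cT
  loadM <- pts$monitor$A * pts$monitor$P * cM
  mM <- loadM * cfg@poolT / (cfg@kappaT + loadT + loadM)
  dT <- pts$kozaks[["Kz1"]] * loadT * cfg@poolT /
    (cfg@kappaT + loadT + loadM)
  qM <- mM * cfg@poolL / (cfg@kappaL + dT + mM)
  oracle <- mean(qM) * exp(cfg@noiseSd^2 / 2) +
    exp(cfg@autofluorLogMean[["mKATE"]] +
          cfg@autofluorLogSd[["mKATE"]]^2 / 2)

  se <- sqrt(var(measured) / length(measured) + var(qM) / nD)
  expect_lt(abs(mean(measured) - oracle), 3 * se)
})

test_that("library simulation: counts, sheet validity, determinism", {
  designs <- designGrid(names(defaultParts()$promoters), "Kz1", "SV40pA")
  cfg <- simConfig(nEvents = 200L)
  lib <- simulateLibrary(designs, cfg, seed = 17, nReplicates = 3L)
  expect_equal(sum(lib$sheet$role == "test"), 8L * 3L)
  expect_equal(sum(lib$sheet$role == "empty_control"), 3L)
  expect_equal(sum(lib$sheet$role == "negative_control"), 1L)
  expect_silent(validateSampleSheet(lib$sheet))

  lib2 <- simulateLibrary(designs, cfg, seed = 17, nReplicates = 3L)
  expect_identical(lapply(lib$events, exprs), lapply(lib2$events, exprs))

  noCtrl <- designs[designs$role == "test", ]
  expect_error(simulateLibrary(noCtrl, cfg, 1), "empty_control")
})

test_that("monitor mean decreases across promoter strengths 1,2,4,8", {
  # averaged over 5 seeds, strengths spanning 8x at small kappaT
  parts <- defaultParts()
  means <- sapply(c("PGKp", "hACTBp", "EF1ap", "CAGp"), function(p) {
    mean(sapply(1:5, function(s) {
      sim <- simulateSample(testDesign(p), smallConfig(), s)
      mean(sim$truth$q_mKATE[sim$truth$transfected])
    }))
  })
  expect_equal(unname(parts$promoters[c("PGKp", "hACTBp", "EF1ap", "CAGp")]),
               c(1, 2, 4, 8))  # the strengths the claim is about
  expect_true(all(diff(means) < 0))
})

test_that("resource pools are conserved on every simulated event", {
  for (arr in c("single_TU", "two_TU", "IRES")) {
    cfg <- smallConfig()
    sim <- simulateSample(testDesign(arrangement = arr, polyA = "PGKpA"),
                          cfg, 13)
    q <- as.matrix(sim$truth[, grep("^q_", names(sim$truth))])
    expect_true(all(rowSums(q) <= cfg@poolL + 1e-9))
  }
})

test_that("translation stays unsaturated: 10x Kozak moves the monitor < 1%", {
  # kappaL >= 100x demand by construction; paired draws isolate the model
  cfg <- smallConfig()
  parts <- defaultParts()
  parts$kozaks <- c(KzLo = 0.1, KzHi = 1.0)
  lo <- simulateSample(testDesign(kozak = "KzLo"), cfg, 31, parts)
  hi <- simulateSample(testDesign(kozak = "KzHi"), cfg, 31, parts)
  tr <- lo$truth$transfected
  egfpRatio <- mean(hi$truth$q_EGFP[tr]) / mean(lo$truth$q_EGFP[tr])
  monShift <- abs(mean(hi$truth$q_mKATE[tr]) /
                    mean(lo$truth$q_mKATE[tr]) - 1)
  expect_gt(egfpRatio, 5)
  expect_lt(monShift, 0.01)
})
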