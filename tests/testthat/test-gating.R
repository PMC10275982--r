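test_that("control fitting matches analytic log-normal quantiles", {
  set.seed(42)
  et <- eventTable("neg", cbind(EGFP = rlnorm(2e5, log(80), 0.5)))
  model <- fitControl(et, "EGFP")
  expect_equal(unname(model@location["EGFP"]), qlnorm(0.999, log(80), 0.5),
               tolerance = 0.02)
  expect_gt(unname(model@scale["EGFP"]), 0)
})

test_that("degenerate controls get the documented scale floor", {
  et <- eventTable("neg", cbind(EGFP = rep(100, 500)))
  model <- fitControl(et, "EGFP")
  expect_equal(unname(model@location["EGFP"]), 100)
  expect_equal(unname(model@scale["EGFP"]),
               sqrt(.Machine$double.eps) * 100)
  # effectively crisp: membership jumps at the location
  expect_lt(membership(99.99, model, "EGFP"), 1e-6)
  expect_gt(membership(100.01, model, "EGFP"), 1 - 1e-6)
})

test_that("control fitting rejects unmapped channels and small controls", {
  et <- eventTable("neg", cbind(EGFP = rlnorm(500)))
  expect_error(fitControl(et, "mKATE"), "mKATE")
  small <- eventTable("neg", cbind(EGFP = rlnorm(99)))
  expect_error(fitControl(small, "EGFP"), "100")
})

test_that("logistic membership: midpoint, tails, monotonicity", {
  et <- eventTable("neg", cbind(EGFP = rlnorm(1000, log(80), 0.5)))
  model <- fitControl(et, "EGFP")
  loc <- model@location[["EGFP"]]; sc <- model@scale[["EGFP"]]
  expect_equal(membership(loc, model, "EGFP"), 0.5)
  expect_gt(membership(loc + 20 * sc, model, "EGFP"), 0.999)
  grid <- seq(loc - 30 * sc, loc + 30 * sc, length.out = 200)
  memb <- membership(grid, model, "EGFP")
  expect_true(all(diff(memb) >= 0))
  expect_true(all(memb >= 0 & memb <= 1))
  expect_equal(memb, plogis((grid - loc) / sc))  # closed form
})

test_that("fuzzy OR gate is commutative, monotone, and grows with channels", {
  set.seed(11)
  neg <- eventTable("neg", cbind(EGFP = rlnorm(5000, log(80), 0.5),
                                 mKATE = rlnorm(5000, log(80), 0.5)))
  model <- fitControl(neg)
  mix <- eventTable("s", cbind(EGFP = c(rlnorm(500, log(80), 0.5),
                                        rlnorm(500, log(4e4), 0.4)),
                               mKATE = c(rlnorm(500, log(80), 0.5),
                                         rlnorm(500, log(4e4), 0.4))))
  g12 <- gateTransfected(mix, model, c("EGFP", "mKATE"))
  g21 <- gateTransfected(mix, model, c("mKATE", "EGFP"))
  expect_equal(g12@combined, g21@combined)
  expect_identical(gateFlags(g12), gateFlags(g21))

  g1 <- gateTransfected(mix, model, "EGFP")
  expect_true(all(gateFlags(g12) | !gateFlags(g1)))  # OR only grows the set

  gLoose <- gateTransfected(mix, model, threshold = 0.2)
  gTight <- gateTransfected(mix, model, threshold = 0.8)
  expect_true(all(gateFlags(g12) | !gateFlags(gTight)))
  expect_true(all(gateFlags(gLoose) | !gateFlags(g12)))

  expect_error(gateTransfected(mix, model, character()), "at least one")
})

test_that("events at the control median are not gated", {
  neg <- eventTable("neg", cbind(EGFP = rlnorm(1000, log(80), 0.5)))
  model <- fitControl(neg)
  flat <- eventTable("s", cbind(EGFP = rep(median(exprs(neg)), 200)))
  expect_equal(gatedFraction(gateTransfected(flat, model)), 0)
})

test_that("gate recovers the transfected population from the simulator", {
  cfg <- smallConfig()
  neg <- simulateSample(testDesign(role = "negative_control"), cfg, 8)
  model <- fitControl(neg$events, c("EGFP", "mKATE"))
  sim <- simulateSample(testDesign(), cfg, 9)
  gate <- gateTransfected(sim$events, model, c("EGFP", "mKATE"))
  tr <- sim$truth$transfected; fl <- gateFlags(gate)
  expect_gte(sum(fl & tr) / sum(tr), 0.99)  # recall
  expect_gte(sum(fl & tr) / sum(fl), 0.99)  # precision

  # gated fraction within the binomial 99% CI of the transfection rate
  n <- nEvents(sim$events)
  half <- qnorm(0.995) * sqrt(0.5 * 0.5 / n)
  expect_lt(abs(gatedFraction(gate) - cfg@fTransfected), half + 0.003)
})
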