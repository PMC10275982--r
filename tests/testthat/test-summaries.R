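test_that("gated summary: hand arithmetic, population sd", {
  et <- eventTable("s", cbind(ch = c(10, 20, 30, 999, 999)))
  s <- summarizeSample(et, manualGate(c(TRUE, TRUE, TRUE, FALSE, FALSE)))
  expect_equal(s$mean_rfu, 20)
  expect_equal(s$sd_rfu, sqrt(200 / 3), tolerance = 1e-12)  # approx 8.1650
  expect_equal(s$n_events, 5L)
  expect_equal(s$n_gated, 3L)
  expect_false(s$excluded)
})

test_that("a fully gated-out sample is excluded with a warning", {
  et <- eventTable("s", cbind(ch = c(1, 2)))
  expect_warning(s <- summarizeSample(et, manualGate(c(FALSE, FALSE))),
                 "no events pass")
  expect_true(s$excluded)
  expect_true(is.na(s$mean_rfu))
})

test_that("Tukey fences: worked example, ties, partition, order invariance", {
  r <- tukeyFilter(c(1, 2, 3, 4, 100))
  expect_identical(r$removed, 100)       # Q1=2, Q3=4, fences [-1, 7]
  expect_identical(r$kept, c(1, 2, 3, 4))

  expect_length(tukeyFilter(c(5, 5, 5, 5))$removed, 0L)  # zero IQR

  set.seed(2)
  for (i in 1:20) {
    x <- rlnorm(sample(3:12, 1), 5, sample(c(0.1, 1, 3), 1))
    r <- tukeyFilter(x)
    expect_setequal(c(r$kept, r$removed), x)
    expect_length(c(r$kept, r$removed), length(x))
    perm <- tukeyFilter(sample(x))
    expect_setequal(perm$kept, r$kept)
  }
  expect_warning(r2 <- tukeyFilter(c(1, 2)), "unfiltered")
  expect_identical(r2$kept, c(1, 2))
})

test_that("capacity: identity, worked example, scale invariance", {
  expect_identical(capacityPercent(c(1000, 1000), c(1000, 1000))$capacity,
                   100)
  cp <- capacityPercent(c(480, 480), c(1000, 1000))
  expect_equal(cp$capacity, 48)
  x <- c(450, 510, 480); e <- c(980, 1030, 990)
  expect_equal(capacityPercent(x, e)$capacity,
               capacityPercent(2 * x, 2 * e)$capacity)
  expect_equal(capacityPercent(x, e)$error,
               capacityPercent(2 * x, 2 * e)$error)
  expect_error(capacityPercent(c(1), c(0)), "positive")
})

test_that("capacity error combines both replicate CVs in quadrature", {
  x <- c(450, 510); e <- c(980, 1020)
  cp <- capacityPercent(x, e)
  want <- 100 * mean(x) / mean(e) *
    sqrt((sd(x) / mean(x))^2 + (sd(e) / mean(e))^2)
  expect_equal(cp$error, want)
  expect_true(is.na(capacityPercent(480, c(1000, 1000))$error))
})

test_that("fold change: identity, arithmetic, dose-response property", {
  expect_equal(foldChange(100, 100), 1)
  expect_equal(foldChange(500, 50), 10)
  expect_error(foldChange(10, 0), "positive")

  # induced output rises with dox through the Hill response
  cfg <- smallConfig()
  means <- sapply(c(0, 0.05, 0.2, 1), function(d) {
    sim <- simulateSample(testDesign("TETp", dox = d), cfg, 19)
    mean(sim$truth$q_EGFP[sim$truth$transfected])
  })
  fc <- means[-1] / means[1]
  expect_true(all(diff(fc) > 0))
  expect_gt(fc[3], 5)  # strong induction at 1 ng/uL over the 2% leak
})

test_that("Mann-Whitney: exact worked case and symmetry", {
  mw <- mannWhitneyTwoSided(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U1, 0)
  expect_equal(mw$U2, 9)
  expect_equal(mw$p, 0.1)
  expect_identical(mw$method, "exact")

  sw <- mannWhitneyTwoSided(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sw$p, mw$p)
  expect_equal(sw$U1, mw$U2)
  expect_equal(sw$U2, mw$U1)
})

test_that("Mann-Whitney agrees with wilcox.test on tie-free samples", {
  set.seed(8)
  for (i in 1:25) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    x <- rnorm(n); y <- rnorm(m, sample(c(0, 2), 1))
    mw <- mannWhitneyTwoSided(x, y)
    wt <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(mw$U1, unname(wt$statistic))
    expect_equal(mw$U1 + mw$U2, n * m)
    expect_equal(mw$p, wt$p.value, tolerance = 1e-12)
  }
})

test_that("ties and large samples fall back to the corrected normal path", {
  same <- mannWhitneyTwoSided(c(1, 2, 2, 3), c(1, 2, 2, 3))
  expect_identical(same$method, "normal-approximation")
  expect_equal(same$p, 1)

  set.seed(9)
  x <- rnorm(40); y <- rnorm(45, 0.8)
  mw <- mannWhitneyTwoSided(x, y)
  wt <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_identical(mw$method, "normal-approximation")
  expect_equal(mw$p, wt$p.value, tolerance = 1e-10)
  expect_true(mw$p > 0 && mw$p <= 1)
})

test_that("significance stars follow the four-level convention", {
  expect_identical(significanceStars(c(0.5, 0.04, 0.004, 4e-4, 9e-5)),
                   c("ns", "*", "**", "***", "****"))
  expect_identical(significanceStars(c(0.05, 0.005, 5e-4, 1e-4)),
                   c("ns", "*", "**", "***"))  # thresholds are strict
})
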