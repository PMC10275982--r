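gridSummaries <- function(promoters, kozaks, polyAs, seed = 1) {
  set.seed(seed)
  g <- expand.grid(promoter = promoters, kozak = kozaks, polyA = polyAs,
                   stringsAsFactors = FALSE)
  g$egfp <- rlnorm(nrow(g), 10, 1)
  g$mkate <- rlnorm(nrow(g), 11, 0.5)
  g
}

test_that("single-factor pair enumeration hits the G * C(L,2) identity", {
  cases <- list(c(2, 2, 2), c(3, 2, 2), c(4, 3, 2), c(8, 3, 2))
  for (dims in cases) {
    g <- gridSummaries(paste0("P", seq_len(dims[1])),
                       paste0("K", seq_len(dims[2])),
                       paste0("A", seq_len(dims[3])))
    sizes <- c(promoter = dims[1], kozak = dims[2], polyA = dims[3])
    for (el in names(sizes)) {
      L <- sizes[[el]]
      G <- prod(sizes[names(sizes) != el])
      expect_equal(nrow(enumerateSingleFactorPairs(g, el)),
                   G * choose(L, 2))
    }
  }
  expect_equal(nrow(enumerateSingleFactorPairs(gridSummaries("P1", "K1", "A1"),
                                               "promoter")), 0L)
})

test_that("pairs are oriented with non-negative reporter delta", {
  g <- gridSummaries(paste0("P", 1:4), paste0("K", 1:2), paste0("A", 1:2))
  for (el in c("promoter", "kozak", "polyA")) {
    p <- enumerateSingleFactorPairs(g, el)
    expect_true(all(p$delta_egfp >= 0))
  }
  # exact ties resolved by lexicographic design label
  tie <- data.frame(promoter = c("Pa", "Pb"), kozak = "K", polyA = "A",
                    egfp = 5, mkate = c(9, 7))
  p <- enumerateSingleFactorPairs(tie, "promoter")
  expect_equal(p$design_low, "Pa|K|A")
  expect_equal(p$design_high, "Pb|K|A")
  expect_equal(p$delta_mkate, -2)
})

test_that("missing grid combinations drop their pairs without error", {
  g <- gridSummaries(paste0("P", 1:3), paste0("K", 1:2), paste0("A", 1:2))
  drop <- !(g$promoter == "P2" & g$kozak == "K1" & g$polyA == "A1")
  p <- enumerateSingleFactorPairs(g[drop, ], "promoter")
  # one context lost C(3,2) - C(2,2) = 2 of its pairs
  expect_equal(nrow(p), 4 * choose(3, 2) - 2)
  expect_false(any(grepl("^P2\\|K1\\|A1$", c(p$design_low, p$design_high))))

  dup <- rbind(g, g[1, ])
  expect_error(enumerateSingleFactorPairs(dup, "promoter"), "duplicate")
})

test_that("quartile bars reproduce the worked example", {
  pairs <- data.frame(element = "promoter", delta_egfp = 1:8,
                      delta_mkate = -(1:8))
  bars <- quartileAttribution(pairs)
  expect_equal(bars$mean_delta_mkate, c(-1.5, -3.5, -5.5, -7.5))
  expect_equal(bars$n_pairs, rep(2L, 4))
  expect_equal(bars$quartile, 1:4)

  zero <- pairs; zero$delta_mkate <- 0
  expect_true(all(quartileAttribution(zero)$mean_delta_mkate == 0))

  shuffled <- pairs[sample(8), ]
  expect_equal(quartileAttribution(shuffled), bars)

  expect_warning(one <- quartileAttribution(pairs[1:3, ]), "single-bin")
  expect_equal(one$n_pairs, 3L)
  expect_true(is.na(one$quartile))
})

test_that("Pareto front matches brute-force dominance for random clouds", {
  single <- data.frame(egfp = 1, mkate = 2)
  expect_equal(paretoFront(single), single)

  spec <- data.frame(egfp = c(1, 2, 3, 2), mkate = c(5, 4, 1, 5))
  expect_equal(paretoFront(spec),
               data.frame(egfp = c(3, 2), mkate = c(1, 5),
                          row.names = c(3L, 4L)))

  dupes <- data.frame(egfp = c(2, 2, 1), mkate = c(5, 5, 1))
  expect_equal(nrow(paretoFront(dupes)), 2L)  # identical ties retained

  set.seed(3)
  for (i in 1:5) {
    cloud <- data.frame(egfp = sample(round(rlnorm(200, 10, 1)), 200),
                        mkate = round(rlnorm(200, 11, 0.5)))
    expect_equal(paretoFront(cloud), brutePareto(cloud))
  }
})

test_that("plot helpers return ggplot objects", {
  g <- gridSummaries(paste0("P", 1:4), paste0("K", 1:2), paste0("A", 1:2))
  expect_s3_class(plotLibraryLandscape(g), "ggplot")
  pairs <- enumerateSingleFactorPairs(g, "promoter")
  expect_s3_class(plotQuartileBars(quartileAttribution(pairs)), "ggplot")
})
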