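test_that("fGn generator is seed-deterministic and standardised", {
  x1 <- generateFGN(0.7, 256, seed = 11)
  x2 <- generateFGN(0.7, 256, seed = 11)
  expect_identical(x1, x2)
  expect_false(identical(x1, generateFGN(0.7, 256, seed = 12)))

  # ensemble moments: Monte-Carlo averages of the sample mean and sample
  # variance settle at 0 and 1 (persistent series drift too much for a
  # single draw: Var(sample mean) = n^(2h - 2))
  for (h in c(0.3, 0.6, 0.8)) {
    mom <- vapply(1:50, function(s) {
      x <- generateFGN(h, 4096, seed = 20 + s)
      c(mean(x), var(x))
    }, numeric(2))
    expect_lt(abs(mean(mom[1, ])), 0.1)
    expect_lt(abs(mean(mom[2, ]) - 1), 0.15)
  }
  # strongly persistent case: the expected sample variance is depressed by
  # exactly the variance of the sample mean, 1 - n^(2h - 2)
  v9 <- mean(vapply(1:50, function(s)
    var(generateFGN(0.9, 4096, seed = 70 + s)), numeric(1)))
  expect_lt(abs(v9 - (1 - 4096^(2 * 0.9 - 2))), 0.1)
  expect_error(generateFGN(1.2, 256, 1), "generatePowerLawSignal")
  expect_error(generateFGN(0.5, 32, 1), ">= 64")
})

test_that("fGn with H = 0.5 is white and H = 0.8 is recovered by DFA", {
  x <- generateFGN(0.5, 1024, seed = 5)
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1), 0.1)

  hh <- vapply(1:100, function(s)
    scalingExponent(dfaHurst(generateFGN(0.8, 1024, seed = s))),
    numeric(1))
  expect_lt(abs(mean(hh) - 0.8), 0.05)
})

test_that("power-law synthesis hits the requested spectral slope", {
  # flat spectrum by construction
  b0 <- scalingExponent(psdBeta(generatePowerLawSignal(0, 4096, seed = 3)))
  expect_lt(abs(b0), 0.1)

  b1 <- mean(vapply(1:5, function(s)
    scalingExponent(psdBeta(generatePowerLawSignal(1, 4096, seed = s))),
    numeric(1)))
  expect_lt(abs(b1 - 1), 0.1)
  h1 <- mean(vapply(1:5, function(s)
    scalingExponent(dfaHurst(generatePowerLawSignal(1, 4096, seed = s))),
    numeric(1)))
  expect_lt(abs(h1 - 1.0), 0.1)

  # nonstationary regime H = (beta + 1) / 2 = 1.2
  h14 <- mean(vapply(1:10, function(s)
    scalingExponent(dfaHurst(generatePowerLawSignal(1.4, 4096, seed = s))),
    numeric(1)))
  expect_lt(abs(h14 - 1.2), 0.1)

  expect_error(generatePowerLawSignal(-0.5, 256, 1), "beta")
})

test_that("coupled pairs have the requested Pearson coupling", {
  p <- generateCoupledPair(0.8, 1, 256, seed = 2)
  expect_equal(p$x, p$y)
  pm <- generateCoupledPair(0.8, -1, 256, seed = 2)
  expect_equal(pm$x, -pm$y)

  p6 <- generateCoupledPair(0.8, 0.6, 4096, seed = 7)
  expect_lt(abs(cor(p6$x, p6$y) - 0.6), 0.05)

  r0 <- vapply(1:100, function(s) {
    p <- generateCoupledPair(0.7, 0, 1024, seed = s)
    rhoQ(p$x, p$y, s = 10)
  }, numeric(1))
  expect_lt(abs(mean(r0)), 0.05)

  expect_error(generateCoupledPair(0.8, 1.2, 256, 1), "rhoTarget")
})

test_that("ROI surrogates honour shape, blocks and Hurst targets", {
  spec <- surrogateSpec(nRegions = 116, nFrames = 400)
  x <- generateROISurrogate(spec)
  expect_identical(dim(boldValues(x)), c(400L, 116L))
  expect_identical(regionLabels(x), regionLabels(spec))

  # two blocks, strong within-block coupling vs none across
  sp2 <- surrogateSpec(nRegions = 10, nFrames = 512, hurst = 0.8,
                       blocks = rep(1:2, each = 5),
                       blockCorrelation = c(0.9, 0.9), seed = 4)
  v <- boldValues(generateROISurrogate(sp2))
  cc <- cor(v)
  within <- c(cc[1:5, 1:5][upper.tri(diag(5))],
              cc[6:10, 6:10][upper.tri(diag(5))])
  between <- as.vector(cc[1:5, 6:10])
  expect_gt(mean(within), mean(between))

  # per-region Hurst recovery: halves at 0.6 vs 1.1 differ by ~0.5
  sp3 <- surrogateSpec(nRegions = 24, nFrames = 1024,
                       hurst = rep(c(0.6, 1.1), each = 12),
                       blocks = 1L, blockCorrelation = 0, seed = 9)
  v3 <- boldValues(generateROISurrogate(sp3))
  hs <- apply(v3, 2, function(col) scalingExponent(dfaHurst(col)))
  expect_lt(abs((mean(hs[13:24]) - mean(hs[1:12])) - 0.5), 0.1)
})

test_that("the default trial schedule concatenates to exactly 400 frames", {
  sched <- generateEventSchedule()
  df <- as.data.frame(sched)
  expect_identical(sum(df$trial_type == "encoding"), 60L)
  expect_identical(sum(df$trial_type == "retrieval"), 60L)
  expect_true(all(diff(eventOnsets(sched, "encoding")) > 0))
  expect_true(all(diff(eventOnsets(sched, "retrieval")) > 0))

  for (ph in c("encoding", "retrieval")) {
    lens <- vapply(eventOnsets(sched, ph), function(o)
      length(fractalBOLD:::frameIndicesInWindow(o, 12.0, 1.8)), integer(1))
    expect_true(all(lens %in% c(6L, 7L)))
    expect_identical(sum(lens), 400L)
  }

  # overlapping events are rejected
  expect_error(EventSchedule(c(0, 1), c(2, 2), c("encoding", "retrieval")),
               "overlap")
  expect_identical(as.data.frame(generateEventSchedule(seed = 3)),
                   as.data.frame(generateEventSchedule(seed = 3)))
})

test_that("shuffling preserves values and destroys temporal scaling", {
  x <- generateFGN(0.9, 512, seed = 1)
  y <- shuffleSeries(x, seed = 2)
  expect_identical(sort(y), sort(x))
  expect_equal(mean(y), mean(x))
  expect_equal(var(y), var(x))

  cst <- rep(3.5, 100)
  expect_identical(shuffleSeries(cst, seed = 1), cst)

  hs <- vapply(1:50, function(s)
    scalingExponent(dfaHurst(shuffleSeries(
      generateFGN(0.9, 1024, seed = s), seed = s + 1000))),
    numeric(1))
  expect_lt(abs(mean(hs) - 0.5), 0.05)
})
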