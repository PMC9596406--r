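test_that("detrended covariance reduces to DFA variance when y = x", {
  x <- withr::with_seed(1, rnorm(128))
  segs <- detrendedCovariance(x, x, s = 8)
  expect_true(all(segs >= 0))
  # Eq(q = 2) collapses to the squared fluctuation function
  expect_equal(qCovariance(x, x, s = 8, q = 2),
               curveValues(dfaFluctuation(x, scales = 8L))^2,
               tolerance = 1e-12)
  # bilinearity: negating one series flips every segment
  expect_equal(detrendedCovariance(x, -x, s = 8), -segs, tolerance = 1e-12)
  expect_equal(qCovariance(x, -x, s = 8, q = 1),
               -qCovariance(x, x, s = 8, q = 1), tolerance = 1e-12)
  expect_error(detrendedCovariance(x, rnorm(64), 8), "equal length")
})

test_that("DCCA quantities match the brute-force oracle", {
  for (r in 1:10) {
    x <- withr::with_seed(r, rnorm(64))
    y <- withr::with_seed(r + 50, rnorm(64))
    got <- detrendedCovariance(x, y, s = 8)
    want <- oracleSegmentCov(x, y, 8)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-10)
    expect_equal(qCovariance(x, y, s = 10, q = 1),
                 oracleQCov(x, y, 10, 1), tolerance = 1e-10)
    expect_equal(rhoQ(x, y, s = 10), oracleRho(x, y, 10), tolerance = 1e-10)
  }
})

test_that("rho(1, s) behaves like a correlation coefficient", {
  x <- withr::with_seed(3, rnorm(256))
  expect_equal(rhoQ(x, x), 1, tolerance = 1e-12)
  expect_equal(rhoQ(x, 2 * x + 3), 1, tolerance = 1e-12)
  expect_equal(rhoQ(x, -x), -1, tolerance = 1e-12)
  expect_equal(rhoQ(x, withr::with_seed(4, rnorm(256))),
               rhoQ(withr::with_seed(4, rnorm(256)), x), tolerance = 1e-12)
  expect_error(rhoQ(x, rep(1, 256)), "vanishing detrended variance")
})

test_that("mean rho(1, 10) rises with the planted coupling and tracks its sign", {
  means <- vapply(c(0, 0.3, 0.6, 0.9), function(rt) {
    mean(vapply(1:100, function(s) {
      p <- generateCoupledPair(0.8, rt, 512, seed = s + 1000 * rt)
      rhoQ(p$x, p$y, s = 10)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  # sign consistency with Pearson coupling at |rho| >= 0.3
  expect_true(all(means[-1] > 0))
  negMean <- mean(vapply(1:50, function(s) {
    p <- generateCoupledPair(0.8, -0.5, 512, seed = s)
    rhoQ(p$x, p$y, s = 10)
  }, numeric(1)))
  expect_lt(negMean, 0)
})

test_that("correlation matrices are symmetric, unit-diagonal and block-aware", {
  x <- generateROISurrogate(surrogateSpec(
    nRegions = 10, nFrames = 512, hurst = 0.8,
    blocks = rep(1:2, each = 5), blockCorrelation = c(0.9, 0.9), seed = 12))
  for (meth in c("rho_q", "pearson")) {
    dm <- correlationMatrix(x, meth)
    v <- dccValues(dm)
    expect_identical(diag(v), setNames(rep(1, 10), regionLabels(x)))
    expect_lt(max(abs(v - t(v))), 1e-12)
    within <- c(v[1:5, 1:5][upper.tri(diag(5))],
                v[6:10, 6:10][upper.tri(diag(5))])
    between <- as.vector(v[1:5, 6:10])
    expect_gt(mean(within), mean(between))
  }

  # duplicated columns correlate perfectly
  dup <- ROITimeSeries(cbind(boldValues(x)[, 1], boldValues(x)[, 1],
                             boldValues(x)[, 2]),
                       tr = 1.8, regionLabels = c("a", "b", "c"))
  expect_equal(dccValues(correlationMatrix(dup))["a", "b"], 1,
               tolerance = 1e-12)

  degen <- ROITimeSeries(cbind(rnorm(64), rep(1, 64)), tr = 1.8,
                         regionLabels = c("ok", "flat"))
  expect_error(correlationMatrix(degen), "flat")
  expect_error(correlationMatrix(degen, "pearson"), "flat")
})

test_that("matrix TSV round trip preserves values", {
  x <- generateROISurrogate(surrogateSpec(nRegions = 6, nFrames = 256,
                                          seed = 5))
  dm <- correlationMatrix(x)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeDCCMatrix(dm, f)
  back <- readDCCMatrix(f)
  expect_lt(max(abs(dccValues(back) - dccValues(dm))), 1e-9)
  expect_identical(rownames(dccValues(back)), regionLabels(x))
})

test_that("condition-difference profiles average off-diagonal contrasts", {
  a <- makeDCC(diag(3))
  expect_true(all(conditionDifferenceProfile(
    list(rest = a, task = a), "rest")$score == 0))

  # 3-region toy: region R1's |differences| are 0.2 and 0.4 -> score 0.3
  base <- diag(3)
  shift <- base
  shift[1, 2] <- shift[2, 1] <- 0.2
  shift[1, 3] <- shift[3, 1] <- 0.4
  prof <- conditionDifferenceProfile(
    list(rest = makeDCC(base), task = makeDCC(shift)), "rest")
  expect_equal(prof$score[prof$region == "R1"], 0.3, tolerance = 1e-12)

  expect_error(conditionDifferenceProfile(list(task = a), "rest"),
               "not found")
})

test_that("a planted block-coupling change surfaces in the profile", {
  mats <- function(cB) {
    lapply(1:6, function(s) correlationMatrix(generateROISurrogate(
      surrogateSpec(nRegions = 12, nFrames = 512, hurst = 0.8,
                    blocks = rep(1:2, each = 6),
                    blockCorrelation = c(0.5, cB), seed = s + 100 * cB))))
  }
  prof <- conditionDifferenceProfile(
    list(rest = averageDCC(mats(0.2)), task = averageDCC(mats(0.9))),
    "rest")
  top <- prof$region[order(prof$score, decreasing = TRUE)][1:6]
  expect_setequal(top, sprintf("ROI%03d", 7:12))
})
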