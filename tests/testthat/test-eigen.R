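# Build an ensemble directly from given unit vectors / eigenvalues.
makeEnsemble <- function(V, values, config = NULL) {
  if (is.null(config))
    config <- data.frame(subject = sprintf("s%02d", seq_along(values)),
                         tod = "morning", task = "GLO", phase = "encoding",
                         matrixId = seq_along(values))
  new("EigenEnsemble", values = values, vectors = V, config = config,
      clusterLabels = rep(NA_integer_, length(values)),
      clusterOrder = integer())
}

test_that("eigendecomposition is spectral and trace-conserving", {
  e <- eigenDecompose(diag(116))
  expect_equal(e$values, rep(1, 116))

  ones <- matrix(1, 116, 116)
  e1 <- eigenDecompose(ones)
  expect_equal(e1$values[1], 116, tolerance = 1e-10)
  expect_lt(max(abs(e1$values[-1])), 1e-8)

  # reconstruction and trace conservation for a rho matrix
  x <- generateROISurrogate(surrogateSpec(nRegions = 8, nFrames = 256,
                                          seed = 2))
  dm <- correlationMatrix(x)
  ed <- eigenDecompose(dm)
  expect_lt(max(abs(dccValues(dm) -
                    ed$vectors %*% diag(ed$values) %*% t(ed$vectors))),
            1e-8)
  expect_equal(sum(ed$values), 8, tolerance = 1e-8)

  expect_error(eigenDecompose(matrix(c(1, 2, 0, 1), 2, 2)),
               "not symmetric")
})

test_that("small-matrix spectra match the characteristic-polynomial oracle", {
  for (r in 1:10) {
    A <- withr::with_seed(r, matrix(rnorm(25), 5, 5))
    M <- (A + t(A)) / 2
    expect_equal(eigenDecompose(M)$values, oracleEigenvalues(M),
                 tolerance = 1e-8)
  }
})

test_that("large-eigenvalue selection is a strict cutoff", {
  ens <- eigenEnsemble(list(makeDCC(diag(4))),
                       data.frame(subject = "s1", tod = "m", task = "t",
                                  phase = "e"))
  expect_length(eigenvalues(selectLarge(ens, 2)), 0)

  # a near-duplicated-signal session has exactly one large eigenvalue
  v <- withr::with_seed(1, rnorm(64))
  dup <- ROITimeSeries(cbind(v, v + 1e-8 * rnorm(64), v + 1e-8 * rnorm(64)),
                       tr = 1, regionLabels = c("a", "b", "c"))
  ensDup <- eigenEnsemble(list(correlationMatrix(dup, "pearson")),
                          data.frame(subject = "s1", tod = "m",
                                     task = "t", phase = "e"))
  kept <- selectLarge(ensDup, 2)
  expect_length(eigenvalues(kept), 1L)
  expect_equal(eigenvalues(kept), 3, tolerance = 1e-4)
})

test_that("reflection distance identifies sign-flipped vectors", {
  u <- withr::with_seed(5, rnorm(10)); u <- u / sqrt(sum(u^2))
  expect_equal(reflectionDistance(u, u), 0)
  expect_equal(reflectionDistance(u, -u), 0)

  Q <- qr.Q(qr(withr::with_seed(6, matrix(rnorm(100), 10))))
  expect_equal(reflectionDistance(Q[, 1], Q[, 2]), 2, tolerance = 1e-12)

  # identity d~ = 2 - 2|u'v| against the min-of-distances form
  for (r in 1:25) {
    a <- withr::with_seed(r, rnorm(8)); a <- a / sqrt(sum(a^2))
    b <- withr::with_seed(r + 99, rnorm(8)); b <- b / sqrt(sum(b^2))
    expect_equal(reflectionDistance(a, b), 2 - 2 * abs(sum(a * b)),
                 tolerance = 1e-12)
    expect_lte(reflectionDistance(a, b), sum((a - b)^2) + 1e-15)
  }
  expect_error(reflectionDistance(1:3, 1:4), "equal length")
})

test_that("clustering recovers planted prototypes despite sign flips", {
  p <- 12
  Q <- qr.Q(qr(withr::with_seed(7, matrix(rnorm(p * p), p))))
  proto <- Q[, 1:3]
  truth <- rep(1:3, times = 10)
  signs <- withr::with_seed(8, sample(c(-1, 1), 30, replace = TRUE))
  V <- sapply(seq_along(truth), function(i) signs[i] * proto[, truth[i]])
  ens <- makeEnsemble(V, withr::with_seed(9, runif(30, 3, 6)))
  cl <- clusterEigenvectors(ens, nClusters = 3)
  lab <- clusterLabels(cl)
  # exact recovery: partition identical to the planted one
  expect_identical(length(unique(lab)), 3L)
  for (g in 1:3) expect_identical(length(unique(lab[truth == g])), 1L)

  # sign-flip invariance of the labels
  V2 <- V; V2[, c(2, 9, 17)] <- -V2[, c(2, 9, 17)]
  cl2 <- clusterEigenvectors(makeEnsemble(V2, eigenvalues(ens)), 3)
  expect_identical(clusterLabels(cl2), lab)

  expect_error(clusterEigenvectors(makeEnsemble(V[, 1:2, drop = FALSE],
                                                c(3, 4)), 3),
               "fewer than")
})

test_that("noisy prototype clustering recovers >= 95% of memberships", {
  p <- 12
  Q <- qr.Q(qr(withr::with_seed(17, matrix(rnorm(p * p), p))))
  proto <- Q[, 1:3]
  total <- 0L; correct <- 0L
  for (seed in 1:20) {
    truth <- rep(1:3, times = 8)
    V <- sapply(seq_along(truth), function(i) {
      v <- proto[, truth[i]] +
        withr::with_seed(seed * 100 + i, rnorm(p, 0, 0.05))
      sign(withr::with_seed(seed * 100 + i + 50, rnorm(1))) *
        v / sqrt(sum(v^2))
    })
    cl <- clusterEigenvectors(
      makeEnsemble(V, withr::with_seed(seed, runif(24, 3, 6))), 3)
    lab <- clusterLabels(cl)
    # best label <-> prototype matching
    for (g in 1:3) {
      tab <- table(lab[truth == g])
      correct <- correct + max(tab)
      total <- total + sum(tab)
    }
  }
  expect_gte(correct / total, 0.95)
})

test_that("deduplication keeps the largest eigenvalue per configuration", {
  u <- c(1, rep(0, 5)); w <- c(0, 1, rep(0, 4))
  V <- cbind(u, u, -u, w, w)
  cfg <- data.frame(subject = c("s1", "s1", "s2", "s1", "s2"),
                    tod = "m", task = "t", phase = "e", matrixId = 1:5)
  ens <- makeEnsemble(V, c(5, 7, 6, 4, 3), cfg)
  cl <- clusterEigenvectors(ens, nClusters = 2)
  lab <- clusterLabels(cl)
  # s1 had two entries in the u-cluster: only the lambda = 7 one survives
  expect_true(is.na(lab[1]))
  expect_false(is.na(lab[2]))
  expect_false(is.na(lab[3]))
  # every retained entry sits in exactly one ordered cluster
  expect_setequal(unique(lab[!is.na(lab)]), clusterOrder(cl))
  # u-cluster mean (6.5) beats w-cluster mean (3.5): ordered first
  expect_identical(clusterOrder(cl)[1], lab[2])
})

test_that("alignment collapses reflections and shrinks standard errors", {
  u <- withr::with_seed(20, rnorm(9)); u <- u / sqrt(sum(u^2))
  ens <- clusterEigenvectors(makeEnsemble(cbind(u, -u, u), c(3, 4, 5)), 1)
  al <- alignAndAverage(ens, clusterOrder(ens)[1])
  expect_equal(abs(al$mean), abs(u), tolerance = 1e-12)
  expect_equal(unname(al$se), rep(0, 9), tolerance = 1e-12)

  single <- clusterEigenvectors(
    makeEnsemble(cbind(u, u * 0 + c(1, rep(0, 8))), c(3, 4)), 2)
  lab1 <- clusterLabels(single)[1]
  al1 <- alignAndAverage(single, lab1)
  expect_identical(al1$n, 1L)
  expect_equal(unname(al1$se), rep(0, 9))

  # CLT: SE shrinks like 1/sqrt(members)
  ratios <- vapply(1:50, function(seed) {
    mk <- function(n, off) sapply(1:n, function(i) {
      v <- u + withr::with_seed(seed * 1000 + off + i, rnorm(9, 0, 0.1))
      v / sqrt(sum(v^2))
    })
    e1 <- clusterEigenvectors(makeEnsemble(mk(10, 0), rep(3, 10)), 1)
    e2 <- clusterEigenvectors(makeEnsemble(mk(40, 500), rep(3, 40)), 1)
    mean(alignAndAverage(e1, clusterOrder(e1)[1])$se) /
      mean(alignAndAverage(e2, clusterOrder(e2)[1])$se)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 2), 0.4)  # 2 within 20%
})

test_that("Scheffe comparisons are conservative and detect real shifts", {
  # identical groups: zero differences, never flagged
  v <- rep(c(1, 2, 3), 2)
  g <- rep(c("a", "b"), each = 3)
  tab <- scheffePairwise(c(v[1:3], v[1:3]), g)
  expect_identical(tab$diff, 0)
  expect_identical(tab$sig, "")

  # type-I calibration at the 0.05 level
  flags <- vapply(1:500, function(s) {
    x <- withr::with_seed(s, rnorm(40))
    any(scheffePairwise(x, rep(c("a", "b"), each = 20))$p < 0.05)
  }, logical(1))
  expect_lte(mean(flags), 0.05 + 2 * sqrt(0.05 * 0.95 / 500) + 0.01)

  # power: +3 shift, sigma = 1, n = 25/group flagged at 0.001
  hits <- vapply(1:100, function(s) {
    x <- withr::with_seed(s, c(rnorm(25), rnorm(25) + 3))
    scheffePairwise(x, rep(c("a", "b"), each = 25))$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  expect_warning(tab3 <- scheffePairwise(c(1, 2, 3, 4, 9),
                                         c("a", "a", "b", "b", "c")),
                 "fewer than 2")
  expect_identical(nrow(tab3), 1L)  # only the a-b contrast survives
  expect_error(expect_warning(
    scheffePairwise(c(1, 2, 3, 4), c("a", "a", "a", "b"))),
    "at least 2 groups")
})

test_that("clustered eigenvalue comparison flags a planted condition shift", {
  u <- c(1, rep(0, 4))
  n <- 50
  vals <- withr::with_seed(33, c(rnorm(n / 2, 5), rnorm(n / 2, 8)))
  cfg <- data.frame(subject = sprintf("s%02d", 1:n), tod = "m",
                    task = rep(c("rest", "GLO"), each = n / 2),
                    phase = "e", matrixId = 1:n)
  ens <- clusterEigenvectors(
    makeEnsemble(matrix(u, 5, n), vals, cfg), 1)
  cmp <- compareClusteredEigenvalues(ens, "task")
  expect_identical(nrow(cmp), 1L)
  expect_equal(abs(cmp$diff), 3, tolerance = 0.6)
  expect_identical(cmp$sig, "***")
  expect_error(compareClusteredEigenvalues(ens, "nope"), "nope")
})

test_that("the eigenvalue fence summarises per-configuration spectra", {
  ens <- eigenEnsemble(list(makeDCC(diag(4))),
                       data.frame(subject = "s1", tod = "m", task = "t",
                                  phase = "e"))
  expect_equal(eigenvalueFence(ens), 1)  # degenerate spectrum: all ones
  x <- generateROISurrogate(surrogateSpec(nRegions = 8, nFrames = 256,
                                          seed = 3))
  ens2 <- eigenEnsemble(list(correlationMatrix(x)),
                        data.frame(subject = "s1", tod = "m", task = "t",
                                   phase = "e"))
  expect_true(is.finite(eigenvalueFence(ens2)))
  expect_gt(eigenvalueFence(ens2), stats::median(eigenvalues(ens2)))
})

test_that("15 planted correlation patterns yield 10-16 large eigenvalues", {
  x <- generateROISurrogate(surrogateSpec(
    nRegions = 116, nFrames = 400, hurst = 0.8,
    blocks = rep(1:15, length.out = 116), blockCorrelation = 0.75,
    seed = 19))
  ens <- selectLarge(eigenEnsemble(
    list(correlationMatrix(x)),
    data.frame(subject = "s1", tod = "m", task = "t", phase = "e")), 2)
  cnt <- as.integer(perConfigCounts(ens))
  expect_gte(cnt, 10L); expect_lte(cnt, 16L)
})
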