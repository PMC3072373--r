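test_that("running median matches hand cases and the brute-force oracle", {
  # isolated probe keeps its raw value
  tr <- tinyTrack(5000, matrix(3.7))
  expect_equal(unname(assay(smoothRunningMedian(tr), "smoothed")[1, 1]),
               3.7)

  # constant track stays constant
  tr <- tinyTrack(seq(0, 2200, by = 220), matrix(2, 11, 1))
  expect_true(all(assay(smoothRunningMedian(tr), "smoothed") == 2))

  # five probes within one 1400 bp window: middle value is the median of all
  mids <- c(0, 220, 440, 660, 880)
  M <- c(0, 1, 5, 1, 0)
  sm <- assay(smoothRunningMedian(tinyTrack(mids, matrix(M))),
              "smoothed")[, 1]
  expect_equal(sm[3], 1)
  expect_equal(sm, bruteSmooth(mids, M, 1400))

  # randomised irregular spacings against the oracle
  set.seed(101)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    mids <- sort(sample.int(8000, n))
    M <- rnorm(n)
    w <- sample(c(300, 700, 1400, 2500), 1)
    got <- assay(smoothRunningMedian(tinyTrack(mids, matrix(M)), w),
                 "smoothed")[, 1]
    expect_equal(got, bruteSmooth(mids, M, w))
  }
})

test_that("smoothing is per chromosome and preserves probe order", {
  gr <- GRanges(rep(c("chr1", "chr2"), each = 3),
                IRanges(rep(c(0, 220, 440), 2), width = 1))
  M <- matrix(c(0, 0, 0, 10, 10, 10), ncol = 1)
  tr <- ProbeTrack(gr, M, "Me", 1)
  sm <- assay(smoothRunningMedian(tr), "smoothed")[, 1]
  expect_equal(sm, c(0, 0, 0, 10, 10, 10))  # windows never cross chroms
})

test_that("percentile threshold uses linear interpolation per sample", {
  expect_equal(computeThreshold(1:10, 80), 8.2)
  expect_equal(computeThreshold(rep(3.3, 50), 80), 3.3)
  expect_equal(computeThreshold(c(4, 1, 9), 100), 9)
  expect_error(computeThreshold(numeric(0)), "no finite values")
  set.seed(2)
  for (i in 1:25) {
    x <- rnorm(sample(2:60, 1))
    p <- runif(1, 1, 100)
    expect_equal(computeThreshold(x, p), brutePercentile(x, p))
  }
})

test_that("cluster chaining respects the midpoint distance cutoff", {
  pr <- GRanges("chr1", IRanges(c(1000, 1400), width = 1))
  one <- callClusters(pr, c(5, 5), threshold = 1, maxGapBp = 700)
  expect_equal(length(one), 1)
  expect_equal(mcols(one)$n_probes, 2L)

  pr2 <- GRanges("chr1", IRanges(c(1000, 1800), width = 1))
  two <- callClusters(pr2, c(5, 5), threshold = 1, maxGapBp = 700)
  expect_equal(length(two), 2)

  none <- callClusters(pr, c(0.1, 0.2), threshold = 1, maxGapBp = 700)
  expect_equal(length(none), 0)
})

test_that("below-threshold probes inside a span do not break the chain", {
  mids <- c(1000, 1300, 1600)
  pr <- GRanges("chr1", IRanges(mids, width = 1))
  cl <- callClusters(pr, c(5, 0, 5), threshold = 1, maxGapBp = 700)
  expect_equal(length(cl), 1)
  expect_equal(start(cl), 1000)
  expect_equal(end(cl), 1600)
  expect_equal(mcols(cl)$n_probes, 2L)   # only above-threshold probes count
  expect_equal(mcols(cl)$mean_smoothed_M, 5)
})

test_that("~20% of probes sit at or above the 80th percentile threshold", {
  set.seed(31)
  x <- rnorm(5000)                       # continuous, tie-free
  thr <- computeThreshold(x, 80)
  expect_gte(mean(x >= thr), 0.18)
  expect_lte(mean(x >= thr), 0.22)
})

test_that("domain calling is idempotent and monotone in the percentile", {
  sim <- simulateTilingData(
    simulationConfig(nChromosomes = 1, chromLengthBp = 2e5,
                     nGenes = 30, seed = 13))
  a <- callDomains(sim$probes)
  b <- callDomains(sim$probes)
  expect_identical(as.list(clusters(a)), as.list(clusters(b)))

  bp <- vapply(c(70, 80, 90, 95), function(p) {
    cl <- clusters(callDomains(sim$probes, thresholdPercentile = p))
    sum(vapply(cl, function(g) sum(width(g)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(bp) <= 0))
})

test_that("clusters of one track are non-overlapping and sorted", {
  sim <- simulateTilingData(
    simulationConfig(nChromosomes = 2, chromLengthBp = 1e5,
                     nGenes = 20, seed = 17))
  for (cl in as.list(clusters(callDomains(sim$probes)))) {
    expect_true(all(mcols(cl)$n_probes >= 1))
    expect_true(all(end(cl) > start(cl)))
    if (length(cl) > 1) {
      expect_identical(cl, sort(cl))
      expect_equal(sum(countOverlaps(cl, cl) > 1), 0)
    }
  }
})
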