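# closed-form enumeration of the upper-tail hypergeometric probability,
# independent of phyper
enumHyper <- function(k, n, K, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

test_that("fold enrichment follows the frequency-ratio definition", {
  bg <- sprintf("g%04d", 1:1000)
  cat100 <- bg[1:100]
  set <- c(bg[1:20], bg[500:529])           # 50 genes, 20 in category
  fe <- foldEnrichment(set, cat100, bg)
  expect_equal(fe$fold, 4.0)
  expect_equal(fe$observed, 20)
  expect_equal(fe$expected, 5)

  expect_equal(foldEnrichment(bg, cat100, bg)$fold, 1.0)
  expect_equal(foldEnrichment(bg[900:950], cat100, bg)$fold, 0.0)
  expect_true(is.na(foldEnrichment(character(0), cat100, bg)$fold))
  expect_true(is.na(foldEnrichment(set, character(0), bg)$fold))
  expect_error(foldEnrichment("not_there", cat100, bg), "subset")
})

test_that("complementary categories average to fold 1", {
  bg <- sprintf("g%04d", 1:500)
  cat1 <- bg[1:150]
  cat2 <- setdiff(bg, cat1)
  set <- bg[c(1:90, 200:259)]
  f1 <- foldEnrichment(set, cat1, bg)
  f2 <- foldEnrichment(set, cat2, bg)
  expect_equal(f1$backgroundFrequency * f1$fold +
                 f2$backgroundFrequency * f2$fold, 1)
})

test_that("family chi-square matches the goodness-of-fit oracle", {
  cases <- list(c(23, 34, 27600, 100000),   # strongly enriched family
                c(1, 23, 27600, 100000),    # strongly depleted family
                c(5, 8, 5000, 8000),
                c(12, 40, 3000, 10000),
                c(2, 50, 500, 20000))
  for (cs in cases) {
    got <- chi2FamilyTest(cs[1], cs[2], cs[3], cs[4])
    p0 <- cs[3] / cs[4]
    oracle <- suppressWarnings(
      chisq.test(c(cs[1], cs[2] - cs[1]), p = c(p0, 1 - p0)))
    expect_equal(got$statistic, unname(oracle$statistic))
    expect_equal(got$p, oracle$p.value)
  }
})

test_that("chi-square edge behaviour: null split, scaling, Yates, zero expectation", {
  atNull <- chi2FamilyTest(10, 40, 2500, 10000)  # exactly genome frequency
  expect_equal(atNull$statistic, 0)
  expect_equal(atNull$p, 1)

  small <- chi2FamilyTest(23, 34, 276, 1000)
  big <- chi2FamilyTest(46, 68, 552, 2000)       # same proportions, 2n
  expect_gt(big$statistic, small$statistic)
  expect_lt(big$p, small$p)

  expect_lt(chi2FamilyTest(23, 34, 276, 1000, yates = TRUE)$statistic,
            small$statistic)
  expect_error(chi2FamilyTest(0, 10, 0, 100), "hypergeometric")
})

test_that("hypergeometric upper tail agrees with exhaustive enumeration", {
  expect_equal(hypergeometricTermTest(5, 5, 5, 10), 1 / 252)
  expect_equal(hypergeometricTermTest(0, 5, 5, 10), 1)
  for (N in c(8, 12, 20)) {
    for (K in c(2, floor(N / 2))) {
      for (n in c(3, floor(N / 2))) {
        for (k in 0:min(n, K)) {
          expect_equal(hypergeometricTermTest(k, n, K, N),
                       enumHyper(k, n, K, N), tolerance = 1e-12)
        }
      }
    }
  }
  expect_error(hypergeometricTermTest(6, 5, 5, 10), "inconsistent")
})

test_that("family summaries reproduce their own counts at one decimal", {
  fam <- list(A = sprintf("a%02d", 1:34), B = sprintf("b%02d", 1:23),
              C = sprintf("c%02d", 1:7))
  union <- c(fam$A[1:23], fam$B[1])
  res <- familyTargetSummary(fam, union)
  expect_equal(res$percent_target, c(67.6, 4.3, 0.0))
  expect_equal(res$percent_target,
               roundHalfUp(100 * res$n_target / res$n_total, 1))
  expect_error(familyTargetSummary(list(A = character(0)), union),
               "empty family")

  cls <- setNames(rep(c("dM_plus", "M_eq_L"), c(3, 2)),
                  c(fam$A[1:3], fam$A[4:5]))
  withCls <- familyTargetSummary(fam, union, classes = cls)
  expect_equal(withCls$n_dM_plus, c(3L, 0L, 0L))
  expect_equal(withCls$n_M_eq_L, c(2L, 0L, 0L))
})

test_that("small-RNA coupling totals are sums of rows with recomputed percents", {
  loci <- list(f1 = c("l1", "l2"), f2 = c("l3", "l4", "l5"))
  map <- list(f1 = c("t1", "t2"), f2 = "t3")
  union <- c("l1", "l2", "l3", "t1")
  cp <- smallRNACoupling(loci, map, union)
  expect_equal(cp$rows$loci_percent, c(100, 33))
  expect_equal(cp$totals$loci_total, 5)
  expect_equal(cp$totals$loci_targeted, 3)
  expect_equal(cp$totals$genes_percent, roundHalfUp(100 * 1 / 3, 0))

  reg <- GRanges("chr1", IRanges(1:4 * 100, width = 10))
  names(reg) <- c("l1", "l2", "l3", "l4")
  expect_error(smallRNACoupling(loci, map, union, registry = reg),
               "not in annotation registry")

  empty <- smallRNACoupling(list(), list(), union)
  expect_equal(empty$totals$loci_total, 0)
  expect_true(is.na(empty$totals$loci_percent))
})

test_that("a bin equal to the whole universe gives fold 1 everywhere", {
  ids <- sprintf("g%03d", 1:200)
  meth <- setNames(rep(c("dM_plus", "non_target"), c(50, 150)), ids)
  expr <- setNames(rep("all", 200), ids)
  ct <- crosstabExpressionMethylation(meth, expr)
  row <- ct[ct$direction == "meth_within_expr", ]
  expect_true(all(row$fold == 1))
})

test_that("uniform random labels produce no spurious enrichment", {
  set.seed(123)
  ids <- sprintf("g%04d", 1:5000)
  meth <- setNames(sample(c("dM_plus", "dL_plus", "M_eq_L",
                            "non_target"), 5000, replace = TRUE), ids)
  expr <- setNames(sample(c("dXM_ge2", "dXL_le2", "X_M_eq_L",
                            "not_expressed"), 5000, replace = TRUE), ids)
  ct <- crosstabExpressionMethylation(meth, expr)
  expect_true(all(ct$fold >= 0.8 & ct$fold <= 1.25))
  expect_false(any(ct$p <= 0.05 / nrow(ct), na.rm = TRUE))
  expect_error(crosstabExpressionMethylation(
    setNames("a", "x1"), setNames("b", "y1")), "share no genes")
})
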