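test_that("methylation rules reproduce the worked examples", {
  ms <- scoresFromReps(
    rbind(c(50, 54),    # dM+: leaf zero, diff 52, t = 26
          c(30, 30),    # M=L: identical in both tissues
          c(38, 42)),   # target_other: ratio 1.6, diff 15
    rbind(c(0, 0),
          c(30, 30),
          c(24, 26)))
  mc <- classifyMethylation(ms)
  expect_equal(mc$label, c("dM_plus", "M_eq_L", "target_other"))

  # the dM+ t-test p equals the standard equal-variance t-test
  oracle <- t.test(c(50, 54), c(0, 0), var.equal = TRUE)$p.value
  expect_equal(mc$p[1], oracle)
  expect_lte(mc$p[1], 0.05)
  expect_equal(mc$diff[1], 52)
  expect_equal(mc$diff[3], 15)
  expect_equal(mc$ratio[3], 40 / 25)
})

test_that("degenerate zero-variance replicates follow the magnitude rule", {
  ms <- scoresFromReps(rbind(c(40, 40), c(6, 6)),
                       rbind(c(0, 0), c(0, 0)))
  mc <- classifyMethylation(ms)
  expect_true(is.na(mc$p[1]))
  expect_equal(mc$label[1], "dM_plus")        # |diff| = 40 >= 10
  expect_equal(mc$label[2], "target_other")   # |diff| = 6 < 10
})

test_that("labels partition the annotations and non-targets are separated", {
  set.seed(77)
  n <- 120
  repMe <- matrix(round(runif(2 * n, 0, 60)), ncol = 2)
  repLe <- matrix(round(runif(2 * n, 0, 60)), ncol = 2)
  mc <- classifyMethylation(scoresFromReps(repMe, repLe))
  expect_equal(nrow(mc), n)
  expect_equal(sum(table(mc$label)), n)
  expect_setequal(setdiff(unique(mc$label), c(
    "non_target", "dM_plus", "dL_plus", "M_eq_L", "target_other")),
    character(0))
  nt <- mc$label == "non_target"
  tgt <- apply(repMe > 0, 1, all) | apply(repLe > 0, 1, all)
  expect_equal(nt, !tgt)
})

test_that("swapping the tissues mirrors the differential labels", {
  set.seed(88)
  n <- 150
  repMe <- matrix(round(runif(2 * n, 0, 60)), ncol = 2)
  repLe <- matrix(round(runif(2 * n, 0, 60)), ncol = 2)
  fwd <- classifyMethylation(scoresFromReps(repMe, repLe))
  rev <- classifyMethylation(scoresFromReps(repLe, repMe))
  map <- c(dM_plus = "dL_plus", dL_plus = "dM_plus", M_eq_L = "M_eq_L",
           non_target = "non_target", target_other = "target_other")
  expect_equal(unname(map[fwd$label]), rev$label)
})

test_that("expression bins follow the delta-log2 and significance rules", {
  expr <- data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    log2_Me_rep1 = c(10.0, 9.0, 9.75, 7.0, NA),
    log2_Me_rep2 = c(10.1, 9.0, 9.85, 7.1, 9),
    log2_Le_rep1 = c(7.0, 9.0, 8.30, 10.0, 9),
    log2_Le_rep2 = c(7.1, 9.0, 8.30, 10.1, 9))
  eb <- classifyExpression(expr)
  expect_equal(eb$bin,
               c("dXM_ge2", "X_M_eq_L", "dXM_1_2", "dXL_le2",
                 "not_expressed"))
  expect_equal(eb$dlog2[1], 3.0)
  expect_equal(eb$p[1], t.test(c(10, 10.1), c(7, 7.1),
                               var.equal = TRUE)$p.value)
  expect_equal(eb$dlog2[3], 1.5)

  # below the detection threshold in both tissues -> not expressed
  off <- data.frame(gene_id = "z", log2_Me_rep1 = 5, log2_Me_rep2 = 5.1,
                    log2_Le_rep1 = 5, log2_Le_rep2 = 5.2)
  expect_equal(classifyExpression(off)$bin, "not_expressed")
})

test_that("expression binning mirrors under tissue swap", {
  set.seed(99)
  n <- 80
  expr <- data.frame(gene_id = sprintf("g%02d", 1:n),
                     log2_Me_rep1 = runif(n, 6, 12),
                     log2_Me_rep2 = runif(n, 6, 12),
                     log2_Le_rep1 = runif(n, 6, 12),
                     log2_Le_rep2 = runif(n, 6, 12))
  swapped <- expr
  names(swapped) <- sub("_Le_", "_XX_", names(swapped))
  names(swapped) <- sub("_Me_", "_Le_", names(swapped))
  names(swapped) <- sub("_XX_", "_Me_", names(swapped))
  fwd <- classifyExpression(expr)
  rev <- classifyExpression(swapped)
  map <- c(dXM_ge2 = "dXL_le2", dXL_le2 = "dXM_ge2",
           dXM_1_2 = "dXL_1_2", dXL_1_2 = "dXM_1_2",
           X_M_eq_L = "X_M_eq_L", other = "other",
           not_expressed = "not_expressed")
  expect_equal(unname(map[fwd$bin]), rev$bin)
})

test_that("Spearman concordance handles identity, reversal and noise", {
  x <- 1:100
  expect_equal(replicateConcordance(cbind(a = x, b = x))["a", "b"], 1)
  expect_equal(replicateConcordance(cbind(a = x, b = rev(x)))["a", "b"],
               -1)
  set.seed(5)
  r <- replicateConcordance(matrix(rnorm(2000), ncol = 2))
  expect_lt(abs(r[1, 2]), 0.1)
  rc <- replicateConcordance(cbind(a = x, b = rep(1, 100)))
  expect_true(is.na(rc["a", "b"]))
})

test_that("planted truth is recovered by the classification rules", {
  fx <- .fullSim()
  tr <- fx$sim$truth$class[match(fx$meth$id, fx$sim$truth$gene_id)]
  expect_gte(mean(fx$meth$label[tr == "meristem_only"] == "dM_plus"), 0.9)
  expect_gte(mean(fx$meth$label[tr == "leaf_only"] == "dL_plus"), 0.9)
  expect_lte(mean(fx$meth$label[tr == "shared_methylated"] %in%
                    c("dM_plus", "dL_plus")), 0.05)
})
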