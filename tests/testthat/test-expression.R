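# ddCt normalization, fold changes, ANOVA and profile clustering.

test_that("dCt is the gene Ct minus the mean reference Ct per sample", {
  rec <- data.frame(
    tissue = "leaf", treatment = "control", bio_rep = 1,
    tech_rep = rep(1, 3),
    gene = c("G1", "R1", "R2"),
    ct = c(21, 20, 22))
  d <- normalizeCt(rec, c("R1", "R2"))
  expect_equal(d$delta_ct, 0)   # 21 - mean(20, 22)
  rec2 <- rec[rec$gene != "R2", ]
  expect_error(normalizeCt(rec2, c("R1", "R2")), "R2")
})

test_that("technical replicates are averaged before normalization", {
  rec <- data.frame(
    tissue = "leaf", treatment = "control", bio_rep = 1,
    tech_rep = c(1, 2, 1),
    gene = c("G1", "G1", "R1"),
    ct = c(20, 22, 20))
  d <- normalizeCt(rec, "R1")
  expect_equal(d$delta_ct, 1)   # mean(20, 22) - 20
})

test_that("ddCt fold-change identities hold", {
  expect_equal(ddctFoldChange(c(1, 1), c(1, 1)), 1)
  expect_equal(ddctFoldChange(0, 1), 2)    # ddCt = -1
  expect_equal(ddctFoldChange(3, 1), 0.25) # ddCt = 2
  expect_error(ddctFoldChange(numeric(0), 1), "treated")
  expect_error(ddctFoldChange(1, numeric(0)), "control")
})

test_that("one-way ANOVA matches the classical decomposition", {
  g <- list(c(1, 2, 3), c(2, 3, 4), c(5, 6, 7))
  r <- oneWayAnova(g)
  ref <- stats::oneway.test(
    y ~ grp, data = data.frame(y = unlist(g),
                               grp = factor(rep(1:3, each = 3))),
    var.equal = TRUE)
  expect_equal(r$F, unname(ref$statistic))
  expect_equal(r$p, ref$p.value)
  # two groups: F equals the squared pooled-variance t statistic
  g2 <- list(c(1, 2, 3, 2), c(4, 3, 5, 4))
  r2 <- oneWayAnova(g2)
  tt <- stats::t.test(g2[[1]], g2[[2]], var.equal = TRUE)
  expect_equal(r2$F, unname(tt$statistic)^2)
  # degenerate inputs
  expect_equal(oneWayAnova(list(c(1, 1), c(1, 1))), list(F = 0, p = 1))
  expect_error(oneWayAnova(list(1:3)), "2 groups")
})

test_that("ANOVA type-I error is calibrated near the nominal level", {
  reject <- withr::with_seed(61, {
    vapply(seq_len(1000), function(i) {
      g <- split(stats::rnorm(15), rep(1:5, each = 3))
      oneWayAnova(g)$p < 0.05
    }, logical(1))
  })
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("significance requires both the fold threshold and the p-value", {
  res <- data.frame(fold_change = c(1.9, 4, 4, 0.4),
                    p_value = c(0.001, 0.2, 0.01, 0.01))
  f <- flagSignificant(res)
  expect_equal(f$significant, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(f$direction, c("up", "up", "up", "down"))
})

test_that("reference-gene fold change stays near 1 under default noise", {
  folds <- withr::with_seed(62, {
    vapply(1:40, function(i) {
      cfg <- qpcrSimConfig(c("T1", "CTRLGENE"),
                           seed = sample.int(1e6, 1))
      er <- expressionAnalysis(simulateQpcr(cfg), cfg$referenceGenes)
      er$fold_change[er$gene == "CTRLGENE"]
    }, numeric(8))
  })
  expect_gte(mean(folds >= 0.8 & folds <= 1.25), 0.95)
})

test_that("clustering recovers planted orthogonal response groups", {
  mat <- rbind(up1 = c(2, 2, 0, 0), up2 = c(2.1, 1.9, 0.1, 0),
               dn1 = c(-2, -2, 2, 2), dn2 = c(-1.9, -2.2, 2.1, 1.8))
  cl <- clusterProfiles(mat, k = 2)
  expect_equal(cl$clusters[["up1"]], cl$clusters[["up2"]])
  expect_equal(cl$clusters[["dn1"]], cl$clusters[["dn2"]])
  expect_false(cl$clusters[["up1"]] == cl$clusters[["dn1"]])
})

test_that("identical profiles merge at distance 0 and negated ones at 2", {
  mat <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(-1, -2, -3))
  cl <- clusterProfiles(mat, k = 2)
  expect_equal(cl$clusters[["a"]], cl$clusters[["b"]])
  h <- cl$hclust
  expect_equal(min(h$height), 0)
  expect_equal(max(h$height), 2, tolerance = 1e-9)
})

test_that("constant profiles are flagged and placed by the zero-distance convention", {
  mat <- rbind(a = c(1, 1, 1), b = c(1, 1, 1), c = c(0, 5, 2))
  cl <- clusterProfiles(mat, k = 2)
  expect_setequal(cl$flagged, c("a", "b"))
  expect_equal(cl$clusters[["a"]], cl$clusters[["b"]])
  expect_false(cl$clusters[["a"]] == cl$clusters[["c"]])
})
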