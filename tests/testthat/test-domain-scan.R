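# PWM repeat models, conservation statistics and protein scanning.

test_that("identical rows with zero pseudocount give frequency 1 columns", {
  block <- rep("MKWVDE", 10)
  m <- buildRepeatModel(block, pseudocount = 0)
  expect_equal(m@width, 6L)
  expect_equal(unname(m@freq["M", 1]), 1)
  expect_equal(unname(m@freq["W", 3]), 1)
  expect_equal(colSums(m@freq), rep(1, 6), ignore_attr = TRUE)
  expect_equal(m@trpColumns, 3L)
})

test_that("empty alignment blocks are rejected", {
  expect_error(buildRepeatModel(character(0)), "empty")
})

test_that("column information is log2(20) for invariant columns and 0 for uniform", {
  block <- rep("A", 5)
  expect_equal(unname(columnInformation(block)), log2(20))
  uni <- vapply(c("A","C","D","E","F","G","H","I","K","L",
                  "M","N","P","Q","R","S","T","V","W","Y"),
                identity, character(1))
  expect_equal(unname(columnInformation(uni)), 0)
  expect_error(columnInformation(rep("-", 4)), "gaps")
})

test_that("information content is bounded in [0, log2(20)]", {
  sim <- sharedSim()
  fam <- geneOrder(sim)$gene_id[geneOrder(sim)$family]
  prot <- as.character(simProteins(sim))[fam]
  bits <- columnInformation(substr(prot, 11, 59))
  expect_true(all(bits >= 0 & bits <= log2(20) + 1e-12))
})

test_that("conserved columns follow the threshold semantics", {
  block <- c("MKWVDE", "MKWVDE", "MKWVDE")
  expect_equal(conservedColumns(block), 1:6)
  block2 <- c("MKWVDE", "MKWVDE", "MAWVDE")   # column 2 broken by one row
  expect_equal(conservedColumns(block2, threshold = 1), c(1, 3, 4, 5, 6))
  expect_equal(conservedColumns(block2, threshold = 0.6), 1:6)
  expect_error(conservedColumns(block, threshold = 0), "0, 1")
})

test_that("scan localizes an embedded consensus exactly and is shift-covariant", {
  cons <- defaultRepeatConsensus()[["R2"]]
  m <- buildRepeatModel(rep(cons, 3))
  withr::with_seed(31, {
    pad1 <- paste(sample(.mybkit_aa(), 17, replace = TRUE), collapse = "")
    pad2 <- paste(sample(.mybkit_aa(), 30, replace = TRUE), collapse = "")
  })
  prot <- paste0(pad1, cons, pad2)
  hits <- scanProtein(prot, m)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 18)
  expect_equal(hits$end, 18 + 48)
  expect_true(hits$trp_ok)
  # prepending k residues shifts coordinates by exactly k
  shifted <- scanProtein(paste0("AAAAA", prot), m)
  expect_equal(shifted$start, hits$start + 5)
})

test_that("an R2-linker-R3 protein yields exactly two ordered hits", {
  cons <- defaultRepeatConsensus()
  m2 <- buildRepeatModel(rep(cons[["R2"]], 3))
  m3 <- buildRepeatModel(rep(cons[["R3"]], 3))
  prot <- paste0("M", cons[["R2"]], "GSSGS", cons[["R3"]], "DDEE")
  cl <- classifyRepeats(c(x = prot), m2, m3)
  expect_equal(cl$classification$label, "R2R3")
  expect_equal(nrow(cl$hits), 2)
  expect_equal(cl$hits$repeat_type, c("R2", "R3"))
})

test_that("random proteins almost never produce hits at the default threshold", {
  sim <- sharedSim()
  models <- repeatModelsFromSim(sim)
  withr::with_seed(32, {
    nHit <- 0
    for (i in 1:100) {
      s <- paste(sample(.mybkit_aa(), 300, replace = TRUE), collapse = "")
      nHit <- nHit + (nrow(scanProtein(s, models$R2)) > 0)
    }
    expect_lte(nHit, 1)
  })
})

test_that("repeat detection on the simulated family is sensitive and specific", {
  sim <- sharedSim()
  go <- geneOrder(sim)
  models <- repeatModelsFromSim(sim)
  cl <- classifyRepeats(simProteins(sim), models$R2, models$R3)
  fam <- go$gene_id[go$family]
  lab <- cl$classification
  sens <- mean(lab$label[match(fam, lab$protein_id)] == "R2R3")
  expect_gte(sens, 0.95)
  # false hits: repeat hits on background proteins
  fp <- sum(!cl$hits$protein_id %in% fam)
  expect_lte(fp / max(1, nrow(cl$hits)), 0.05)
})

test_that("ORF filtering drops proteins without Met start or with internal stops", {
  cons <- defaultRepeatConsensus()
  m2 <- buildRepeatModel(rep(cons[["R2"]], 3))
  m3 <- buildRepeatModel(rep(cons[["R3"]], 3))
  prots <- c(noMet = paste0("K", cons[["R2"]], "GSSGS", cons[["R3"]]),
             stop = paste0("M", cons[["R2"]], "G*SGS", cons[["R3"]]),
             ok = paste0("M", cons[["R2"]], "GSSGS", cons[["R3"]]))
  cl <- classifyRepeats(prots, m2, m3)
  expect_equal(cl$classification$excluded, c(TRUE, TRUE, FALSE))
  expect_equal(unique(cl$classification$reason[1:2]), "incomplete ORF")
  expect_equal(cl$r2r3, "ok")
})

test_that("three ordered repeats are labelled 3R and excluded from the R2R3 set", {
  cons <- defaultRepeatConsensus()
  m2 <- buildRepeatModel(rep(cons[["R2"]], 3))
  m3 <- buildRepeatModel(rep(cons[["R3"]], 3))
  prot <- paste0("M", cons[["R2"]], "GSSGS", cons[["R3"]], "GSSGS",
                 cons[["R3"]])
  cl <- classifyRepeats(c(x = prot), m2, m3)
  expect_equal(cl$classification$label, "3R")
  expect_equal(length(cl$r2r3), 0)
})
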