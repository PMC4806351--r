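# NG86 site counting, pathway averaging and Jukes-Cantor correction.

test_that("per-codon synonymous site counts match enumeration of all 9 mutants", {
  expect_equal(synonymousSites("TTT"), 1 / 3)
  expect_equal(synonymousSites("ATG"), 0)
  sense <- names(Biostrings::GENETIC_CODE)[
    as.character(Biostrings::GENETIC_CODE) != "*"]
  oracle <- vapply(sense, oracleSynSites, numeric(1))
  expect_equal(synonymousSites(sense), unname(oracle), tolerance = 1e-12)
})

test_that("identical sequences give Ka = Ks = 0 and exact site conservation", {
  withr::with_seed(10, {
    codons <- randomSenseCodons(50)
    r <- ng86(codons, codons)
    expect_equal(r$ka, 0)
    expect_equal(r$ks, 0)
    expect_equal(r$sSites + r$nSites, 3 * 50)
    expect_false(r$saturated)
  })
})

test_that("pathway-averaged difference counts equal the brute-force enumerator", {
  withr::with_seed(11, {
    for (rep in 1:60) {
      a <- randomSenseCodons(8)
      b <- randomSenseCodons(8)
      r <- ng86(a, b)
      o <- oracleNg86(a, b)
      expect_equal(r$sd, o$sd, tolerance = 1e-9)
      expect_equal(r$nd, o$nd, tolerance = 1e-9)
      expect_equal(r$sSites, o$S, tolerance = 1e-9)
    }
  })
})

test_that("ng86 is symmetric in its arguments", {
  withr::with_seed(12, {
    a <- randomSenseCodons(40)
    b <- vapply(a, function(cd) {
      if (stats::runif(1) < 0.3) randomSenseCodons(1) else cd
    }, character(1))
    r1 <- ng86(a, b); r2 <- ng86(b, a)
    expect_equal(r1$sd, r2$sd)
    expect_equal(r1$nd, r2$nd)
    expect_equal(r1$ks, r2$ks)
    expect_equal(r1$ka, r2$ka)
  })
})

test_that("site conservation S + N = 3 x codons holds for arbitrary codon sets", {
  withr::with_seed(13, {
    for (rep in 1:10) {
      n <- sample(5:60, 1)
      a <- randomSenseCodons(n); b <- randomSenseCodons(n)
      r <- ng86(a, b)
      expect_equal(r$sSites + r$nSites, 3 * n, tolerance = 1e-12)
    }
  })
})

test_that("saturated comparisons are flagged rather than numeric", {
  # maximally different third positions cannot saturate, so construct a
  # pathological pair with p_N beyond the Jukes-Cantor bound
  a <- rep("AAA", 20)  # Lys
  b <- rep("TGC", 20)  # Cys, 3 differences each
  r <- ng86(a, b)
  expect_true(r$saturated)
  expect_true(is.na(r$ka) || is.na(r$ks))
})

test_that("codon alignment expands protein gaps to codon gaps and round-trips", {
  cdsA <- "ATGAAATTTGGG"          # M K F G
  cdsB <- "ATGTTTGGG"             # M F G
  aln <- globalAlign(translateCds(cdsA), translateCds(cdsB))
  ca <- codonAlign(aln$alignedA, aln$alignedB, cdsA, cdsB)
  expect_equal(length(ca$codonsA), length(ca$codonsB))
  # degapping the full expansion recovers both CDS
  expect_equal(paste(ca$alignmentA[ca$alignmentA != "---"], collapse = ""),
               cdsA)
  expect_equal(paste(ca$alignmentB[ca$alignmentB != "---"], collapse = ""),
               cdsB)
  # exactly one protein gap => exactly one dropped codon column
  expect_equal(ca$nDropped, 1)
})

test_that("codon alignment rejects translation mismatches naming the residue", {
  expect_error(codonAlign("MK", "MK", "ATGAAA", "ATGCCC"),
               "residue 2")
})

test_that("molecular-clock dating reproduces T = Ks / 2 lambda in Mya", {
  expect_equal(dateDuplication(0.19), 6.33, tolerance = 0.005)
  expect_equal(dateDuplication(0), 0)
  expect_equal(dateDuplication(0.30), 10.00, tolerance = 1e-9)
  # linear in Ks, inverse-linear in lambda
  expect_equal(dateDuplication(0.4), 2 * dateDuplication(0.2))
  expect_equal(dateDuplication(0.3, lambda = 3e-8),
               dateDuplication(0.3) / 2)
  expect_error(dateDuplication(0.1, lambda = -1), "positive")
})

test_that("selection labels split at the 0.5 and 1 cut-offs", {
  expect_equal(selectionLabel(c(0.2, 0.5, 0.9, 1, 1.2, NA)),
               c("purifying", "candidate_positive", "candidate_positive",
                 "candidate_positive", "positive", NA))
})
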