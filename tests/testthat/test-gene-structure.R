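# GFF3 parsing, intron statistics, pattern conservation.

makeGff <- function(exonsByGene, strand = "+") {
  # exonsByGene: named list of data.frame(start, end); single chromosome
  feats <- list()
  for (g in names(exonsByGene)) {
    ex <- exonsByGene[[g]]
    feats[[g]] <- data.frame(
      type = c("gene", "mRNA", rep("exon", nrow(ex)), rep("CDS", nrow(ex))),
      start = c(min(ex$start), min(ex$start), ex$start, ex$start),
      end = c(max(ex$end), max(ex$end), ex$end, ex$end),
      ID = c(g, paste0(g, ".1"), rep(NA, 2 * nrow(ex))),
      Parent = c(NA, g, rep(paste0(g, ".1"), 2 * nrow(ex))))
  }
  df <- do.call(rbind, feats)
  GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(df$start, df$end), strand = strand,
    type = df$type, ID = df$ID,
    Parent = IRanges::CharacterList(lapply(df$Parent, function(p)
      if (is.na(p)) character(0) else p)))
}

test_that("single-exon genes have no introns", {
  gr <- makeGff(list(g1 = data.frame(start = 1, end = 300)))
  m <- parseGeneModels(gr)
  expect_equal(nrow(m$g1$introns), 0)
  expect_equal(m$g1$phases, integer(0))
})

test_that("introns are the exact gaps between exons with CDS-relative phases", {
  gr <- makeGff(list(g1 = data.frame(start = c(1, 201, 401),
                                     end = c(100, 300, 500))))
  m <- parseGeneModels(gr)$g1
  expect_equal(m$introns$start, c(101, 301))
  expect_equal(m$introns$end, c(200, 400))
  expect_equal(m$intron_cds_offsets, c(100, 200))
  expect_equal(m$phases, c(100 %% 3, 200 %% 3))
  expect_false(m$cds_incomplete) # 100+100+100 = 300 nt, divisible by 3
})

test_that("minus-strand exons are reported in transcription order", {
  gr <- makeGff(list(g1 = data.frame(start = c(1, 201), end = c(100, 320))),
                strand = "-")
  m <- parseGeneModels(gr)$g1
  expect_equal(m$exons$start, c(201, 1))       # 3'-most genomic exon first
  expect_equal(m$intron_cds_offsets, 120)      # first transcribed exon: 120 nt
})

test_that("overlapping exons and orphan genes are rejected by name", {
  bad <- makeGff(list(gX = data.frame(start = c(1, 50), end = c(100, 200))))
  expect_error(parseGeneModels(bad), "gX")
  orphan <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1, 10), strand = "+", type = "gene",
    ID = "lonely", Parent = IRanges::CharacterList(list(character(0))))
  expect_error(parseGeneModels(orphan), "lonely")
})

test_that("parsed simulated gene models match the intron template", {
  sim <- sharedSim()
  models <- parseGeneModels(sim@gff)
  fam <- geneOrder(sim)$gene_id[geneOrder(sim)$family]
  for (g in fam) {
    expect_equal(models[[g]]$intron_cds_offsets,
                 sim@config@intronTemplate)
    expect_false(models[[g]]$cds_incomplete)
  }
  # intron count = exon count - 1 for every model
  it <- intronTable(models)
  expect_true(all(it$n_introns == it$n_exons - 1))
})

test_that("structure summary reports the intron-count distribution", {
  ex <- list(
    a = data.frame(start = 1, end = 300),
    b = data.frame(start = c(1, 201), end = c(100, 400)),
    c = data.frame(start = c(1, 201), end = c(100, 400)),
    d = data.frame(start = c(1, 201), end = c(100, 400)),
    e = data.frame(start = c(1, 201, 601), end = c(100, 400, 700)))
  m <- parseGeneModels(makeGff(ex))
  s <- structureSummary(m)
  one <- s$byIntronCount[s$byIntronCount$n_introns == 1, ]
  expect_equal(one$n_genes, 3)
  expect_equal(one$fraction, 0.6)
  expect_null(s$bySubgroup)
  expect_error(structureSummary(list()), "no gene models")
})

test_that("pattern conservation scores modal-pattern sharing per subgroup", {
  ex <- list(
    a = data.frame(start = c(1, 201), end = c(100, 400)),
    b = data.frame(start = c(1, 201), end = c(100, 400)),
    c = data.frame(start = c(1, 201), end = c(100, 400)),
    d = data.frame(start = 1, end = 300),
    e = data.frame(start = 1, end = 300))
  m <- parseGeneModels(makeGff(ex))
  sg <- data.frame(taxon = c("a", "b", "c", "d", "e"),
                   subgroup = c("C1", "C1", "C1", "C1", "C2"))
  pc <- patternConservation(m, sg)
  expect_equal(pc$conservation[pc$subgroup == "C1"], 0.75)
  expect_equal(pc$conservation[pc$subgroup == "C2"], 1)
  expect_true(pc$singleton[pc$subgroup == "C2"])
})

test_that("subfamilies sharing the intron template score as conserved", {
  sim <- sharedSim()
  models <- parseGeneModels(sim@gff)
  fam <- geneOrder(sim)$gene_id[geneOrder(sim)$family]
  sg <- data.frame(taxon = fam,
                   subgroup = rep(c("C1", "C2"), length.out = length(fam)))
  pc <- patternConservation(models[fam], sg)
  expect_true(all(pc$conservation >= 0.9))
})
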