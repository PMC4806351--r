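# Pairwise/progressive alignment, Poisson distances, NJ and bootstrap.

test_that("self-alignment has identity and coverage 1", {
  a <- "MKVAWDERT"
  aln <- globalAlign(a, a)
  expect_equal(aln$identity, 1)
  expect_equal(aln$coverageA, 1)
  expect_equal(aln$alignedA, a)
})

test_that("single-residue alignment produces one substitution column", {
  aln <- globalAlign("A", "G")
  expect_equal(aln$alignedA, "A")
  expect_equal(aln$alignedB, "G")
  expect_equal(aln$identity, 0)
})

test_that("illegal residues are rejected naming the position", {
  expect_error(globalAlign("MKX9", "MK"), "position 3")
})

test_that("alignment scores match exhaustive enumeration on tiny sequences", {
  sub <- mybkit:::.blosum62()
  withr::with_seed(41, {
    for (rep in 1:12) {
      a <- paste(sample(.mybkit_aa(), sample(2:6, 1), replace = TRUE),
                 collapse = "")
      b <- paste(sample(.mybkit_aa(), sample(2:6, 1), replace = TRUE),
                 collapse = "")
      expect_equal(globalAlign(a, b)$score,
                   bruteForceAlignScore(a, b, sub), tolerance = 1e-9)
    }
  })
})

test_that("degapping a pairwise alignment recovers the inputs", {
  withr::with_seed(42, {
    a <- paste(sample(.mybkit_aa(), 30, replace = TRUE), collapse = "")
    b <- paste(sample(.mybkit_aa(), 24, replace = TRUE), collapse = "")
  })
  aln <- globalAlign(a, b)
  expect_equal(gsub("-", "", aln$alignedA), a)
  expect_equal(gsub("-", "", aln$alignedB), b)
})

test_that("progressive MSA of identical sequences is gap-free", {
  msa <- progressiveMSA(c(a = "MKVAWDE", b = "MKVAWDE", c = "MKVAWDE"))
  expect_false(any(grepl("-", msa)))
  expect_equal(unname(nchar(msa)), rep(7, 3))
})

test_that("progressive MSA of two sequences equals the pairwise alignment", {
  a <- "MKVAWDEGH"; b <- "MKVWDEH"
  pa <- globalAlign(a, b)
  msa <- progressiveMSA(c(x = a, y = b))
  expect_equal(unname(msa["x"]), pa$alignedA)
  expect_equal(unname(msa["y"]), pa$alignedB)
})

test_that("MSA output columns cover the longest input and degap to inputs", {
  withr::with_seed(43, {
    base <- paste(sample(.mybkit_aa(), 40, replace = TRUE), collapse = "")
    seqs <- c(a = base,
              b = paste0(substr(base, 1, 20), substr(base, 26, 40)),
              c = paste0("MKV", base))
  })
  msa <- progressiveMSA(seqs)
  expect_true(all(nchar(msa) >= max(nchar(seqs))))
  for (n in names(seqs))
    expect_equal(gsub("-", "", msa[[n]]), seqs[[n]])
})

test_that("Poisson distance matches -log(1 - p) with pairwise deletion", {
  msa <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAC", c = "AA--AAAAAA")
  d <- poissonDistMatrix(msa)
  expect_equal(d["a", "b"], -log(1 - 0.1))
  expect_equal(d["a", "c"], 0)       # gapped columns excluded
  expect_equal(d["a", "a"], 0)
  expect_equal(d, t(d))
  # monotone in p and d >= p
  p <- seq(0.05, 0.9, by = 0.05)
  dd <- -log(1 - p)
  expect_true(all(diff(dd) > 0))
  expect_true(all(dd >= p))
})

test_that("saturated pairs are flagged NA with a warning", {
  expect_warning(d <- poissonDistMatrix(c(a = "AAAA", b = "CCCC")),
                 "saturated")
  expect_true(is.na(d["a", "b"]))
})

test_that("three taxa give the closed-form star solution", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d)
  ph <- ape::cophenetic.phylo(tr)
  expect_equal(ph[rownames(d), colnames(d)], d, tolerance = 1e-9)
  expect_error(njTree(d[1:2, 1:2]), "3 taxa")
})

test_that("additive 4- and 5-taxon matrices are recovered exactly", {
  tr4 <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  d4 <- ape::cophenetic.phylo(tr4)
  out4 <- njTree(d4)
  expect_equal(ape::cophenetic.phylo(out4)[rownames(d4), colnames(d4)],
               d4, tolerance = 1e-9)
  expect_equal(ape::dist.topo(ape::unroot(tr4), out4)[1], 0)

  tr5 <- ape::read.tree(text = "((A:1.5,B:0.8):0.6,(C:2,(D:1,E:0.5):0.7):0.4);")
  d5 <- ape::cophenetic.phylo(tr5)
  out5 <- njTree(d5)
  expect_equal(ape::cophenetic.phylo(out5)[rownames(d5), colnames(d5)],
               d5, tolerance = 1e-9)
  expect_equal(ape::dist.topo(ape::unroot(tr5), out5)[1], 0)
})

test_that("taxon input order does not change the topology", {
  tr5 <- ape::read.tree(text = "((A:1.5,B:0.8):0.6,(C:2,(D:1,E:0.5):0.7):0.4);")
  d5 <- ape::cophenetic.phylo(tr5)
  perm <- c("D", "A", "E", "B", "C")
  out <- njTree(d5[perm, perm])
  expect_equal(ape::dist.topo(njTree(d5), out)[1], 0)
})

test_that("negative NJ branch lengths are clamped with deficit transfer", {
  # a non-additive matrix known to produce a negative NJ edge
  d <- matrix(c(0, 5, 9, 9, 5, 0, 8, 9, 9, 8, 0, 1, 9, 9, 1, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  raw <- ape::nj(as.dist(d))
  tr <- njTree(d)
  expect_true(all(tr$edge.length >= 0))
  expect_equal(sum(tr$edge.length), sum(raw$edge.length), tolerance = 1e-9)
})

test_that("bootstrap supports are reproducible, bounded, and perfect for clean splits", {
  msa <- c(a = "AAAAAAAAAACCCC", b = "AAAAAAAAAACCCG",
           c = "TTTTTTTTTTCCCC", d = "TTTTTTTTTTCCCG")
  t1 <- bootstrapSupports(msa, nReplicates = 100, seed = 5)
  t2 <- bootstrapSupports(msa, nReplicates = 100, seed = 5)
  expect_identical(t1$node.label, t2$node.label)
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  # every column separates {a,b} from {c,d}: full support for the split
  expect_true(any(sup == 100))
  expect_error(bootstrapSupports(msa, nReplicates = 0), "nReplicates")
})

test_that("true duplication partners are high-support siblings", {
  sim <- simulateFamily(cherryConfig())
  go <- geneOrder(sim)
  fam <- go$gene_id[go$family]
  msa <- progressiveMSA(simProteins(sim)[fam])
  tree <- bootstrapSupports(msa, nReplicates = 200, seed = 8)
  h <- trueHistory(sim)
  shallow <- h[h$target_ks < 0.5, ]
  ntip <- length(tree$tip.label)
  for (i in seq_len(nrow(shallow))) {
    mrca <- ape::getMRCA(tree, c(shallow$gene_a[i], shallow$gene_b[i]))
    tips <- ape::extract.clade(tree, mrca)$tip.label
    expect_setequal(tips, c(shallow$gene_a[i], shallow$gene_b[i]))
    sup <- suppressWarnings(as.numeric(tree$node.label))[mrca - ntip]
    expect_gte(sup, 90)
  }
})

test_that("subgroup cutting follows the support threshold", {
  tr <- ape::read.tree(text = "((A,B)x,(C,(D,E)y)z);")
  # supports: root NA, then clades x, z, y by node order
  tr$node.label <- c(NA, 100, 30, 100)
  sg <- cutSubgroups(tr, minSupport = 50)
  byg <- split(sg$taxon, sg$subgroup)
  expect_true(any(vapply(byg, function(g) setequal(g, c("A", "B")),
                         logical(1))))
  expect_true(any(vapply(byg, function(g) setequal(g, c("D", "E")),
                         logical(1))))
  expect_true(any(vapply(byg, function(g) setequal(g, "C"), logical(1))))
  # all supports zero: every leaf is a singleton
  tr$node.label <- c(NA, 0, 0, 0)
  sg0 <- cutSubgroups(tr, minSupport = 50)
  expect_equal(length(unique(sg0$subgroup)), 5)
})

test_that("planted subfamilies are recovered as subgroups", {
  sim <- simulateFamily(cherryConfig())
  go <- geneOrder(sim)
  fam <- go$gene_id[go$family]
  msa <- progressiveMSA(simProteins(sim)[fam])
  tree <- bootstrapSupports(msa, nReplicates = 200, seed = 9)
  sg <- cutSubgroups(tree, minSupport = 50)
  h <- trueHistory(sim)
  shallow <- h[h$target_ks < 0.5, ]
  # each cherry pair must share a subgroup
  for (i in seq_len(nrow(shallow)))
    expect_equal(sg$subgroup[sg$taxon == shallow$gene_a[i]],
                 sg$subgroup[sg$taxon == shallow$gene_b[i]])
})
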