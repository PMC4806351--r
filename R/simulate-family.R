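# Synthetic genomes carrying a gene family with known duplication history.

#' Default R2 / R3 MYB repeat consensus sequences
#'
#' 49-residue consensus blocks used by the default simulation config and
#' repeat models. Tryptophan columns: 4, 24, 44 in R2; 4, 23 in R3.
#'
#' @return Named character vector with elements `R2` and `R3`.
#' @export
defaultRepeatConsensus <- function() {
  c(R2 = "KGAWTEEEDILLRKCIEKYGEGKWHLVPLRAGLNRCRKSCRLRWLNYLR",
    R3 = "GNRWSLIAGRLPGRTDNEIKNYWNTHLSKKLISQGIDPRTHKPLNPQAK")
}

#' @noRd
.randomSenseCodons <- function(n) {
  tab <- .codonTables()
  sense <- names(tab$code)[tab$code != "*"]
  sample(sense, n, replace = TRUE)
}

#' @noRd
.reverseTranslate <- function(protein) {
  code <- .codonTables()$code
  byAA <- split(names(code), code)
  vapply(strsplit(protein, "")[[1]], function(a) {
    opts <- byAA[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1), USE.NAMES = FALSE)
}

#' Build a family ancestor CDS carrying the R2 and R3 repeat blocks
#'
#' The ancestor protein is `M` + 9 random residues + R2 consensus + 5-residue
#' linker + R3 consensus + random C-terminal tail, reverse-translated with
#' uniformly drawn synonymous codons, plus a TAA stop. The construction is
#' deterministic for a given seed.
#'
#' @param nCodons Number of sense codons (protein length); at least 120.
#' @param r2,r3 49-residue repeat consensus strings.
#' @param seed Integer seed.
#' @return CDS string with attributes `r2Start` and `r3Start` (1-based
#'   protein coordinates of the planted repeats).
#' @export
familyAncestorCds <- function(nCodons = 500,
                              r2 = defaultRepeatConsensus()[["R2"]],
                              r3 = defaultRepeatConsensus()[["R3"]],
                              seed = 20160324L) {
  w2 <- nchar(r2); w3 <- nchar(r3)
  tail <- nCodons - 1L - 9L - w2 - 5L - w3
  if (tail < 0) stop("nCodons too small to host both repeats")
  withr::with_seed(seed, {
    pad <- paste(sample(.AA20, 9, replace = TRUE), collapse = "")
    linker <- paste(sample(.AA20, 5, replace = TRUE), collapse = "")
    tailSeq <- paste(sample(.AA20, tail, replace = TRUE), collapse = "")
    protein <- paste0("M", pad, r2, linker, r3, tailSeq)
    cds <- paste(c(.reverseTranslate(protein), "TAA"), collapse = "")
    attr(cds, "r2Start") <- 11L
    attr(cds, "r3Start") <- 11L + w2 + 5L
    cds
  })
}

#' Default duplication-event table
#'
#' Ten events (4 tandem, 6 segmental) with target Ks spanning 0.04-0.60 and
#' target Ka/Ks at the purifying end of the range reported for duplicated
#' R2R3-MYB pairs; tandem events are younger than segmental events, as in
#' the surveyed family.
#'
#' @return data.frame with columns `type`, `targetKs`, `targetKaKs`,
#'   `source` (`NA` = random source gene).
#' @export
defaultDuplicationEvents <- function() {
  data.frame(
    type = c("tandem", "tandem", "tandem", "tandem",
             "segmental", "segmental", "segmental", "segmental",
             "segmental", "segmental"),
    targetKs = c(0.04, 0.12, 0.20, 0.30,
                 0.19, 0.30, 0.35, 0.45, 0.52, 0.60),
    targetKaKs = c(0.40, 0.50, 0.35, 0.25,
                   0.30, 0.25, 0.20, 0.15, 0.15, 0.10),
    source = NA_integer_,
    stringsAsFactors = FALSE)
}

setClassUnion("dfOrNULL", c("data.frame", "NULL"))

#' Simulation configuration
#'
#' @slot nChromosomes Number of chromosomes.
#' @slot chromosomeLength Maximum chromosome length (bp).
#' @slot nBackgroundGenes Number of non-family genes.
#' @slot familyAncestorCds Ancestor coding sequence (with repeat-offset
#'   attributes, see [familyAncestorCds()]).
#' @slot duplicationEvents data.frame: `type` (tandem/segmental),
#'   `targetKs`, `targetKaKs`, `source`.
#' @slot repeatConsensusR2,repeatConsensusR3 49-residue repeat consensi.
#' @slot intronTemplate CDS offsets (nt after which an intron is inserted)
#'   shared by all family genes.
#' @slot transitionBias Transition:transversion weight.
#' @slot seed Integer master seed.
#' @export
setClass("SimulationConfig", representation(
  nChromosomes = "integer",
  chromosomeLength = "numeric",
  nBackgroundGenes = "integer",
  familyAncestorCds = "character",
  ancestorR2Start = "integer",
  ancestorR3Start = "integer",
  duplicationEvents = "dfOrNULL",
  repeatConsensusR2 = "character",
  repeatConsensusR3 = "character",
  intronTemplate = "numeric",
  transitionBias = "numeric",
  seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  ev <- object@duplicationEvents
  if (!is.null(ev) && nrow(ev) > 0) {
    if (!all(ev$type %in% c("tandem", "segmental")))
      msg <- c(msg, "event types must be 'tandem' or 'segmental'")
    if (any(ev$targetKs < 0)) msg <- c(msg, "target Ks must be >= 0")
    if (any(ev$targetKaKs < 0 | ev$targetKaKs > 1.5))
      msg <- c(msg, "target Ka/Ks must be in [0, 1.5]")
  }
  prot <- tryCatch(translateCds(object@familyAncestorCds),
                   error = function(e) conditionMessage(e))
  if (!grepl(object@repeatConsensusR2, prot, fixed = TRUE) ||
      !grepl(object@repeatConsensusR3, prot, fixed = TRUE))
    msg <- c(msg, "family ancestor must contain both repeat consensi")
  if (object@nChromosomes < 1) msg <- c(msg, "need at least 1 chromosome")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' @param nChromosomes,chromosomeLength,nBackgroundGenes Genome layout.
#' @param familyAncestorCds Ancestor CDS (default [familyAncestorCds()]).
#' @param duplicationEvents Event table (default
#'   [defaultDuplicationEvents()]).
#' @param repeatConsensusR2,repeatConsensusR3 Repeat consensi.
#' @param intronTemplate CDS intron offsets for family genes.
#' @param transitionBias Transition:transversion weight (default 2).
#' @param seed Master seed.
#' @return A [SimulationConfig-class] object.
#' @export
simulationConfig <- function(nChromosomes = 5,
                             chromosomeLength = 2e5,
                             nBackgroundGenes = 40,
                             familyAncestorCds = NULL,
                             duplicationEvents = defaultDuplicationEvents(),
                             repeatConsensusR2 = defaultRepeatConsensus()[["R2"]],
                             repeatConsensusR3 = defaultRepeatConsensus()[["R3"]],
                             intronTemplate = c(133, 266),
                             transitionBias = 2,
                             seed = 1L) {
  if (is.null(familyAncestorCds))
    familyAncestorCds <- mybkit::familyAncestorCds(
      r2 = repeatConsensusR2, r3 = repeatConsensusR3)
  r2s <- attr(familyAncestorCds, "r2Start")
  r3s <- attr(familyAncestorCds, "r3Start")
  if (is.null(r2s)) {
    prot <- translateCds(familyAncestorCds)
    r2s <- as.integer(regexpr(repeatConsensusR2, prot, fixed = TRUE))
    r3s <- as.integer(regexpr(repeatConsensusR3, prot, fixed = TRUE))
  }
  if (!is.null(duplicationEvents) && nrow(duplicationEvents) > 0 &&
      is.null(duplicationEvents$source))
    duplicationEvents$source <- NA_integer_
  methods::new("SimulationConfig",
               nChromosomes = as.integer(nChromosomes),
               chromosomeLength = chromosomeLength,
               nBackgroundGenes = as.integer(nBackgroundGenes),
               familyAncestorCds = as.character(familyAncestorCds),
               ancestorR2Start = as.integer(r2s),
               ancestorR3Start = as.integer(r3s),
               duplicationEvents = duplicationEvents,
               repeatConsensusR2 = repeatConsensusR2,
               repeatConsensusR3 = repeatConsensusR3,
               intronTemplate = intronTemplate,
               transitionBias = transitionBias,
               seed = as.integer(seed))
}

#' Simulated gene family
#'
#' Container returned by [simulateFamily()]: the genome, coding and protein
#' sequences, gene models, gene order and the true duplication history.
#'
#' @slot genome [Biostrings::DNAStringSet] of chromosomes.
#' @slot cds,proteins Coding and protein sequences (family + background).
#' @slot genes data.frame: `gene_id`, `chromosome`, `rank`, `start`, `end`,
#'   `strand`, `family`.
#' @slot gff [GenomicRanges::GRanges] with gene/mRNA/exon/CDS features.
#' @slot history data.frame of duplication events (true history).
#' @slot config The generating [SimulationConfig-class].
#' @slot repeatOffsets 1-based protein start positions of the planted R2
#'   and R3 repeats.
#' @export
setClass("FamilySim", representation(
  genome = "ANY", cds = "ANY", proteins = "ANY",
  genes = "data.frame", gff = "ANY", history = "data.frame",
  config = "SimulationConfig", repeatOffsets = "integer"))

setMethod("show", "FamilySim", function(object) {
  cat("FamilySim:", length(object@genome), "chromosomes,",
      nrow(object@genes), "genes (", sum(object@genes$family),
      "family ), ", nrow(object@history), "duplication events\n")
})

#' @rdname FamilySim-class
#' @param sim A `FamilySim`.
#' @export
simGenome <- function(sim) sim@genome
#' @rdname FamilySim-class
#' @export
simProteins <- function(sim) sim@proteins
#' @rdname FamilySim-class
#' @export
simCds <- function(sim) sim@cds
#' @rdname FamilySim-class
#' @export
geneOrder <- function(sim) sim@genes
#' @rdname FamilySim-class
#' @export
trueHistory <- function(sim) sim@history

#' @noRd
.randomDna <- function(n) paste(sample(.NT, n, replace = TRUE), collapse = "")

#' @noRd
.randomIntron <- function() {
  n <- sample(80:200, 1L)
  paste0("GT", .randomDna(n - 4L), "AG")
}

# Split a CDS at intron offsets into exon chunks.
#' @noRd
.exonChunks <- function(cds, offsets) {
  L <- nchar(cds)
  offsets <- offsets[offsets > 0 & offsets < L]
  bounds <- c(0, sort(offsets), L)
  mapply(function(a, b) substr(cds, a + 1, b),
         bounds[-length(bounds)], bounds[-1])
}

#' Simulate a genome carrying a gene family of known duplication history
#'
#' Generates a multi-chromosome genome with background genes and a gene
#' family grown from a single ancestor by the configured duplication
#' events. Each event copies a current family gene to a new locus (the
#' adjacent slot for a tandem event; a uniformly chosen non-adjacent
#' location, possibly on another chromosome, for a segmental event) and
#' diverges the new copy to the event's target Ks and Ka/Ks with
#' [mutateCDS()]. Identical seeds give identical output.
#'
#' @param config A [SimulationConfig-class].
#' @return A [FamilySim-class] object.
#' @export
simulateFamily <- function(config = simulationConfig()) {
  methods::validObject(config)
  jcInv <- function(d) 0.75 * (1 - exp(-4 * d / 3))
  ev <- config@duplicationEvents
  if (!is.null(ev) && nrow(ev) > 0 && any(jcInv(ev$targetKs) >= 0.75))
    stop("saturation: an event's target Ks implies p_S >= 3/4")
  withr::with_seed(config@seed, .simulateFamilyImpl(config))
}

#' @noRd
.simulateFamilyImpl <- function(config) {
  nBg <- config@nBackgroundGenes
  nChr <- config@nChromosomes
  chromNames <- sprintf("Chr%02d", seq_len(nChr))

  genes <- list()  # per-gene record: id, cds, intronOffsets, strand, family
  addGene <- function(id, cds, introns, family) {
    genes[[id]] <<- list(id = id, cds = cds, intronOffsets = introns,
                         strand = sample(c("+", "-"), 1L), family = family)
  }
  # Background genes: random CDS, 0-3 introns at random offsets
  for (k in seq_len(nBg)) {
    nCod <- sample(150:350, 1L)
    cds <- paste(c("ATG", .randomSenseCodons(nCod - 1L), "TAA"),
                 collapse = "")
    nInt <- sample(0:3, 1L)
    introns <- if (nInt > 0)
      sort(sample(seq(30L, 3L * nCod - 30L), nInt)) else numeric(0)
    addGene(sprintf("BG%03d", k), cds, introns, FALSE)
  }
  # Family founder
  famIds <- "MYB001"
  addGene("MYB001", as.character(config@familyAncestorCds),
          config@intronTemplate, TRUE)

  # Chromosome orders: distribute background genes, then the founder
  order <- stats::setNames(vector("list", nChr), chromNames)
  chrOf <- sample(rep_len(chromNames, nBg))
  for (k in seq_len(nBg))
    order[[chrOf[k]]] <- c(order[[chrOf[k]]], sprintf("BG%03d", k))
  fchr <- sample(chromNames, 1L)
  fpos <- sample.int(length(order[[fchr]]) + 1L, 1L)
  order[[fchr]] <- append(order[[fchr]], "MYB001", after = fpos - 1L)

  protectedPairs <- list()
  chromOfGene <- function(id)
    names(order)[vapply(order, function(o) id %in% o, logical(1))]
  isProtectedGap <- function(chr, at) {
    # would inserting after index `at` split a protected adjacent pair?
    o <- order[[chr]]
    if (at < 1L || at >= length(o)) return(FALSE)
    any(vapply(protectedPairs, function(p)
      setequal(p, o[c(at, at + 1L)]), logical(1)))
  }

  history <- list()
  ev <- config@duplicationEvents
  nEv <- if (is.null(ev)) 0L else nrow(ev)
  freeFlank <- function(id) {
    # a tandem copy needs a side of the source that does not split a
    # protected pair; a gene flanked by two earlier tandem partners is
    # not eligible as a tandem source
    chr <- chromOfGene(id)
    at <- match(id, order[[chr]])
    !isProtectedGap(chr, at) || !isProtectedGap(chr, at - 1L)
  }
  for (e in seq_len(nEv)) {
    type <- ev$type[e]
    src <- ev$source[e]
    if (is.na(src)) {
      eligible <- if (type == "tandem")
        which(vapply(famIds, freeFlank, logical(1))) else
          seq_along(famIds)
      if (length(eligible) == 0)
        stop("no eligible tandem source gene (all flanks occupied)")
      src <- eligible[sample.int(length(eligible), 1L)]
    }
    srcId <- famIds[src]
    newId <- sprintf("MYB%03d", length(famIds) + 1L)
    mut <- mutateCDS(genes[[srcId]]$cds, ev$targetKs[e], ev$targetKaKs[e],
                     transitionBias = config@transitionBias,
                     immutableCodons = 1L)
    genes[[newId]] <- list(id = newId, cds = as.character(mut),
                           intronOffsets = config@intronTemplate,
                           strand = sample(c("+", "-"), 1L), family = TRUE)
    srcChr <- chromOfGene(srcId)
    if (type == "tandem") {
      o <- order[[srcChr]]
      at <- match(srcId, o)
      # insert on a side of the source that does not split a protected pair
      side <- if (!isProtectedGap(srcChr, at)) at
      else if (!isProtectedGap(srcChr, at - 1L)) at - 1L
      else stop("tandem source ", srcId, " has no free flank")
      order[[srcChr]] <- append(o, newId, after = side)
      protectedPairs[[length(protectedPairs) + 1L]] <- c(srcId, newId)
    } else {
      # candidate slots: (chromosome, gap index 0..len); exclude slots that
      # split a protected pair or leave the copy family-adjacent to the
      # source on the source's chromosome
      slots <- list()
      for (chr in chromNames) {
        o <- order[[chr]]
        for (at in 0:length(o)) {
          if (isProtectedGap(chr, at)) next
          if (chr == srcChr) {
            newOrder <- append(o, newId, after = at)
            fam <- newOrder[newOrder %in% c(famIds, newId)]
            i1 <- match(newId, fam); i2 <- match(srcId, fam)
            if (abs(i1 - i2) == 1L) next
          }
          slots[[length(slots) + 1L]] <- list(chr = chr, at = at)
        }
      }
      if (length(slots) == 0L) stop("no valid segmental insertion slot")
      pickI <- sample.int(length(slots), 1L)
      pick <- slots[[pickI]]
      order[[pick$chr]] <- append(order[[pick$chr]], newId, after = pick$at)
    }
    famIds <- c(famIds, newId)
    history[[e]] <- data.frame(
      event = e, gene_a = srcId, gene_b = newId, type = type,
      target_ks = ev$targetKs[e], target_kaks = ev$targetKaKs[e],
      n_syn = attr(mut, "nSyn"), n_nonsyn = attr(mut, "nNonsyn"),
      stringsAsFactors = FALSE)
  }
  history <- if (length(history)) do.call(rbind, history) else
    data.frame(event = integer(0), gene_a = character(0),
               gene_b = character(0), type = character(0),
               target_ks = numeric(0), target_kaks = numeric(0),
               n_syn = integer(0), n_nonsyn = integer(0))

  # Lay out coordinates and assemble chromosome sequences
  geneRows <- list(); feat <- list(); chromSeqs <- character(nChr)
  names(chromSeqs) <- chromNames
  for (chr in chromNames) {
    cursor <- 0L; pieces <- character(0)
    rank <- 0L
    for (id in order[[chr]]) {
      g <- genes[[id]]
      rank <- rank + 1L
      spacer <- sample(300:800, 1L)
      pieces <- c(pieces, .randomDna(spacer))
      cursor <- cursor + spacer
      chunks <- .exonChunks(g$cds, g$intronOffsets)
      intrs <- if (length(chunks) > 1)
        vapply(seq_len(length(chunks) - 1L), function(i) .randomIntron(),
               character(1)) else character(0)
      fwd <- paste(c(rbind(c(chunks, ""), c(intrs, "", ""))[
        seq_len(2 * length(chunks) - 1)]), collapse = "")
      # exon coordinates within the forward gene block (1-based)
      exLen <- nchar(chunks); inLen <- nchar(intrs)
      exStart <- cumsum(c(1, utils::head(exLen, -1) + inLen))
      exEnd <- exStart + exLen - 1L
      blockLen <- nchar(fwd)
      gStart <- cursor + 1L
      gEnd <- cursor + blockLen
      if (g$strand == "+") {
        gexS <- gStart + exStart - 1L; gexE <- gStart + exEnd - 1L
        block <- fwd
      } else {
        gexS <- gEnd - exEnd + 1L; gexE <- gEnd - exStart + 1L
        o <- base::order(gexS); gexS <- gexS[o]; gexE <- gexE[o]
        block <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(fwd)))
      }
      pieces <- c(pieces, block)
      cursor <- cursor + blockLen
      geneRows[[length(geneRows) + 1L]] <- data.frame(
        gene_id = id, chromosome = chr, rank = rank,
        start = gStart, end = gEnd, strand = g$strand,
        family = g$family, stringsAsFactors = FALSE)
      # GFF3 features: phases of CDS pieces in transcription order
      nEx <- length(exLen)
      txOrder <- if (g$strand == "+") seq_len(nEx) else rev(seq_len(nEx))
      cum <- cumsum(c(0, exLen[seq_len(nEx - 1)]))
      phase <- (3L - cum %% 3L) %% 3L  # GFF3 phase of each CDS piece
      phaseByCoord <- integer(nEx)
      phaseByCoord[txOrder] <- phase
      feat[[length(feat) + 1L]] <- data.frame(
        chromosome = chr,
        type = c("gene", "mRNA", rep("exon", nEx), rep("CDS", nEx)),
        start = c(gStart, gStart, gexS, gexS),
        end = c(gEnd, gEnd, gexE, gexE),
        strand = g$strand,
        ID = c(id, paste0(id, ".1"), rep(NA_character_, 2 * nEx)),
        Parent = c(NA_character_, id, rep(paste0(id, ".1"), 2 * nEx)),
        phase = c(NA_integer_, NA_integer_, rep(NA_integer_, nEx),
                  phaseByCoord),
        stringsAsFactors = FALSE)
    }
    pieces <- c(pieces, .randomDna(sample(300:800, 1L)))
    chromSeqs[[chr]] <- paste(pieces, collapse = "")
    if (nchar(chromSeqs[[chr]]) > config@chromosomeLength)
      stop("genes exceed chromosomeLength on ", chr)
  }
  genesDf <- do.call(rbind, geneRows)
  featDf <- do.call(rbind, feat)
  gff <- GenomicRanges::GRanges(
    seqnames = featDf$chromosome,
    ranges = IRanges::IRanges(featDf$start, featDf$end),
    strand = featDf$strand,
    type = featDf$type, ID = featDf$ID,
    Parent = IRanges::CharacterList(lapply(featDf$Parent, function(p)
      if (is.na(p)) character(0) else p)),
    phase = featDf$phase)
  cdsSet <- Biostrings::DNAStringSet(
    vapply(genes, function(g) g$cds, character(1)))
  protSet <- Biostrings::AAStringSet(
    vapply(genes, function(g) translateCds(g$cds), character(1)))
  ord <- genesDf$gene_id
  methods::new("FamilySim",
               genome = Biostrings::DNAStringSet(chromSeqs),
               cds = cdsSet[ord], proteins = protSet[ord],
               genes = genesDf, gff = gff, history = history,
               config = config,
               repeatOffsets = c(R2 = config@ancestorR2Start,
                                 R3 = config@ancestorR3Start))
}

#' Write simulation outputs to disk
#'
#' Writes the genome, CDS and protein FASTA files, the GFF3 gene models,
#' the gene-order table and the true history JSON.
#'
#' @param sim A [FamilySim-class] object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named vector of file paths.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fasta"),
             cds = file.path(dir, "cds.fasta"),
             proteins = file.path(dir, "proteins.fasta"),
             gff = file.path(dir, "genes.gff3"),
             geneOrder = file.path(dir, "gene_order.tsv"),
             history = file.path(dir, "true_history.json"))
  Biostrings::writeXStringSet(sim@genome, paths[["genome"]])
  Biostrings::writeXStringSet(sim@cds, paths[["cds"]])
  Biostrings::writeXStringSet(sim@proteins, paths[["proteins"]])
  rtracklayer::export(sim@gff, paths[["gff"]], format = "gff3")
  utils::write.table(sim@genes, paths[["geneOrder"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim@history, paths[["history"]], digits = NA)
  invisible(paths)
}
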