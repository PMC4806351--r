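# End-to-end orchestration: simulate -> scan -> tree -> duplications ->
# structure -> motifs -> expression, with machine-readable reports.

#' Pipeline configuration
#'
#' @param simConfig A [SimulationConfig-class] (default
#'   [simulationConfig()]).
#' @param qpcrLog2fc Optional planted log2 fold-change matrix for the
#'   expression stage (genes x conditions); default plants none for the
#'   first 5 family genes.
#' @param stages Named logical vector toggling stages: `scan`, `tree`,
#'   `dup`, `structure`, `motifs`, `expr`.
#' @param outdir Output directory.
#' @param bootstrapReplicates Bootstrap replicates for the tree stage
#'   (default 200).
#' @param motifWidth Width for motif discovery (default 8).
#' @param maxMotifs Maximum motifs (default 5).
#' @param lambda Clock rate for dating (default 1.5e-8).
#' @param seed Master seed for the analysis stages.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(simConfig = simulationConfig(),
                           qpcrLog2fc = NULL,
                           stages = c(scan = TRUE, tree = TRUE, dup = TRUE,
                                      structure = TRUE, motifs = TRUE,
                                      expr = TRUE),
                           outdir = tempfile("mybkit_run_"),
                           bootstrapReplicates = 200,
                           motifWidth = 8, maxMotifs = 5,
                           lambda = 1.5e-8, seed = 1L) {
  defaults <- c(scan = TRUE, tree = TRUE, dup = TRUE, structure = TRUE,
                motifs = TRUE, expr = TRUE)
  defaults[names(stages)] <- stages
  structure(list(simConfig = simConfig, qpcrLog2fc = qpcrLog2fc,
                 stages = defaults, outdir = outdir,
                 bootstrapReplicates = bootstrapReplicates,
                 motifWidth = motifWidth, maxMotifs = maxMotifs,
                 lambda = lambda, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' @noRd
.stage <- function(name, files, report, fun) {
  res <- tryCatch(fun(), error = function(e) {
    for (f in files) if (file.exists(f)) unlink(f)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  res
}

#' Run the full gene-family survey pipeline
#'
#' Executes the stages in dependency order on a simulated family:
#' simulation (always), repeat scan, alignment/NJ tree/subgroups,
#' duplicate detection with Ka/Ks dating, exon/intron structure, motif
#' discovery and qPCR expression analysis. Any stage failure removes that
#' stage's partial outputs and aborts with a stage-named error. All
#' randomness is seeded, so reruns with the same config are reproducible.
#'
#' @param config A [pipelineConfig()].
#' @return list of class `RunReport`: per-stage row counts, emitted files,
#'   parameter echo and timing.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  t0 <- Sys.time()
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, ...)
  report <- list(parameters = list(seed = config$seed,
                                   simSeed = config$simConfig@seed,
                                   lambda = config$lambda,
                                   bootstrapReplicates =
                                     config$bootstrapReplicates),
                 stages = list(), files = list())
  note <- function(stage, files, counts) {
    report$stages[[stage]] <<- counts
    report$files[[stage]] <<- basename(files)
  }

  # --- simulate ------------------------------------------------------
  simFiles <- character(0)
  sim <- .stage("simulate", simFiles, report, function() {
    sim <- simulateFamily(config$simConfig)
    simFiles <<- writeSimulation(sim, config$outdir)
    ct <- simulateQpcrForSim(sim, config$qpcrLog2fc,
                             seed = config$seed + 11L)
    writeCtTable(ct, out("ct_table.tsv"))
    simFiles <<- c(simFiles, ct = out("ct_table.tsv"))
    list(sim = sim, ct = ct)
  })
  ct <- sim$ct; sim <- sim$sim
  note("simulate", simFiles,
       list(genes = nrow(sim@genes), events = nrow(sim@history),
            ctRows = nrow(ct)))
  famIds <- sim@genes$gene_id[sim@genes$family]
  famProt <- as.character(sim@proteins)[famIds]

  # --- domain scan ---------------------------------------------------
  if (config$stages[["scan"]]) {
    files <- out(c("domain_hits.tsv", "repeat_classes.tsv"))
    cls <- .stage("scan", files, report, function() {
      models <- repeatModelsFromSim(sim)
      cls <- classifyRepeats(sim@proteins, models$R2, models$R3)
      utils::write.table(cls$hits, files[1], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      utils::write.table(cls$classification, files[2], sep = "\t",
                         quote = FALSE, row.names = FALSE)
      cls
    })
    note("scan", files, list(hits = nrow(cls$hits),
                             r2r3 = length(cls$r2r3)))
  }

  # --- alignment / tree / subgroups ---------------------------------
  subgroups <- NULL
  if (config$stages[["tree"]] && length(famProt) < 4) {
    report$stages[["tree"]] <- list(skipped = "fewer than 4 family proteins")
    config$stages[["tree"]] <- FALSE
  }
  if (config$stages[["tree"]]) {
    files <- out(c("alignment.fasta", "distances.tsv", "tree.nwk",
                   "subgroups.tsv"))
    res <- .stage("tree", files, report, function() {
      msa <- progressiveMSA(famProt)
      Biostrings::writeXStringSet(Biostrings::AAStringSet(msa), files[1])
      d <- poissonDistMatrix(msa)
      utils::write.table(d, files[2], sep = "\t", quote = FALSE)
      tree <- bootstrapSupports(msa, nReplicates =
                                  config$bootstrapReplicates,
                                seed = config$seed + 21L)
      ape::write.tree(tree, files[3])
      sg <- cutSubgroups(tree, minSupport = 50)
      utils::write.table(sg, files[4], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      list(tree = tree, subgroups = sg)
    })
    subgroups <- res$subgroups
    note("tree", files, list(taxa = length(famProt),
                             subgroups = length(unique(subgroups$subgroup))))
  }

  # --- duplications --------------------------------------------------
  if (config$stages[["dup"]]) {
    files <- out(c("duplications.tsv", "duplication_summary.json"))
    rep2 <- .stage("dup", files, report, function() {
      pairs <- findDuplicates(famProt)
      if (nrow(pairs) > 0) {
        pairs <- classifyDuplication(pairs, sim@genes, familyIds = famIds)
        pairs <- pairKaKs(pairs, sim@cds, lambda = config$lambda)
      }
      repn <- duplicationReport(pairs)
      utils::write.table(repn$table, files[1], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      jsonlite::write_json(repn$aggregates, files[2], digits = NA,
                           auto_unbox = TRUE, force = TRUE)
      repn
    })
    note("dup", files, list(pairs = nrow(rep2$table)))
  }

  # --- gene structure ------------------------------------------------
  if (config$stages[["structure"]]) {
    files <- out(c("gene_structure.tsv", "intron_conservation.tsv"))
    res <- .stage("structure", files, report, function() {
      models <- parseGeneModels(sim@gff)
      models <- models[famIds]
      summ <- structureSummary(models, subgroups)
      utils::write.table(summ$perGene, files[1], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      cons <- if (!is.null(subgroups))
        patternConservation(models, subgroups) else NULL
      if (!is.null(cons))
        utils::write.table(cons, files[2], sep = "\t", quote = FALSE,
                           row.names = FALSE)
      summ
    })
    note("structure", files, list(models = nrow(res$perGene)))
  }

  # --- motifs --------------------------------------------------------
  if (config$stages[["motifs"]]) {
    files <- out(c("motifs.txt", "motif_occurrences.tsv"))
    res <- .stage("motifs", files, report, function() {
      motifs <- discoverMotifs(famProt, maxMotifs = config$maxMotifs,
                               widthRange = config$motifWidth,
                               seed = config$seed + 31L)
      writeMotifs(motifs, files[1])
      occ <- if (length(motifs)) motifOccurrence(motifs, famProt) else
        data.frame()
      utils::write.table(occ, files[2], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      list(motifs = motifs, occ = occ)
    })
    note("motifs", files, list(motifs = length(res$motifs)))
  }

  # --- expression ----------------------------------------------------
  if (config$stages[["expr"]]) {
    files <- out(c("expression_results.tsv", "log2fc_matrix.tsv",
                   "expression_clusters.tsv"))
    res <- .stage("expr", files, report, function() {
      er <- expressionAnalysis(ct, referenceGenes = c("REF1", "REF2"))
      utils::write.table(er, files[1], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      mat <- log2fcMatrix(er)
      utils::write.table(mat, files[2], sep = "\t", quote = FALSE)
      cl <- if (nrow(mat) >= 2) clusterProfiles(mat) else NULL
      if (!is.null(cl))
        utils::write.table(
          data.frame(gene = names(cl$clusters), cluster = cl$clusters),
          files[3], sep = "\t", quote = FALSE, row.names = FALSE)
      list(er = er, clusters = cl)
    })
    note("expr", files, list(results = nrow(res$er)))
  }
  report$skipped <- names(config$stages)[!config$stages]
  report$wallTimeSec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(report, out("run_report.json"), digits = NA,
                       auto_unbox = TRUE, force = TRUE)
  class(report) <- "RunReport"
  report
}

#' Simulate a Ct table matched to a simulated family
#'
#' Plants the provided log2 fold changes (default: a 5-gene block with
#' up/down responses, including one strong salt-induced root response of
#' about 226-fold) on family genes and simulates a Ct table.
#'
#' @param sim A [FamilySim-class].
#' @param log2fc Optional genes x conditions matrix.
#' @param seed Seed for the Ct simulation.
#' @return Ct table data.frame (see [simulateQpcr()]).
#' @export
simulateQpcrForSim <- function(sim, log2fc = NULL, seed = 1L) {
  famIds <- sim@genes$gene_id[sim@genes$family]
  conds <- defaultQpcrConditions()
  condNames <- paste(conds$tissue, conds$treatment, sep = ".")
  genes <- famIds
  if (is.null(log2fc)) {
    log2fc <- matrix(0, length(genes), nrow(conds),
                     dimnames = list(genes, condNames))
    picks <- utils::head(genes, 5)
    if (length(picks) >= 1)
      log2fc[picks[1], "root.salt_1"] <- log2(226)
    if (length(picks) >= 2)
      log2fc[picks[2], c("root.drought_1", "root.drought_2")] <- c(2, 3)
    if (length(picks) >= 3)
      log2fc[picks[3], c("leaf.salt_1", "leaf.salt_2")] <- c(-2, -3)
    if (length(picks) >= 4)
      log2fc[picks[4], c("leaf.drought_2", "root.drought_2")] <- 2
    if (length(picks) >= 5)
      log2fc[picks[5], c("root.salt_2")] <- -2
  }
  cfg <- qpcrSimConfig(genes, conditions = conds, plantedLog2fc = log2fc,
                       seed = seed)
  simulateQpcr(cfg)
}

#' Build repeat models from a simulation's planted repeat instances
#'
#' Extracts the R2 and R3 repeat blocks (at the planted offsets) from all
#' family proteins and builds one [RepeatModel-class] per repeat — the
#' "seed alignment" route to scan models.
#'
#' @param sim A [FamilySim-class].
#' @return list with elements `R2` and `R3`.
#' @export
repeatModelsFromSim <- function(sim) {
  famIds <- sim@genes$gene_id[sim@genes$family]
  prot <- as.character(sim@proteins)[famIds]
  w2 <- nchar(sim@config@repeatConsensusR2)
  w3 <- nchar(sim@config@repeatConsensusR3)
  r2 <- substr(prot, sim@repeatOffsets[["R2"]],
               sim@repeatOffsets[["R2"]] + w2 - 1L)
  r3 <- substr(prot, sim@repeatOffsets[["R3"]],
               sim@repeatOffsets[["R3"]] + w3 - 1L)
  list(R2 = buildRepeatModel(r2), R3 = buildRepeatModel(r3))
}

#' Log2 fold-change matrix from expression results
#'
#' @param results Output of [expressionAnalysis()].
#' @return Numeric matrix genes x (tissue.treatment) of log2 fold changes.
#' @export
log2fcMatrix <- function(results) {
  cond <- paste(results$tissue, results$treatment, sep = ".")
  genes <- unique(results$gene)
  conds <- unique(cond)
  mat <- matrix(NA_real_, length(genes), length(conds),
                dimnames = list(genes, conds))
  mat[cbind(match(results$gene, genes), match(cond, conds))] <-
    results$log2fc
  mat
}
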