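# Simulated qRT-PCR plates with planted fold changes.

#' qPCR simulation configuration
#'
#' @param genes Character vector of target gene ids.
#' @param conditions data.frame with columns `tissue` and `treatment`; the
#'   default mirrors a two-tissue design (leaf, root) with a control and two
#'   drought (PEG) and two salt (NaCl) levels.
#' @param plantedLog2fc Numeric matrix `genes x conditions` (condition
#'   columns named `tissue.treatment`) of planted log2 fold changes
#'   relative to the control of the same tissue; default all 0.
#' @param referenceGenes Character vector of reference gene ids (stable
#'   expression; planted fold change exactly 1 everywhere).
#' @param nBiological,nTechnical Replicate counts (defaults 3, 3).
#' @param ctNoiseSd Gaussian technical noise on each Ct measurement
#'   (cycles; default 0.25).
#' @param baselineCt Mean Ct of an unregulated gene (default 22).
#' @param seed Integer seed.
#' @return A list of class `QpcrSimConfig`.
#' @export
qpcrSimConfig <- function(genes,
                          conditions = defaultQpcrConditions(),
                          plantedLog2fc = NULL,
                          referenceGenes = c("REF1", "REF2"),
                          nBiological = 3L, nTechnical = 3L,
                          ctNoiseSd = 0.25, baselineCt = 22,
                          seed = 1L) {
  if (nrow(conditions) < 1) stop("condition list must not be empty")
  if (length(referenceGenes) < 1) stop("need at least one reference gene")
  condNames <- paste(conditions$tissue, conditions$treatment, sep = ".")
  if (is.null(plantedLog2fc)) {
    plantedLog2fc <- matrix(0, length(genes), nrow(conditions),
                            dimnames = list(genes, condNames))
  }
  stopifnot(nrow(plantedLog2fc) == length(genes),
            ncol(plantedLog2fc) == nrow(conditions))
  dimnames(plantedLog2fc) <- list(genes, condNames)
  ctrl <- grepl("^control$", conditions$treatment)
  if (any(plantedLog2fc[, ctrl] != 0))
    stop("planted log2 fold changes must be 0 in control conditions")
  structure(list(genes = genes, conditions = conditions,
                 plantedLog2fc = plantedLog2fc,
                 referenceGenes = referenceGenes,
                 nBiological = as.integer(nBiological),
                 nTechnical = as.integer(nTechnical),
                 ctNoiseSd = ctNoiseSd, baselineCt = baselineCt,
                 seed = as.integer(seed)),
            class = "QpcrSimConfig")
}

#' Default qPCR condition design
#'
#' @return data.frame of tissue x treatment combinations: leaf and root
#'   under control, two drought levels and two salt levels.
#' @export
defaultQpcrConditions <- function() {
  expand.grid(tissue = c("leaf", "root"),
              treatment = c("control", "drought_1", "drought_2",
                            "salt_1", "salt_2"),
              stringsAsFactors = FALSE)[, c("tissue", "treatment")]
}

#' Simulate a qPCR Ct table
#'
#' Inverts the 2^-ddCt model: each target gene's Ct in a condition is its
#' baseline minus the planted log2 fold change, plus Gaussian technical
#' noise per measurement; reference genes have planted fold change 1
#' everywhere. Gene baselines are drawn once per gene around
#' `baselineCt` and shared across conditions, so the planted log2fc is
#' exactly the expected -ddCt. Emitted Ct values are clamped to [10, 40].
#'
#' @param config A [qpcrSimConfig()] object.
#' @return data.frame with columns `sample`, `tissue`, `treatment`, `gene`,
#'   `bio_rep`, `tech_rep`, `ct`.
#' @export
simulateQpcr <- function(config) {
  stopifnot(inherits(config, "QpcrSimConfig"))
  withr::with_seed(config$seed, {
    allGenes <- c(config$genes, config$referenceGenes)
    base <- stats::setNames(
      config$baselineCt + stats::rnorm(length(allGenes), 0, 1.5), allGenes)
    rows <- list()
    condNames <- colnames(config$plantedLog2fc)
    for (ci in seq_len(nrow(config$conditions))) {
      tis <- config$conditions$tissue[ci]
      trt <- config$conditions$treatment[ci]
      for (b in seq_len(config$nBiological)) {
        sampleId <- paste(tis, trt, b, sep = "_")
        for (g in allGenes) {
          lfc <- if (g %in% config$referenceGenes) 0 else
            config$plantedLog2fc[g, condNames[ci]]
          for (t in seq_len(config$nTechnical)) {
            ct <- base[[g]] - lfc +
              stats::rnorm(1L, 0, config$ctNoiseSd)
            rows[[length(rows) + 1L]] <- data.frame(
              sample = sampleId, tissue = tis, treatment = trt,
              gene = g, bio_rep = b, tech_rep = t,
              ct = min(40, max(10, ct)), stringsAsFactors = FALSE)
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Write a Ct table as TSV
#'
#' @param ct Ct table from [simulateQpcr()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeCtTable <- function(ct, path) {
  utils::write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
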