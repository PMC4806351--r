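# GFF3 gene models: intron counts, positions, phases and subgroup-level
# pattern conservation.

#' Parse gene models from GFF3
#'
#' Reads a GFF3 file (gene / mRNA / exon / CDS features) and builds one
#' model per gene using its longest mRNA. Exons are re-ordered to
#' transcription order on the minus strand; introns are the gaps between
#' consecutive exons; intron phases are the cumulative CDS length modulo 3
#' at each intron position (CDS-relative, comparable across loci).
#'
#' @param gff Path to a GFF3 file, or a `GRanges` with `type`, `ID`,
#'   `Parent` metadata columns.
#' @return list of gene models; each model is a list with `gene_id`,
#'   `chromosome`, `strand`, `exons` and `introns` (data.frames of 1-based
#'   inclusive genomic intervals in transcription order), `cds_length`,
#'   `intron_cds_offsets`, `phases`, `cds_incomplete` flag.
#' @export
parseGeneModels <- function(gff) {
  gr <- if (is.character(gff)) rtracklayer::import(gff, format = "gff3")
  else gff
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  geneIdx <- which(type == "gene")
  mrnaIdx <- which(type == "mRNA")
  models <- list()
  for (gi in geneIdx) {
    gid <- ids[gi]
    mIdx <- mrnaIdx[parents[mrnaIdx] == gid]
    if (length(mIdx) == 0)
      stop("gene ", gid, " has no mRNA child")
    # pick the longest mRNA by summed exon width
    exLen <- vapply(mIdx, function(mi) {
      ex <- which(type == "exon" & parents == ids[mi])
      sum(BiocGenerics::width(gr[ex]))
    }, numeric(1))
    mi <- mIdx[which.max(exLen)]
    mid <- ids[mi]
    exIdx <- which(type == "exon" & parents == mid)
    cdsIdx <- which(type == "CDS" & parents == mid)
    if (length(exIdx) == 0) stop("mRNA ", mid, " has no exons")
    strand <- as.character(BiocGenerics::strand(gr[mi]))
    ex <- data.frame(start = BiocGenerics::start(gr[exIdx]),
                     end = BiocGenerics::end(gr[exIdx]))
    ex <- ex[base::order(ex$start), ]
    if (nrow(ex) > 1 &&
        any(ex$start[-1] <= ex$end[-nrow(ex)]))
      stop("overlapping exons in mRNA ", mid)
    introns <- if (nrow(ex) > 1)
      data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
    else data.frame(start = integer(0), end = integer(0))
    # transcription order
    if (strand == "-") {
      ex <- ex[rev(seq_len(nrow(ex))), ]
      introns <- introns[rev(seq_len(nrow(introns))), ]
    }
    rownames(ex) <- rownames(introns) <- NULL
    cdsLens <- if (length(cdsIdx) > 0) BiocGenerics::width(gr[cdsIdx])
    else BiocGenerics::width(gr[exIdx])
    cdsTotal <- sum(cdsLens)
    exonLens <- ex$end - ex$start + 1L
    offsets <- if (nrow(ex) > 1) cumsum(exonLens[-nrow(ex)]) else numeric(0)
    models[[gid]] <- list(
      gene_id = gid,
      chromosome = as.character(GenomicRanges::seqnames(gr[gi])),
      strand = strand, exons = ex, introns = introns,
      cds_length = cdsTotal,
      intron_cds_offsets = as.numeric(offsets),
      phases = as.integer(offsets %% 3),
      cds_incomplete = (cdsTotal %% 3) != 0)
  }
  models
}

#' Intron table of a set of gene models
#'
#' @param models Output of [parseGeneModels()].
#' @return data.frame: `gene_id`, `n_exons`, `n_introns`, `pattern`
#'   (intron count + phase vector signature), `cds_incomplete`.
#' @export
intronTable <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    data.frame(gene_id = m$gene_id,
               n_exons = nrow(m$exons),
               n_introns = nrow(m$introns),
               pattern = paste0(nrow(m$introns), ":",
                                paste(m$phases, collapse = ",")),
               cds_incomplete = m$cds_incomplete,
               stringsAsFactors = FALSE)
  })) -> tab
  rownames(tab) <- NULL
  tab
}

#' Exon/intron structure summary
#'
#' Distribution of genes over intron-count classes, with fractions; if
#' subgroup labels are given, also a per-subgroup pattern table.
#'
#' @param models Output of [parseGeneModels()].
#' @param subgroups Optional data.frame with `taxon`/`gene_id` and
#'   `subgroup` columns.
#' @return list with `perGene`, `byIntronCount` (count + fraction per
#'   intron-count class) and `bySubgroup` (`NULL` without labels).
#' @export
structureSummary <- function(models, subgroups = NULL) {
  if (length(models) == 0) stop("no gene models")
  tab <- intronTable(models)
  counts <- table(tab$n_introns)
  byIntron <- data.frame(n_introns = as.integer(names(counts)),
                         n_genes = as.integer(counts),
                         fraction = as.numeric(counts) / nrow(tab))
  bySub <- NULL
  if (!is.null(subgroups) && nrow(subgroups) > 0) {
    idCol <- if ("gene_id" %in% names(subgroups)) "gene_id" else "taxon"
    tab$subgroup <- subgroups$subgroup[match(tab$gene_id,
                                             subgroups[[idCol]])]
    bySub <- stats::aggregate(list(n = tab$gene_id),
                              by = list(subgroup = tab$subgroup,
                                        pattern = tab$pattern),
                              FUN = length)
  }
  list(perGene = tab, byIntronCount = byIntron, bySubgroup = bySub)
}

#' Intron-pattern conservation within subgroups
#'
#' For each subgroup, the fraction of members sharing the subgroup's modal
#' (intron count, phase vector) pattern; 1.0 means fully conserved.
#' Singleton subgroups score 1.0 and are flagged.
#'
#' @inheritParams structureSummary
#' @param subgroups data.frame with `taxon`/`gene_id` and `subgroup`.
#' @return data.frame: `subgroup`, `n`, `modal_pattern`, `conservation`,
#'   `singleton`.
#' @export
patternConservation <- function(models, subgroups) {
  tab <- intronTable(models)
  idCol <- if ("gene_id" %in% names(subgroups)) "gene_id" else "taxon"
  tab$subgroup <- subgroups$subgroup[match(tab$gene_id,
                                           subgroups[[idCol]])]
  tab <- tab[!is.na(tab$subgroup), ]
  out <- lapply(split(tab, tab$subgroup), function(s) {
    counts <- sort(table(s$pattern), decreasing = TRUE)
    data.frame(subgroup = s$subgroup[1], n = nrow(s),
               modal_pattern = names(counts)[1],
               conservation = as.numeric(counts[1]) / nrow(s),
               singleton = nrow(s) == 1L, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
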