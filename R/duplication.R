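# Duplicate-pair detection, tandem/segmental classification, Ka/Ks and
# molecular-clock dating.

#' Detect duplicate gene pairs by the >80% coverage / >80% similarity rule
#'
#' Aligns every unordered protein pair globally and reports pairs whose
#' aligned region covers more than `covMin` of the longer gene and whose
#' aligned-column identity exceeds `simMin` (both strictly).
#'
#' @param proteins Named character vector or AAStringSet (>= 2).
#' @param covMin,simMin Strict lower bounds (defaults 0.8).
#' @return data.frame with columns `gene_a`, `gene_b`, `coverage`,
#'   `similarity`.
#' @export
findDuplicates <- function(proteins, covMin = 0.8, simMin = 0.8) {
  seqs <- .asNamedChar(proteins)
  if (length(seqs) < 2) stop("need at least 2 proteins")
  if (is.null(names(seqs))) names(seqs) <- paste0("p", seq_along(seqs))
  ids <- names(seqs)
  rows <- list()
  for (i in seq_len(length(seqs) - 1)) {
    for (j in (i + 1):length(seqs)) {
      aln <- globalAlign(seqs[i], seqs[j])
      coverage <- aln$nAlignedColumns / max(nchar(seqs[i]), nchar(seqs[j]))
      if (coverage > covMin && aln$identity > simMin) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = ids[i], gene_b = ids[j],
          coverage = coverage, similarity = aln$identity,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      coverage = numeric(0), similarity = numeric(0)))
  do.call(rbind, rows)
}

#' Classify duplicate pairs as tandem or segmental
#'
#' A pair is tandem iff both genes lie on the same chromosome at adjacent
#' family ranks (no other family gene between them, "one following the
#' other"); segmental_intra iff on the same chromosome but not adjacent;
#' segmental_inter iff on different chromosomes.
#'
#' @param pairs data.frame with `gene_a`, `gene_b` (e.g. from
#'   [findDuplicates()]).
#' @param geneOrder data.frame with `gene_id`, `chromosome`, `rank`
#'   (genomic order of all genes).
#' @param familyIds Gene ids constituting the family for rank adjacency;
#'   defaults to the genes appearing in `pairs`.
#' @return `pairs` with an added `dup_class` column.
#' @export
classifyDuplication <- function(pairs, geneOrder, familyIds = NULL) {
  if (is.null(familyIds)) familyIds <- unique(c(pairs$gene_a, pairs$gene_b))
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)),
                     geneOrder$gene_id)
  if (length(missing) > 0)
    stop("gene(s) missing from gene order table: ",
         paste(missing, collapse = ", "))
  fam <- geneOrder[geneOrder$gene_id %in% familyIds, ]
  fam <- fam[base::order(fam$chromosome, fam$rank), ]
  fam$famRank <- stats::ave(seq_len(nrow(fam)), fam$chromosome,
                            FUN = seq_along)
  look <- function(id, col) fam[[col]][match(id, fam$gene_id)]
  cls <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    ca <- look(a, "chromosome"); cb <- look(b, "chromosome")
    if (is.na(ca) || is.na(cb))
      stop("pair gene not in familyIds: ", a, " / ", b)
    if (ca != cb) {
      cls[i] <- "segmental_inter"
    } else if (abs(look(a, "famRank") - look(b, "famRank")) == 1L) {
      cls[i] <- "tandem"
    } else {
      cls[i] <- "segmental_intra"
    }
  }
  pairs$dup_class <- cls
  pairs
}

#' Ka/Ks and dating for classified duplicate pairs
#'
#' Runs [kaKsPair()] on each pair, dates the event via [dateDuplication()],
#' and labels the selection regime.
#'
#' @param pairs data.frame with `gene_a`, `gene_b` (and optionally
#'   `dup_class`).
#' @param cds Named coding sequences covering all pair members.
#' @param lambda Clock rate (default 1.5e-8).
#' @return `pairs` with added `ka`, `ks`, `ka_ks`, `t_mya`,
#'   `selection_label` columns.
#' @export
pairKaKs <- function(pairs, cds, lambda = 1.5e-8) {
  cds <- as.character(cds)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    kk <- kaKsPair(cds[[pairs$gene_a[i]]], cds[[pairs$gene_b[i]]])
    data.frame(ka = kk$ka, ks = kk$ks, ka_ks = kk$ratio)
  })
  res <- do.call(rbind, res)
  out <- cbind(pairs, res)
  out$t_mya <- dateDuplication(out$ks, lambda)
  out$selection_label <- selectionLabel(out$ka_ks)
  out
}

#' Duplication summary report
#'
#' Combines classified, dated pairs into a per-pair table plus aggregates:
#' per duplication class the count and mean/min/max age, and counts by
#' selection label.
#'
#' @param pairs data.frame with at least `ks`, `ka_ks`, `t_mya` and a
#'   class column (`dup_class` or `class`).
#' @return list with `table` (the input, normalized) and `aggregates`
#'   (list with `byClass` data.frame and `bySelection` table); empty input
#'   gives an empty table and `NULL` aggregates.
#' @export
duplicationReport <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0)
    return(list(table = data.frame(), aggregates = NULL))
  cls <- if ("dup_class" %in% names(pairs)) pairs$dup_class else pairs$class
  if (is.null(cls)) stop("pairs need a dup_class or class column")
  if (!"selection_label" %in% names(pairs))
    pairs$selection_label <- selectionLabel(pairs$ka_ks)
  if (!"t_mya" %in% names(pairs))
    pairs$t_mya <- dateDuplication(pairs$ks)
  major <- sub("_(intra|inter)$", "", cls)
  byClass <- do.call(rbind, lapply(split(pairs$t_mya, major), function(t) {
    data.frame(n = length(t), mean_t_mya = mean(t, na.rm = TRUE),
               min_t_mya = min(t, na.rm = TRUE),
               max_t_mya = max(t, na.rm = TRUE))
  }))
  byClass$class <- rownames(byClass)
  rownames(byClass) <- NULL
  bySelection <- table(pairs$selection_label)
  list(table = pairs,
       aggregates = list(byClass = byClass[, c("class", "n", "mean_t_mya",
                                               "min_t_mya", "max_t_mya")],
                         bySelection = bySelection))
}

#' Published Ka/Ks table for duplicated GrMYB gene pairs
#'
#' The reference table of 35 duplicated R2R3-MYB gene pairs in
#' *Gossypium raimondii* (27 segmental, 8 tandem) with their reported Ka,
#' Ks and Ka/Ks values, shipped with the package. Ages are re-derivable
#' from Ks via [dateDuplication()].
#'
#' @return data.frame with columns `gene1`, `gene2`, `ka`, `ks`, `ka_ks`,
#'   `class`.
#' @export
grmybDuplicationPairs <- function() {
  path <- system.file("extdata", "grmyb_duplication_pairs.tsv",
                      package = "mybkit", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
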