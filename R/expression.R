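# qRT-PCR relative expression: reference-gene normalization, 2^-ddCt fold
# changes, one-way ANOVA significance and profile clustering.

#' Reference-gene normalization of Ct values
#'
#' Technical replicates are averaged first; each biological sample's dCt is
#' then the gene's mean Ct minus the arithmetic mean Ct of the reference
#' genes in the same sample (equivalent to the geometric mean of relative
#' quantities).
#'
#' @param records Ct table with columns `tissue`, `treatment`, `gene`,
#'   `bio_rep`, `tech_rep`, `ct` (see [simulateQpcr()]).
#' @param referenceGenes Character vector of reference gene ids; every
#'   sample must have all of them measured.
#' @param censorLimit Ct at or above which a measurement is treated as
#'   undetectable (censored); default 40.
#' @return data.frame with columns `tissue`, `treatment`, `bio_rep`,
#'   `gene`, `delta_ct`, `censored`.
#' @export
normalizeCt <- function(records, referenceGenes, censorLimit = 40) {
  req <- c("tissue", "treatment", "gene", "bio_rep", "tech_rep", "ct")
  if (!all(req %in% names(records)))
    stop("records must have columns: ", paste(req, collapse = ", "))
  agg <- stats::aggregate(list(ct = records$ct),
                          by = list(tissue = records$tissue,
                                    treatment = records$treatment,
                                    bio_rep = records$bio_rep,
                                    gene = records$gene),
                          FUN = mean)
  sampleKey <- paste(agg$tissue, agg$treatment, agg$bio_rep, sep = "|")
  out <- list()
  for (s in unique(sampleKey)) {
    sub <- agg[sampleKey == s, ]
    refs <- sub$ct[match(referenceGenes, sub$gene)]
    if (any(is.na(refs)))
      stop("sample ", s, " is missing reference gene measurement(s): ",
           paste(referenceGenes[is.na(refs)], collapse = ", "))
    tgt <- sub[!(sub$gene %in% referenceGenes), , drop = FALSE]
    tgt$delta_ct <- tgt$ct - mean(refs)
    tgt$censored <- tgt$ct >= censorLimit
    out[[s]] <- tgt[, c("tissue", "treatment", "bio_rep", "gene",
                        "delta_ct", "censored")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' 2^-ddCt fold change
#'
#' `ddCt = mean dCt(treated) - mean dCt(control)`; the relative expression
#' level is `2^-ddCt`.
#'
#' @param deltaCtTreated,deltaCtControl Numeric vectors of per-biological-
#'   replicate dCt values (at least one each).
#' @return Fold change (single number).
#' @export
ddctFoldChange <- function(deltaCtTreated, deltaCtControl) {
  if (length(deltaCtControl) < 1) stop("control condition is missing")
  if (length(deltaCtTreated) < 1) stop("treated condition is missing")
  2^-(mean(deltaCtTreated) - mean(deltaCtControl))
}

#' One-way ANOVA on replicate groups
#'
#' Classical fixed-effects one-way analysis of variance (between/within
#' decomposition via [stats::aov]). Degenerate input with zero within-group
#' variance and equal group means yields `F = 0, p = 1`.
#'
#' @param groups A list of numeric vectors (>= 2 groups with >= 2 values
#'   each).
#' @return list with elements `F` and `p`.
#' @export
oneWayAnova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs at least 2 values")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  means <- vapply(groups, mean, numeric(1))
  ssw <- sum(unlist(lapply(groups, function(v) sum((v - mean(v))^2))))
  if (ssw == 0) {
    if (max(means) - min(means) == 0) return(list(F = 0, p = 1))
    return(list(F = Inf, p = 0))
  }
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  list(F = tab[["F value"]][1], p = tab[["Pr(>F)"]][1])
}

#' Relative expression analysis of a Ct table
#'
#' Runs reference normalization, per-gene/tissue/treatment 2^-ddCt fold
#' changes against the control treatment, a per-gene/tissue one-way ANOVA
#' of dCt across treatments, and Benjamini-Hochberg q-values. Censored
#' (undetectable) measurements are excluded from the ANOVA and flag the
#' fold change as a bound.
#'
#' @inheritParams normalizeCt
#' @param control Name of the control treatment (default `"control"`).
#' @param alpha Significance level for [flagSignificant()] (default 0.05).
#' @param fcThreshold Fold-change threshold (default 2).
#' @return data.frame with one row per gene x tissue x non-control
#'   treatment: `gene`, `tissue`, `treatment`, `fold_change`, `log2fc`,
#'   `bounded`, `p_value`, `q_value`, `significant`, `direction`.
#' @export
expressionAnalysis <- function(records, referenceGenes, control = "control",
                               alpha = 0.05, fcThreshold = 2,
                               censorLimit = 40) {
  dct <- normalizeCt(records, referenceGenes, censorLimit)
  if (!control %in% dct$treatment)
    stop("control treatment '", control, "' not present")
  rows <- list()
  for (tis in unique(dct$tissue)) {
    sub <- dct[dct$tissue == tis, ]
    for (g in unique(sub$gene)) {
      gs <- sub[sub$gene == g, ]
      ctrl <- gs$delta_ct[gs$treatment == control]
      groups <- split(gs$delta_ct[!gs$censored],
                      gs$treatment[!gs$censored])
      groups <- groups[vapply(groups, length, integer(1)) >= 2]
      pv <- if (length(groups) >= 2) oneWayAnova(groups)$p else NA_real_
      for (trt in setdiff(unique(gs$treatment), control)) {
        tr <- gs[gs$treatment == trt, ]
        fc <- ddctFoldChange(tr$delta_ct, ctrl)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, tissue = tis, treatment = trt,
          fold_change = fc, log2fc = log2(fc),
          bounded = any(tr$censored), p_value = pv,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  flagSignificant(res, fcThreshold = fcThreshold, alpha = alpha)
}

#' Flag significantly altered genes
#'
#' A result is significant iff its fold change is at least `fcThreshold`
#' (or at most `1/fcThreshold`) and its raw ANOVA p-value is below `alpha`.
#'
#' @param results data.frame with `fold_change` and `p_value` columns.
#' @param fcThreshold Fold-change threshold (default 2).
#' @param alpha Significance level on the raw p-value (default 0.05).
#' @return `results` with added `significant` and `direction` columns.
#' @export
flagSignificant <- function(results, fcThreshold = 2, alpha = 0.05) {
  fc <- results$fold_change
  results$significant <- !is.na(results$p_value) &
    (fc >= fcThreshold | fc <= 1 / fcThreshold) & results$p_value < alpha
  results$direction <- ifelse(fc >= 1, "up", "down")
  results
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering of gene log2 fold-change profiles under
#' correlation distance `1 - Pearson` with average linkage. Constant
#' profiles (zero variance, undefined correlation) are placed at distance 0
#' from identical profiles and maximal distance from everything else, and
#' flagged.
#'
#' @param mat Numeric matrix, genes x conditions (>= 2 each).
#' @param k Number of flat clusters, or `NULL`.
#' @param h Cut height in distance units, or `NULL`; if both `k` and `h`
#'   are `NULL`, `h = 1` is used.
#' @return list with `clusters` (named integer vector), `hclust` (the
#'   dendrogram), and `flagged` (genes with constant profiles).
#' @export
clusterProfiles <- function(mat, k = NULL, h = NULL) {
  if (nrow(mat) < 2 || ncol(mat) < 2)
    stop("need at least 2 genes and 2 conditions")
  if (any(is.na(mat))) stop("matrix contains missing cells")
  v <- apply(mat, 1, stats::var)
  flagged <- rownames(mat)[v == 0]
  cors <- suppressWarnings(stats::cor(t(mat)))
  d <- 1 - cors
  if (length(flagged) > 0) {
    for (i in which(v == 0)) {
      same <- apply(mat, 1, function(r) all(r == mat[i, ]))
      d[i, ] <- ifelse(same, 0, 2)
      d[, i] <- d[i, ]
    }
  }
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  clusters <- if (!is.null(k)) stats::cutree(hc, k = k)
  else stats::cutree(hc, h = if (is.null(h)) 1 else h)
  list(clusters = clusters, hclust = hc, flagged = flagged)
}
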