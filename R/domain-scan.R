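# PWM detection of R2/R3 MYB repeats and alignment conservation statistics.

#' @noRd
.blockMatrix <- function(block) {
  block <- toupper(as.character(block))
  if (length(block) == 0) stop("empty alignment block")
  if (length(unique(nchar(block))) != 1)
    stop("alignment rows must have equal length")
  do.call(rbind, strsplit(block, ""))
}

#' Position-weight model of a MYB repeat
#'
#' @slot width Number of columns (default models use 49).
#' @slot freq 20 x width residue frequency matrix (columns sum to 1).
#' @slot logOdds 20 x width log2-odds matrix versus the background.
#' @slot background Length-20 background frequency vector.
#' @slot trpColumns Column indices expected to hold tryptophan.
#' @slot pseudocount Pseudocount used at build time.
#' @export
setClass("RepeatModel", representation(
  width = "integer", freq = "matrix", logOdds = "matrix",
  background = "numeric", trpColumns = "integer", pseudocount = "numeric"))

setValidity("RepeatModel", function(object) {
  msg <- character(0)
  if (object@width < 6) msg <- c(msg, "width must be >= 6")
  if (ncol(object@freq) != object@width)
    msg <- c(msg, "freq width mismatch")
  if (any(abs(colSums(object@freq) - 1) > 1e-8))
    msg <- c(msg, "frequency columns must sum to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RepeatModel", function(object) {
  cat("RepeatModel: width", object@width, "| consensus",
      modelConsensus(object), "\n")
})

#' @rdname RepeatModel-class
#' @param model A `RepeatModel`.
#' @export
modelConsensus <- function(model) {
  paste(rownames(model@freq)[apply(model@freq, 2, which.max)],
        collapse = "")
}

#' Build a repeat model from a gap-free alignment block
#'
#' Column frequencies are `(count + pseudocount) / (n + 20 pseudocount)`;
#' log-odds are log2 of frequency over background. Tryptophan columns
#' default to the columns whose modal residue is W.
#'
#' @param block Gap-free alignment rows (character vector or AAStringSet)
#'   of equal length over the 20 amino acids.
#' @param pseudocount Per-residue pseudocount (default 0.5).
#' @param background Length-20 background frequencies (default uniform).
#' @param trpColumns Expected Trp column indices, or `NULL` to detect.
#' @return A [RepeatModel-class].
#' @export
buildRepeatModel <- function(block, pseudocount = 0.5, background = NULL,
                             trpColumns = NULL) {
  mat <- .blockMatrix(block)
  if (any(!mat %in% .AA20))
    stop("alignment block contains non-standard residues")
  n <- nrow(mat); w <- ncol(mat)
  if (is.null(background)) background <- rep(1 / 20, 20)
  if (length(background) != 20 || abs(sum(background) - 1) > 1e-6)
    stop("background must be 20 frequencies summing to 1")
  counts <- apply(mat, 2, function(col)
    as.numeric(table(factor(col, levels = .AA20))))
  rownames(counts) <- .AA20
  freq <- (counts + pseudocount) / (n + 20 * pseudocount)
  logOdds <- log2(freq / background)
  if (is.null(trpColumns)) {
    modal <- apply(freq, 2, function(f) .AA20[which.max(f)])
    trpColumns <- which(modal == "W")
  }
  methods::new("RepeatModel", width = as.integer(w), freq = freq,
               logOdds = logOdds, background = background,
               trpColumns = as.integer(trpColumns),
               pseudocount = pseudocount)
}

#' Per-column information content of an alignment block
#'
#' `I_c = log2(20) + sum_a f_a log2 f_a`, clipped at 0 — the bit score of a
#' sequence-logo column. Gaps are excluded from the frequencies; columns
#' with more than `maxGapFrac` gaps are returned as `NA`.
#'
#' @inheritParams buildRepeatModel
#' @param maxGapFrac Columns with a larger gap fraction are dropped
#'   (default 0.5).
#' @return Numeric vector of bits per column (`NA` for dropped columns).
#' @export
columnInformation <- function(block, maxGapFrac = 0.5) {
  mat <- .blockMatrix(block)
  apply(mat, 2, function(col) {
    gaps <- col %in% c("-", ".")
    if (all(gaps)) stop("column consists entirely of gaps")
    if (mean(gaps) > maxGapFrac) return(NA_real_)
    f <- table(col[!gaps]) / sum(!gaps)
    max(0, log2(20) + sum(f * log2(f)))
  })
}

#' Columns conserved above a frequency threshold
#'
#' @inheritParams columnInformation
#' @param threshold Minimal modal-residue frequency in `(0, 1]`
#'   (default 1 = 100% conserved).
#' @return Integer vector of column indices.
#' @export
conservedColumns <- function(block, threshold = 1.0, maxGapFrac = 0.5) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  mat <- .blockMatrix(block)
  keep <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    gaps <- col %in% c("-", ".")
    if (mean(gaps) > maxGapFrac) return(FALSE)
    f <- table(col[!gaps]) / sum(!gaps)
    max(f) >= threshold
  }, logical(1))
  which(keep)
}

#' Calibrate a scan score threshold from a random-sequence null
#'
#' Generates random proteins from the model background, records each
#' protein's maximum window score, and returns a high quantile — by
#' default the 99.9th percentile, giving a per-protein false positive rate
#' of about 0.1%.
#'
#' @param model A [RepeatModel-class].
#' @param nullLength Length of the null proteins (default 300).
#' @param n Number of null proteins (default 1000).
#' @param q Quantile (default 0.999).
#' @param seed Integer seed.
#' @param background Residue frequencies for the null proteins; defaults
#'   to the model background, but should be the scanned set's own
#'   composition when that differs (codon-usage skew raises null scores).
#' @return Score threshold.
#' @export
calibrateScoreThreshold <- function(model, nullLength = 300, n = 1000,
                                    q = 0.999, seed = 99L,
                                    background = NULL) {
  if (is.null(background)) background <- model@background
  withr::with_seed(seed, {
    maxes <- vapply(seq_len(n), function(i) {
      s <- paste(sample(.AA20, nullLength, replace = TRUE,
                        prob = background), collapse = "")
      max(.windowScores(s, model))
    }, numeric(1))
    as.numeric(stats::quantile(maxes, q))
  })
}

#' @noRd
.residueFreq <- function(seqs) {
  chars <- unlist(strsplit(gsub("\\*", "", toupper(seqs)), ""))
  tab <- table(factor(chars, levels = .AA20))
  as.numeric(tab + 1) / sum(tab + 1)
}

#' @noRd
.windowScores <- function(protein, model) {
  chars <- strsplit(toupper(as.character(protein)), "")[[1]]
  w <- model@width
  L <- length(chars)
  if (L < w) return(numeric(0))
  idx <- match(chars, .AA20)
  lo <- model@logOdds
  vapply(seq_len(L - w + 1L), function(s) {
    cols <- seq_len(w)
    pos <- idx[s + cols - 1L]
    sc <- lo[cbind(pos, cols)]
    sum(sc, na.rm = TRUE)  # non-standard residues contribute 0
  }, numeric(1))
}

#' Scan a protein for repeat occurrences
#'
#' Scores every window of model width with the log-odds matrix and returns
#' non-overlapping hits above the threshold, selected greedily by
#' descending score (ties to the leftmost start). Tryptophan flags record
#' whether each expected Trp column holds a W.
#'
#' @param protein Protein sequence (character or AAString).
#' @param model A [RepeatModel-class].
#' @param scoreThreshold Minimal window score; default calibrates via
#'   [calibrateScoreThreshold()] (cached per model).
#' @param proteinId Optional id for the output.
#' @return data.frame with columns `protein_id`, `start`, `end` (1-based
#'   inclusive residue coordinates), `score`, `trp_ok` (all expected Trp
#'   present), `n_trp` (count present). Zero rows (with a warning) if the
#'   protein is shorter than the model width.
#' @export
scanProtein <- function(protein, model, scoreThreshold = NULL,
                        proteinId = "protein") {
  if (is.null(scoreThreshold)) scoreThreshold <- .cachedThreshold(model)
  scores <- .windowScores(protein, model)
  empty <- data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      trp_ok = logical(0), n_trp = integer(0))
  if (length(scores) == 0) {
    warning("protein shorter than model width; no windows scored")
    return(empty)
  }
  cand <- which(scores > scoreThreshold)
  if (length(cand) == 0) return(empty)
  cand <- cand[base::order(-scores[cand], cand)]
  w <- model@width
  taken <- integer(0)
  keep <- integer(0)
  for (s in cand) {
    span <- s:(s + w - 1L)
    if (length(intersect(span, taken)) == 0) {
      keep <- c(keep, s)
      taken <- c(taken, span)
    }
  }
  keep <- sort(keep)
  chars <- strsplit(toupper(as.character(protein)), "")[[1]]
  trp <- lapply(keep, function(s) chars[s + model@trpColumns - 1L] == "W")
  data.frame(protein_id = proteinId, start = keep,
             end = keep + w - 1L, score = scores[keep],
             trp_ok = vapply(trp, all, logical(1)),
             n_trp = vapply(trp, sum, integer(1)))
}

#' @noRd
.cachedThreshold <- function(model) {
  key <- paste0("thr_", model@width, "_", round(sum(model@logOdds), 6))
  if (is.null(.mybkit_cache[[key]]))
    .mybkit_cache[[key]] <- calibrateScoreThreshold(model)
  .mybkit_cache[[key]]
}

#' Classify proteins by ordered MYB repeat count and filter incomplete ORFs
#'
#' Proteins lacking an initial methionine or containing an internal stop
#' (`*`) are excluded with reason `"incomplete ORF"`. The rest are scanned
#' with the R2 and R3 models, overlaps resolved greedily by score, and
#' labelled by ordered repeat count: `none`, `1R`, `R2R3` (an R2 hit
#' strictly before a non-overlapping R3 hit with gap at most `maxGap`
#' residues), `2R` (two repeats violating that arrangement), `3R`, `4R`.
#'
#' @param proteins Named character vector or AAStringSet.
#' @param r2Model,r3Model [RepeatModel-class] objects for the two repeats.
#' @param maxGap Maximum residue gap between R2 end and R3 start
#'   (default 25).
#' @param scoreThresholdR2,scoreThresholdR3 Scan thresholds (default
#'   calibrated).
#' @return list with `classification` (data.frame: `protein_id`, `label`,
#'   `excluded`, `reason`), `hits` (all retained hits with `repeat_type`),
#'   and `r2r3` (character vector of protein ids labelled R2R3).
#' @export
classifyRepeats <- function(proteins, r2Model, r3Model, maxGap = 25,
                            scoreThresholdR2 = NULL,
                            scoreThresholdR3 = NULL) {
  seqs <- .asNamedChar(proteins)
  if (is.null(names(seqs))) names(seqs) <- paste0("p", seq_along(seqs))
  # calibrate thresholds against the scanned set's own composition
  bg <- .residueFreq(seqs)
  if (is.null(scoreThresholdR2))
    scoreThresholdR2 <- calibrateScoreThreshold(r2Model, background = bg)
  if (is.null(scoreThresholdR3))
    scoreThresholdR3 <- calibrateScoreThreshold(r3Model, background = bg)
  rows <- list(); hits <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    body <- sub("\\*$", "", s)
    if (!startsWith(body, "M") || grepl("*", body, fixed = TRUE)) {
      rows[[id]] <- data.frame(protein_id = id, label = NA_character_,
                               excluded = TRUE, reason = "incomplete ORF",
                               stringsAsFactors = FALSE)
      next
    }
    h2 <- scanProtein(body, r2Model, scoreThresholdR2, id)
    h3 <- scanProtein(body, r3Model, scoreThresholdR3, id)
    if (nrow(h2)) h2$repeat_type <- "R2"
    if (nrow(h3)) h3$repeat_type <- "R3"
    all <- rbind(h2, h3)
    # resolve overlaps between the two scans greedily by score
    if (nrow(all) > 1) {
      all <- all[base::order(-all$score, all$start), ]
      taken <- integer(0); sel <- logical(nrow(all))
      for (i in seq_len(nrow(all))) {
        span <- all$start[i]:all$end[i]
        if (length(intersect(span, taken)) == 0) {
          sel[i] <- TRUE; taken <- c(taken, span)
        }
      }
      all <- all[sel, ]
    }
    all <- all[base::order(all$start), ]
    n <- nrow(all)
    label <- if (n == 0) "none"
    else if (n == 1) "1R"
    else if (n == 2) {
      gap <- all$start[2] - all$end[1] - 1L
      if (all$repeat_type[1] == "R2" && all$repeat_type[2] == "R3" &&
          gap >= 0 && gap <= maxGap) "R2R3" else "2R"
    }
    else if (n == 3) "3R" else "4R"
    rows[[id]] <- data.frame(protein_id = id, label = label,
                             excluded = FALSE, reason = NA_character_,
                             stringsAsFactors = FALSE)
    if (n > 0) hits[[id]] <- all
  }
  classification <- do.call(rbind, rows)
  rownames(classification) <- NULL
  hitTab <- if (length(hits)) do.call(rbind, hits) else
    data.frame(protein_id = character(0), start = integer(0),
               end = integer(0), score = numeric(0), trp_ok = logical(0),
               n_trp = integer(0), repeat_type = character(0))
  rownames(hitTab) <- NULL
  list(classification = classification, hits = hitTab,
       r2r3 = classification$protein_id[!classification$excluded &
                                          classification$label == "R2R3"])
}
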