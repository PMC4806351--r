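#' Back-translate a pairwise protein alignment to a codon alignment
#'
#' Each aligned residue column is expanded to its source codon; protein gaps
#' become codon gaps (`"---"`). Columns containing a gap or a stop codon in
#' either sequence are dropped from the comparable set used for Ka/Ks.
#'
#' @param alignedA,alignedB Aligned protein strings (equal length, `-` gaps),
#'   e.g. from [globalAlign()].
#' @param cdsA,cdsB The coding sequences (character or
#'   [Biostrings::DNAString]); a terminal stop codon is allowed and ignored.
#' @return A list with `codonsA`, `codonsB` (comparable codons, gap/stop
#'   columns removed), the full expanded alignments `alignmentA`,
#'   `alignmentB`, and `nDropped`.
#' @export
codonAlign <- function(alignedA, alignedB, cdsA, cdsB) {
  alignedA <- as.character(alignedA); alignedB <- as.character(alignedB)
  if (nchar(alignedA) != nchar(alignedB))
    stop("aligned sequences differ in length")
  code <- .codonTables()$code
  expand <- function(aligned, cds, what) {
    codons <- .checkCds(cds, what)
    if (code[[codons[length(codons)]]] == "*") codons <- codons[-length(codons)]
    aa <- strsplit(aligned, "")[[1]]
    res <- aa[aa != "-"]
    if (length(res) != length(codons))
      stop("translation of ", what, " does not match its aligned protein ",
           "(", length(codons), " codons vs ", length(res), " residues)")
    trans <- code[codons]
    bad <- which(trans != res)
    if (length(bad) > 0)
      stop("translation mismatch in ", what, " at residue ", bad[1],
           ": codon ", codons[bad[1]], " encodes ", trans[bad[1]],
           " but alignment has ", res[bad[1]])
    out <- rep("---", length(aa))
    out[aa != "-"] <- codons
    out
  }
  ca <- expand(alignedA, cdsA, "cdsA")
  cb <- expand(alignedB, cdsB, "cdsB")
  stops <- .codonTables()$stops
  keep <- ca != "---" & cb != "---" & !(ca %in% stops) & !(cb %in% stops)
  list(codonsA = ca[keep], codonsB = cb[keep],
       alignmentA = ca, alignmentB = cb, nDropped = sum(!keep))
}

#' Nei-Gojobori (1986) Ka/Ks estimation on a codon alignment
#'
#' Counts synonymous and nonsynonymous sites per codon as fractional site
#' counts (stop-creating changes excluded, see [synonymousSites()]), averages
#' the synonymous/nonsynonymous difference counts of multi-hit codons over
#' all stop-free mutational pathways with equal weights, and applies the
#' Jukes-Cantor correction `d = -3/4 log(1 - 4p/3)` to the proportions
#' `p_S = sd/S` and `p_N = nd/N`.
#'
#' @param codonsA,codonsB Character vectors of comparable codons (equal
#'   length, no gaps or stops), e.g. from [codonAlign()].
#' @return A list of class `KaKsResult`: `ka`, `ks`, `ratio`, `sSites`,
#'   `nSites`, `sd`, `nd`, `pS`, `pN`, `nCodons`, `saturated`. Saturated
#'   comparisons (`p >= 3/4`) carry `NA` for the affected rate.
#' @export
ng86 <- function(codonsA, codonsB) {
  if (length(codonsA) != length(codonsB))
    stop("codon vectors differ in length")
  if (length(codonsA) < 1) stop("no comparable codons")
  codonsA <- toupper(codonsA); codonsB <- toupper(codonsB)
  pt <- .pathwayTables()
  if (any(!codonsA %in% pt$sense) || any(!codonsB %in% pt$sense))
    stop("codon alignment contains gaps or stop codons")
  ia <- match(codonsA, pt$sense); ib <- match(codonsB, pt$sense)
  sd <- sum(pt$sd[cbind(ia, ib)])
  nd <- sum(pt$nd[cbind(ia, ib)])
  sA <- sum(synonymousSites(codonsA)); sB <- sum(synonymousSites(codonsB))
  S <- (sA + sB) / 2
  N <- 3 * length(codonsA) - S
  pS <- if (S > 0) sd / S else 0
  pN <- if (N > 0) nd / N else 0
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  ks <- jc(pS); ka <- jc(pN)
  res <- list(ka = ka, ks = ks,
              ratio = if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_,
              sSites = S, nSites = N, sd = sd, nd = nd, pS = pS, pN = pN,
              nCodons = length(codonsA),
              saturated = is.na(ka) || is.na(ks))
  class(res) <- "KaKsResult"
  res
}

#' @export
print.KaKsResult <- function(x, ...) {
  cat("NG86 Ka/Ks over", x$nCodons, "codons\n")
  cat(sprintf("  Ka = %s  Ks = %s  Ka/Ks = %s%s\n",
              format(x$ka, digits = 4), format(x$ks, digits = 4),
              format(x$ratio, digits = 4),
              if (x$saturated) "  [saturated]" else ""))
  cat(sprintf("  S = %.2f  N = %.2f  sd = %.3f  nd = %.3f\n",
              x$sSites, x$nSites, x$sd, x$nd))
  invisible(x)
}

#' Ka/Ks for a pair of coding sequences
#'
#' Convenience wrapper: aligns the translated proteins with [globalAlign()],
#' back-translates with [codonAlign()] and estimates rates with [ng86()].
#'
#' @param cdsA,cdsB Coding sequences (terminal stop allowed).
#' @inheritParams globalAlign
#' @return A `KaKsResult` (see [ng86()]).
#' @export
kaKsPair <- function(cdsA, cdsB, gapOpening = 10, gapExtension = 0.5) {
  pa <- translateCds(cdsA)
  pb <- translateCds(cdsB)
  aln <- globalAlign(pa, pb, gapOpening = gapOpening,
                     gapExtension = gapExtension)
  ca <- codonAlign(aln$alignedA, aln$alignedB, cdsA, cdsB)
  ng86(ca$codonsA, ca$codonsB)
}

#' Translate a CDS to protein (terminal stop removed)
#'
#' @param cds Coding sequence; must have no internal stop codon.
#' @return Single protein string.
#' @export
translateCds <- function(cds) {
  codons <- .checkCds(cds)
  code <- .codonTables()$code
  aa <- code[codons]
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

#' Molecular-clock dating of a duplication event
#'
#' Converts a synonymous divergence into an age via `T = Ks / (2 lambda)`,
#' reported in million years (Mya). The default clock rate is
#' `lambda = 1.5e-8` synonymous substitutions per site per year, the rate
#' used for *Gossypium raimondii*.
#'
#' @param ks Numeric vector of synonymous divergences (substitutions per
#'   synonymous site); `NA` (saturated) propagates.
#' @param lambda Clock rate, substitutions/synonymous site/year.
#' @return Ages in Mya.
#' @export
dateDuplication <- function(ks, lambda = 1.5e-8) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0)
    stop("lambda must be a single positive number")
  if (any(ks < 0, na.rm = TRUE)) stop("ks must be non-negative")
  ks / (2 * lambda) * 1e-6
}

#' Selection-regime label from a Ka/Ks ratio
#'
#' Uses 0.5 as the operational cut-off for candidate positive selection:
#' ratios below 0.5 are labelled purifying, ratios in `[0.5, 1]` candidate
#' positive, ratios above 1 positive.
#'
#' @param ratio Numeric vector of Ka/Ks ratios.
#' @return Character vector of labels.
#' @export
selectionLabel <- function(ratio) {
  out <- rep(NA_character_, length(ratio))
  out[!is.na(ratio) & ratio < 0.5] <- "purifying"
  out[!is.na(ratio) & ratio >= 0.5 & ratio <= 1] <- "candidate_positive"
  out[!is.na(ratio) & ratio > 1] <- "positive"
  out
}
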