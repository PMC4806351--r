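.AA_ALPHABET24 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
                    "B", "Z", "X", "*")

#' @noRd
.blosum62 <- function() {
  if (is.null(.mybkit_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .mybkit_cache$blosum62 <- e$BLOSUM62
  }
  .mybkit_cache$blosum62
}

#' @noRd
.checkProtein <- function(x, what = "sequence") {
  chars <- strsplit(toupper(as.character(x)), "")[[1]]
  bad <- which(!chars %in% .AA20)
  if (length(bad) > 0)
    stop(what, " has illegal residue '", chars[bad[1]], "' at position ",
         bad[1])
  chars
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties (BLOSUM62,
#' gap open 10, gap extend 0.5 by default, ClustalW-like), computed with
#' Biostrings. Returns the aligned strings together with the identity and
#' coverage statistics used by the duplicate-pair detector: identity is the
#' fraction of aligned (non-gap-pair) columns with equal residues; coverage
#' of each sequence is the number of aligned residue-pair columns divided by
#' its length.
#'
#' @param a,b Protein sequences (character or [Biostrings::AAString]).
#' @param substitutionMatrix Substitution matrix (default BLOSUM62).
#' @param gapOpening,gapExtension Affine gap penalties (positive costs).
#' @return A list of class `PairwiseAlignment`: `alignedA`, `alignedB`,
#'   `score`, `identity`, `coverageA`, `coverageB`, `nAlignedColumns`.
#' @export
globalAlign <- function(a, b, substitutionMatrix = NULL,
                        gapOpening = 10, gapExtension = 0.5) {
  ca <- .checkProtein(a, "a")
  cb <- .checkProtein(b, "b")
  if (is.null(substitutionMatrix)) substitutionMatrix <- .blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(ca, collapse = "")),
    Biostrings::AAString(paste(cb, collapse = "")),
    substitutionMatrix = substitutionMatrix,
    gapOpening = gapOpening, gapExtension = gapExtension,
    type = "global")
  alnA <- as.character(Biostrings::alignedPattern(pa))
  alnB <- as.character(Biostrings::alignedSubject(pa))
  xa <- strsplit(alnA, "")[[1]]
  xb <- strsplit(alnB, "")[[1]]
  both <- xa != "-" & xb != "-"
  nAligned <- sum(both)
  ident <- if (nAligned > 0) sum(xa[both] == xb[both]) / nAligned else 0
  res <- list(alignedA = alnA, alignedB = alnB,
              score = Biostrings::score(pa),
              identity = ident,
              coverageA = nAligned / length(ca),
              coverageB = nAligned / length(cb),
              nAlignedColumns = nAligned)
  class(res) <- "PairwiseAlignment"
  res
}

#' @export
print.PairwiseAlignment <- function(x, ...) {
  cat("Global protein alignment (score ", format(x$score, digits = 5),
      ", identity ", sprintf("%.3f", x$identity), ")\n", sep = "")
  cat(" ", x$alignedA, "\n ", x$alignedB, "\n", sep = "")
  invisible(x)
}

# Convert a set of aligned sequences (character vector) to a 20 x L
# frequency profile. Gap characters contribute nothing to a column.
#' @noRd
.profileOf <- function(aligned) {
  mat <- do.call(rbind, strsplit(aligned, ""))
  L <- ncol(mat)
  prof <- matrix(0, nrow = 20, ncol = L, dimnames = list(.AA20, NULL))
  n <- nrow(mat)
  for (j in seq_len(L)) {
    tb <- table(factor(mat[, j], levels = .AA20))
    prof[, j] <- as.numeric(tb) / n
  }
  prof
}

#' @noRd
.mergeByPath <- function(alignedA, alignedB, pathA, pathB) {
  gapRow <- function(seqs, path) {
    vapply(seqs, function(s) {
      chars <- strsplit(s, "")[[1]]
      out <- rep("-", length(path))
      out[path > 0] <- chars[path[path > 0]]
      paste(out, collapse = "")
    }, character(1))
  }
  c(gapRow(alignedA, pathA), gapRow(alignedB, pathB))
}

#' Progressive multiple protein alignment
#'
#' A compact progressive aligner: pairwise identity distances from
#' [globalAlign()] build a UPGMA guide tree; profiles are then merged in
#' guide-tree order by profile-profile global alignment with affine gap
#' penalties (sum-of-pairs BLOSUM62 column scores). Two sequences reduce
#' exactly to [globalAlign()].
#'
#' @param seqs Named character vector or [Biostrings::AAStringSet] of
#'   unaligned protein sequences (at least 2; a single sequence is returned
#'   unchanged).
#' @inheritParams globalAlign
#' @return Named character vector of aligned sequences (equal lengths), in
#'   input order.
#' @export
progressiveMSA <- function(seqs, substitutionMatrix = NULL,
                           gapOpening = 10, gapExtension = 0.5) {
  seqs <- vapply(.asNamedChar(seqs), toupper, character(1))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  if (n == 0) stop("no sequences")
  if (n == 1) return(seqs)
  if (is.null(substitutionMatrix)) substitutionMatrix <- .blosum62()
  if (n == 2) {
    pa <- globalAlign(seqs[1], seqs[2], substitutionMatrix,
                      gapOpening, gapExtension)
    return(stats::setNames(c(pa$alignedA, pa$alignedB), names(seqs)))
  }
  # Guide tree from pairwise identity distances
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pa <- globalAlign(seqs[i], seqs[j], substitutionMatrix,
                        gapOpening, gapExtension)
      d[i, j] <- d[j, i] <- 1 - pa$identity
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  S <- substitutionMatrix[.AA20, .AA20]
  # Merge in hclust order; clusters[[k]] holds aligned members
  nodes <- vector("list", n + nrow(hc$merge))
  for (i in seq_len(n)) nodes[[i]] <- seqs[i]
  for (k in seq_len(nrow(hc$merge))) {
    pick <- function(m) if (m < 0) nodes[[-m]] else nodes[[n + m]]
    A <- pick(hc$merge[k, 1]); B <- pick(hc$merge[k, 2])
    pA <- .profileOf(A); pB <- .profileOf(B)
    path <- profile_align_cpp(pA, pB, S, gapOpening, gapExtension)
    nodes[[n + k]] <- .mergeByPath(A, B, path$pathA, path$pathB)
  }
  out <- nodes[[n + nrow(hc$merge)]]
  out[names(seqs)]
}
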