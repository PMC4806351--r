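# Genetic-code lookup tables shared by the NG86 estimator and the sequence
# simulator. Everything is precomputed once per session and cached.

.mybkit_cache <- new.env(parent = emptyenv())

.NT <- c("A", "C", "G", "T")
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.geneticCode <- function() {
  gc <- Biostrings::GENETIC_CODE
  as.character(gc)[match(.allCodons(), names(gc))] |>
    stats::setNames(.allCodons())
}

.allCodons <- function() {
  g <- expand.grid(p3 = .NT, p2 = .NT, p1 = .NT, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

.isTransition <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}

#' @noRd
.codonTables <- function() {
  if (!is.null(.mybkit_cache$codon)) return(.mybkit_cache$codon)
  codons <- .allCodons()
  code <- .geneticCode()
  stops <- names(code)[code == "*"]

  # Per-codon NG86 synonymous site count: at each position, the fraction of
  # non-stop single-nucleotide changes that preserve the amino acid. Stop
  # changes are excluded from numerator and denominator so that per position
  # syn + nonsyn fractions always total 1 (hence S + N = 3 per codon).
  synSites <- stats::setNames(numeric(length(codons)), codons)
  # Mutation catalogue: for each codon, 9 single-nt changes with class
  # 1 = synonymous, 2 = nonsynonymous, 3 = stop-creating, plus transition
  # flag and the mutant codon.
  mut <- stats::setNames(vector("list", length(codons)), codons)
  for (cd in codons) {
    aa <- code[[cd]]
    nts <- strsplit(cd, "")[[1]]
    s <- 0
    rows <- list()
    for (pos in 1:3) {
      alts <- setdiff(.NT, nts[pos])
      syn <- 0L; nonstop <- 0L
      for (alt in alts) {
        m <- nts; m[pos] <- alt
        mcd <- paste(m, collapse = "")
        maa <- code[[mcd]]
        cls <- if (maa == "*") 3L else if (maa == aa) 1L else 2L
        if (cls != 3L) {
          nonstop <- nonstop + 1L
          if (cls == 1L) syn <- syn + 1L
        }
        rows[[length(rows) + 1L]] <- list(pos = pos, alt = alt, mutant = mcd,
                                          class = cls,
                                          transition = .isTransition(nts[pos], alt))
      }
      if (aa != "*" && nonstop > 0L) s <- s + syn / nonstop
    }
    synSites[[cd]] <- if (aa == "*") NA_real_ else s
    mut[[cd]] <- do.call(rbind, lapply(rows, function(r) {
      data.frame(pos = r$pos, alt = r$alt, mutant = r$mutant,
                 class = r$class, transition = r$transition,
                 stringsAsFactors = FALSE)
    }))
  }
  .mybkit_cache$codon <- list(code = code, stops = stops,
                              synSites = synSites, mutations = mut)
  .mybkit_cache$codon
}

# Average synonymous/nonsynonymous difference counts between two codons by
# NG86 pathway averaging: enumerate every ordering of the differing
# positions, drop orderings that pass through a stop codon, average the
# per-step classifications over the remaining orderings with equal weight.
#' @noRd
.pathwayCounts <- function(c1, c2) {
  tab <- .codonTables()
  code <- tab$code
  n1 <- strsplit(c1, "")[[1]]
  n2 <- strsplit(c2, "")[[1]]
  diffs <- which(n1 != n2)
  k <- length(diffs)
  if (k == 0L) return(c(sd = 0, nd = 0))
  orderings <- switch(as.character(k),
    "1" = list(diffs),
    "2" = list(diffs, rev(diffs)),
    "3" = {
      p <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(p, function(i) diffs[i])
    })
  walk <- function(ord, allowStops) {
    cur <- n1
    sd <- 0; nd <- 0
    for (pos in ord) {
      prev <- paste(cur, collapse = "")
      cur[pos] <- n2[pos]
      now <- paste(cur, collapse = "")
      if (code[[now]] == "*" && !allowStops && now != c2) return(NULL)
      if (code[[now]] == code[[prev]]) sd <- sd + 1 else nd <- nd + 1
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(orderings, walk, allowStops = FALSE))
  if (length(res) == 0L) {
    # No stop-free route (guarded; not expected for sense-sense pairs):
    # fall back to averaging over all orderings.
    res <- lapply(orderings, walk, allowStops = TRUE)
  }
  colMeans(do.call(rbind, res))
}

# 64x64 lookup matrices of pathway-averaged sd/nd, built lazily.
#' @noRd
.pathwayTables <- function() {
  if (!is.null(.mybkit_cache$path)) return(.mybkit_cache$path)
  tab <- .codonTables()
  sense <- names(tab$code)[tab$code != "*"]
  n <- length(sense)
  sd <- matrix(0, n, n, dimnames = list(sense, sense))
  nd <- matrix(0, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      pc <- .pathwayCounts(sense[i], sense[j])
      sd[i, j] <- sd[j, i] <- pc[["sd"]]
      nd[i, j] <- nd[j, i] <- pc[["nd"]]
    }
  }
  .mybkit_cache$path <- list(sd = sd, nd = nd, sense = sense)
  .mybkit_cache$path
}

#' Split a coding sequence into codons
#'
#' @param cds A single character string or [Biostrings::DNAString]; length
#'   must be a multiple of 3.
#' @return Character vector of codons.
#' @export
splitCodons <- function(cds) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3 != 0)
    stop("CDS length is not a multiple of 3")
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

#' @noRd
.checkCds <- function(cds, what = "cds") {
  codons <- splitCodons(cds)
  code <- .codonTables()$code
  if (any(!codons %in% names(code)))
    stop(what, " contains non-ACGT characters")
  aa <- code[codons]
  internal <- aa[-length(aa)]
  if (any(internal == "*"))
    stop(what, " contains an internal stop codon at codon ",
         which(internal == "*")[1])
  codons
}

#' NG86 synonymous site count of a codon
#'
#' Fraction of single-nucleotide changes at each position that are
#' synonymous, summed over the three positions; stop-creating changes are
#' excluded from both numerator and denominator, so the synonymous and
#' nonsynonymous site counts of a codon always total 3.
#'
#' @param codons Character vector of codons.
#' @return Numeric vector of synonymous site counts, one per codon.
#' @export
synonymousSites <- function(codons) {
  tab <- .codonTables()
  s <- tab$synSites[toupper(codons)]
  unname(s)
}

# as.character that preserves names (plain character vectors lose names
# under as.character; XStringSet keeps them)
#' @noRd
.asNamedChar <- function(x) {
  nm <- names(x)
  out <- as.character(x)
  if (is.null(names(out)) && !is.null(nm)) names(out) <- nm
  out
}
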