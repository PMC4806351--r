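# Independent oracles used by the tests: these deliberately re-derive
# quantities from first principles (recursion + the raw genetic code) and
# never call the package's own counting machinery.

.oracleCode <- stats::setNames(as.list(as.character(Biostrings::GENETIC_CODE)),
                               names(Biostrings::GENETIC_CODE))

oracleAA <- function(codon) .oracleCode[[codon]]

# Synonymous site count of a codon: per position, synonymous single-nt
# changes over non-stop single-nt changes.
oracleSynSites <- function(codon) {
  nts <- strsplit(codon, "")[[1]]
  aa <- oracleAA(codon)
  total <- 0
  for (pos in 1:3) {
    syn <- 0; nonstop <- 0
    for (alt in setdiff(c("A", "C", "G", "T"), nts[pos])) {
      m <- nts; m[pos] <- alt
      maa <- oracleAA(paste(m, collapse = ""))
      if (maa != "*") {
        nonstop <- nonstop + 1
        if (maa == aa) syn <- syn + 1
      }
    }
    if (nonstop > 0) total <- total + syn / nonstop
  }
  total
}

# Pathway-averaged (sd, nd) between two sense codons: recursive enumeration
# of all orderings of the differing positions; paths through stop codons
# are discarded and the rest averaged with equal weight (all paths if every
# ordering is blocked).
oraclePathCounts <- function(c1, c2) {
  t1 <- strsplit(c1, "")[[1]]
  t2 <- strsplit(c2, "")[[1]]
  diffs <- which(t1 != t2)
  if (length(diffs) == 0) return(c(sd = 0, nd = 0))
  acc <- list()
  rec <- function(cur, remaining, sd, nd, blocked) {
    if (length(remaining) == 0) {
      acc[[length(acc) + 1]] <<- list(sd = sd, nd = nd, blocked = blocked)
      return(invisible())
    }
    for (pos in remaining) {
      nxt <- cur; nxt[pos] <- t2[pos]
      a0 <- oracleAA(paste(cur, collapse = ""))
      a1 <- oracleAA(paste(nxt, collapse = ""))
      isStop <- a1 == "*" && length(remaining) > 1
      rec(nxt, setdiff(remaining, pos),
          sd + as.numeric(a1 == a0), nd + as.numeric(a1 != a0),
          blocked || isStop)
    }
    invisible()
  }
  rec(t1, diffs, 0, 0, FALSE)
  ok <- Filter(function(p) !p$blocked, acc)
  use <- if (length(ok) > 0) ok else acc
  c(sd = mean(vapply(use, function(p) p$sd, numeric(1))),
    nd = mean(vapply(use, function(p) p$nd, numeric(1))))
}

# Full NG86 from the oracle pieces, for two gap-free codon vectors.
oracleNg86 <- function(codonsA, codonsB) {
  sd <- 0; nd <- 0
  for (i in seq_along(codonsA)) {
    pc <- oraclePathCounts(codonsA[i], codonsB[i])
    sd <- sd + pc[["sd"]]; nd <- nd + pc[["nd"]]
  }
  S <- (sum(vapply(codonsA, oracleSynSites, numeric(1))) +
          sum(vapply(codonsB, oracleSynSites, numeric(1)))) / 2
  N <- 3 * length(codonsA) - S
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(sd = sd, nd = nd, S = S, N = N,
       ks = jc(sd / S), ka = jc(nd / N))
}

# Exhaustive global affine-gap alignment score for tiny sequences:
# recursion over (consumed a, consumed b, previous move), gap of length k
# costing open + k * extend.
bruteForceAlignScore <- function(a, b, sub, gapOpen = 10, gapExt = 0.5) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  la <- length(ca); lb <- length(cb)
  best <- -Inf
  rec <- function(i, j, prev, sc) {
    if (i == la && j == lb) {
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i < la && j < lb)
      rec(i + 1, j + 1, "M", sc + sub[ca[i + 1], cb[j + 1]])
    if (i < la)
      rec(i + 1, j, "X", sc - (if (prev == "X") gapExt else gapOpen + gapExt))
    if (j < lb)
      rec(i, j + 1, "Y", sc - (if (prev == "Y") gapExt else gapOpen + gapExt))
    invisible()
  }
  rec(0, 0, "", 0)
  best
}

# Random sense codons (uniform over the 61 sense codons).
randomSenseCodons <- function(n) {
  sense <- names(Biostrings::GENETIC_CODE)[
    as.character(Biostrings::GENETIC_CODE) != "*"]
  sample(sense, n, replace = TRUE)
}

# Random CDS string: ATG + sense codons + TAA.
randomCdsString <- function(nCodons) {
  paste(c("ATG", randomSenseCodons(nCodons - 1), "TAA"), collapse = "")
}

# Shared default simulation, built once per test run.
.fixture_env <- new.env()
sharedSim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- simulateFamily(simulationConfig(seed = 42L))
  .fixture_env$sim
}

# Cherry-structured family: 5 deeply diverged lineages radiating from the
# founder, each then duplicated shallowly once, so every shallow pair is a
# true sibling pair (cherry) in the family tree. The founder itself gets no
# shallow partner: it sits at the radiation point with a zero-length branch,
# where a cherry bipartition is not identifiable.
cherryConfig <- function(seed = 77L) {
  ev <- data.frame(
    type = c(rep("segmental", 5), rep("tandem", 5)),
    targetKs = c(rep(0.9, 5), rep(0.15, 5)),
    targetKaKs = c(rep(0.2, 5), rep(0.3, 5)),
    source = c(1L, 1L, 1L, 1L, 1L, 2L, 3L, 4L, 5L, 6L))
  simulationConfig(duplicationEvents = ev, seed = seed)
}

# The 20 standard amino acids (local copy for test data generation).
.mybkit_aa <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
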