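#' Mutate a coding sequence to target NG86 divergences
#'
#' Places synonymous and nonsynonymous single-nucleotide substitutions on a
#' CDS so that the expected NG86 estimates between input and output equal
#' the targets: the target Ks is converted back through the Jukes-Cantor
#' correction to an expected proportion of synonymous differences
#' `p_S = 3/4 (1 - exp(-4 Ks / 3))`, multiplied by the sequence's NG86
#' synonymous site count, and realized as that many synonymous changes (the
#' fractional part by a Bernoulli draw); nonsynonymous changes follow the
#' same construction with `Ka = Ks x Ka/Ks`. Substitution sites are drawn by
#' per-site multinomial sampling conditioned on site class; codons are hit
#' at most once while untouched codons remain (so NG86 pathway counting
#' recovers the planted substitution counts exactly; only extreme targets
#' reuse codons, up to two hits). Candidate changes are weighted by a
#' transition:transversion bias, and stop-creating changes are never
#' proposed, so the output never contains an internal stop codon.
#'
#' @param cds Coding sequence (character or DNAString), length a multiple
#'   of 3, standard code, no internal stop; a terminal stop codon is kept
#'   unchanged.
#' @param targetKs Target synonymous divergence (substitutions per
#'   synonymous site), `>= 0`.
#' @param targetKaKs Target Ka/Ks ratio in `[0, 1.5]`.
#' @param transitionBias Weight of transitions relative to transversions
#'   (default 2).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param immutableCodons Integer indices of codons that must not be
#'   touched (e.g. the start codon).
#' @return Mutated CDS string with attributes `nSyn` and `nNonsyn`
#'   (realized substitution counts).
#' @export
mutateCDS <- function(cds, targetKs, targetKaKs, transitionBias = 2,
                      seed = NULL, immutableCodons = integer(0)) {
  if (!is.numeric(targetKs) || length(targetKs) != 1 || is.na(targetKs) ||
      !is.finite(targetKs) || targetKs < 0)
    stop("targetKs must be a single finite non-negative number")
  if (!is.numeric(targetKaKs) || length(targetKaKs) != 1 ||
      is.na(targetKaKs) || targetKaKs < 0 || targetKaKs > 1.5)
    stop("targetKaKs must be in [0, 1.5]")
  codons <- .checkCds(cds)
  tab <- .codonTables()
  hasStop <- tab$code[[codons[length(codons)]]] == "*"
  nSense <- length(codons) - as.integer(hasStop)
  sense <- codons[seq_len(nSense)]

  S <- sum(synonymousSites(sense))
  N <- 3 * nSense - S
  jcInv <- function(d) 0.75 * (1 - exp(-4 * d / 3))
  pS <- jcInv(targetKs)
  pN <- jcInv(targetKs * targetKaKs)
  if (pS >= 0.75 || pN >= 0.75)
    stop("saturation: target divergence implies p >= 3/4")

  run <- function() {
    frac <- function(m) floor(m) + stats::rbinom(1L, 1L, m - floor(m))
    # Mutation catalogue: 9 candidate single-nt changes per codon. Codons
    # are preferentially mutated at most once, so changes keep the class
    # they were drawn with and the pairwise NG86 counts recover the
    # planted (nSyn, nNon) exactly - no pathway-averaging drift from
    # multi-hit codons. Only when a class runs out of untouched codons
    # (very high divergence) are once-hit codons reused, up to 2 hits,
    # with the catalogue recomputed against the mutated codon.
    pos <- integer(9L * nSense); alt <- character(9L * nSense)
    cls <- integer(9L * nSense); trs <- logical(9L * nSense)
    for (i in seq_len(nSense)) {
      m <- tab$mutations[[sense[i]]]; k <- (i - 1L) * 9L
      pos[k + 1:9] <- m$pos; alt[k + 1:9] <- m$alt
      cls[k + 1:9] <- m$class; trs[k + 1:9] <- m$transition
    }
    blocked <- logical(9L * nSense)
    for (i in intersect(immutableCodons, seq_len(nSense)))
      blocked[(i - 1L) * 9L + 1:9] <- TRUE
    codonHits <- integer(nSense)
    posUsed <- matrix(FALSE, nSense, 3L)
    codonOf <- rep(seq_len(nSense), each = 9L)
    cur <- sense
    wBase <- 1 + (transitionBias - 1) * trs
    # NG86 normalizes by the mean site count of the two sequences, and
    # substitution drifts codon usage (hence S) away from the input.
    # Calibrate the planted counts against the expected post-mutation site
    # counts: per class, the weight-averaged change in synonymous sites per
    # substitution, then a scalar fixed point for (mS, mN).
    sOrig <- synonymousSites(sense)[codonOf]
    sMut <- synonymousSites(mut <- vapply(seq_along(alt), function(k) {
      nts <- strsplit(sense[codonOf[k]], "")[[1]]
      nts[pos[k]] <- alt[k]
      paste(nts, collapse = "")
    }, character(1)))
    dS <- vapply(1:2, function(cl) {
      sel <- cls == cl & !blocked
      if (!any(sel)) return(0)
      stats::weighted.mean(sMut[sel] - sOrig[sel], wBase[sel])
    }, numeric(1))
    mS <- pS * S; mN <- pN * N
    for (it in 1:6) {
      drift <- (mS * dS[1] + mN * dS[2]) / 2
      mS <- pS * (S + drift)
      mN <- pN * (N - drift)
    }
    nSyn <- frac(max(0, mS))
    nNon <- frac(max(0, mN))
    plan <- c(rep(1L, nSyn), rep(2L, nNon))
    plan <- plan[sample.int(length(plan))]
    counts <- c(0L, 0L)
    for (want in plan) {
      ok <- (cls == want) & !blocked & codonHits[codonOf] == 0L
      if (!any(ok))
        ok <- (cls == want) & !blocked & codonHits[codonOf] < 2L &
          !posUsed[cbind(codonOf, pos)]
      if (!any(ok))
        stop("saturation: target divergence not reachable on this sequence")
      w <- wBase * ok
      pick <- sample.int(length(w), 1L, prob = w)
      ci <- codonOf[pick]
      nts <- strsplit(cur[ci], "")[[1]]
      nts[pos[pick]] <- alt[pick]
      cur[ci] <- paste(nts, collapse = "")
      codonHits[ci] <- codonHits[ci] + 1L
      posUsed[ci, pos[pick]] <- TRUE
      counts[want] <- counts[want] + 1L
      # refresh the reused codon's candidates against its mutated state
      m <- tab$mutations[[cur[ci]]]; k <- (ci - 1L) * 9L
      pos[k + 1:9] <- m$pos; alt[k + 1:9] <- m$alt
      cls[k + 1:9] <- m$class; trs[k + 1:9] <- m$transition
      wBase[k + 1:9] <- 1 + (transitionBias - 1) * trs[k + 1:9]
    }
    out <- paste(c(cur, if (hasStop) codons[length(codons)]), collapse = "")
    attr(out, "nSyn") <- counts[1]
    attr(out, "nNonsyn") <- counts[2]
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
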