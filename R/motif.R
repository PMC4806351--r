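# ZOOPS (zero-or-one-occurrence-per-sequence) EM motif discovery - a
# compact MEME-style elicitor for ungapped protein motifs.

#' ZOOPS motif model
#'
#' @slot width Motif width (residues).
#' @slot pwm 20 x width frequency matrix (columns sum to 1).
#' @slot prior Probability that a sequence contains the motif.
#' @slot logLik Final data log-likelihood.
#' @slot objective Per-iteration penalized objective (non-decreasing).
#' @slot significance Log-likelihood-ratio statistic versus the
#'   background-only model (the retention proxy).
#' @slot background Length-20 background frequencies.
#' @slot posteriors list per sequence: `present` (posterior occurrence
#'   probability) and `site` (MAP start position).
#' @slot seed Seed used for the restarts.
#' @export
setClass("MotifModel", representation(
  width = "integer", pwm = "matrix", prior = "numeric", logLik = "numeric",
  objective = "numeric", significance = "numeric", background = "numeric",
  posteriors = "list", seed = "integer"))

setValidity("MotifModel", function(object) {
  msg <- character(0)
  if (any(abs(colSums(object@pwm) - 1) > 1e-8))
    msg <- c(msg, "pwm columns must sum to 1")
  if (object@prior < 0 || object@prior > 1)
    msg <- c(msg, "prior must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MotifModel", function(object) {
  cat("MotifModel: width", object@width,
      "| consensus", motifConsensus(object),
      "| prior", sprintf("%.2f", object@prior),
      "| LLR", sprintf("%.1f", object@significance), "\n")
})

#' @rdname MotifModel-class
#' @param model A `MotifModel`.
#' @export
motifConsensus <- function(model) {
  paste(rownames(model@pwm)[apply(model@pwm, 2, which.max)], collapse = "")
}

#' @noRd
.encodeSeqs <- function(seqs) {
  seqs <- toupper(.asNamedChar(seqs))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  lapply(seqs, function(s) {
    idx <- match(strsplit(s, "")[[1]], .AA20)
    if (any(is.na(idx))) stop("sequence contains non-standard residues")
    idx
  })
}

#' @noRd
.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# One EM run from a given PWM start; returns model pieces.
#' @noRd
.zoopsRun <- function(enc, width, maxIter, tol, pwm0, bg, alpha = 0.1) {
  lbg <- log(bg)
  pwm <- pwm0
  gamma <- 0.5
  nSeq <- length(enc)
  lbgSeq <- vapply(enc, function(e) sum(lbg[e]), numeric(1))
  objective <- numeric(0)
  zs <- NULL
  repeat {
    lpwm <- log(pwm)
    # E-step: per sequence, log odds of a site at each start vs background
    stats <- lapply(enc, function(e) {
      m <- length(e) - width + 1L
      lr <- vapply(seq_len(m), function(s) {
        win <- e[s:(s + width - 1L)]
        sum(lpwm[cbind(win, seq_len(width))]) - sum(lbg[win])
      }, numeric(1))
      lr
    })
    # responsibilities and log-likelihood
    ll <- 0
    zs <- vector("list", nSeq)
    for (i in seq_len(nSeq)) {
      lr <- stats[[i]]
      m <- length(lr)
      lNum <- log(gamma / m) + lr          # site terms (relative to bg)
      l0 <- log(1 - gamma)                  # no-site term
      denom <- .logSumExp(c(l0, lNum))
      ll <- ll + lbgSeq[i] + denom
      zs[[i]] <- list(site = exp(lNum - denom), none = exp(l0 - denom))
    }
    obj <- ll + sum(alpha * log(pwm))
    objective <- c(objective, obj)
    it <- length(objective)
    if (it > 1 && objective[it] - objective[it - 1] < tol) break
    if (it >= maxIter) break
    # M-step
    counts <- matrix(0, 20, width)
    zTot <- 0
    for (i in seq_len(nSeq)) {
      e <- enc[[i]]; z <- zs[[i]]$site
      m <- length(z)
      for (s in seq_len(m)) {
        if (z[s] < 1e-12) next
        win <- e[s:(s + width - 1L)]
        idx <- cbind(win, seq_len(width))
        counts[idx] <- counts[idx] + z[s]
      }
      zTot <- zTot + sum(z)
    }
    pwm <- sweep(counts + alpha, 2, colSums(counts) + 20 * alpha, "/")
    # keep the occurrence prior away from 1 so absence stays expressible
    gamma <- min(0.99, max(1e-4, zTot / nSeq))
  }
  ll <- objective[length(objective)] - sum(alpha * log(pwm))
  list(pwm = pwm, gamma = gamma, logLik = ll, objective = objective,
       zs = zs)
}

#' ZOOPS EM motif discovery (single motif)
#'
#' Fits a single ungapped motif under the zero-or-one-occurrence-per-
#' sequence model by expectation-maximization: the E-step computes, per
#' sequence, posterior responsibilities over all start positions plus the
#' "no site" outcome; the M-step re-estimates the position weight matrix
#' (with a small Dirichlet pseudocount) and the occurrence prior. The best
#' of `nStarts` seeded restarts (each initialized from a random data
#' window) is returned. The penalized objective is non-decreasing across
#' iterations; a decrease beyond rounding noise is an error.
#'
#' @param seqs At least 2 protein sequences, each at least `width` long.
#' @param width Motif width.
#' @param nStarts Number of EM restarts (default 5).
#' @param maxIter Maximum EM iterations per start (default 100).
#' @param tol Convergence tolerance on the objective (default 1e-6).
#' @param seed Integer seed.
#' @param background Optional length-20 background frequencies; default
#'   estimated from the input (0-order).
#' @return A [MotifModel-class].
#' @export
zoopsEM <- function(seqs, width, nStarts = 5, maxIter = 100, tol = 1e-6,
                    seed = 1L, background = NULL) {
  enc <- .encodeSeqs(seqs)
  if (length(enc) < 2) stop("need at least 2 sequences")
  if (any(vapply(enc, length, integer(1)) < width))
    stop("width exceeds the shortest sequence")
  if (is.null(background)) {
    tab <- tabulate(unlist(enc), nbins = 20)
    background <- (tab + 1) / sum(tab + 1)
  }
  runs <- withr::with_seed(seed, {
    lapply(seq_len(nStarts), function(r) {
      i <- sample.int(length(enc), 1L)
      s <- sample.int(length(enc[[i]]) - width + 1L, 1L)
      win <- enc[[i]][s:(s + width - 1L)]
      pwm0 <- matrix(rep(background, width) * 0.4, 20, width)
      pwm0[cbind(win, seq_len(width))] <-
        pwm0[cbind(win, seq_len(width))] + 0.6
      pwm0 <- sweep(pwm0, 2, colSums(pwm0), "/")
      .zoopsRun(enc, width, maxIter, tol, pwm0, background)
    })
  })
  best <- runs[[which.max(vapply(runs, function(r) r$logLik, numeric(1)))]]
  # Phase-shift refinement: EM readily converges to an off-by-one optimum;
  # restart from column-shifted variants of the best PWM and keep the best.
  repeat {
    improved <- FALSE
    for (s in c(-2L, -1L, 1L, 2L)) {
      pwmS <- matrix(rep(background, width), 20, width)
      src <- seq_len(width) - s
      keep <- src >= 1 & src <= width
      pwmS[, keep] <- best$pwm[, src[keep]]
      pwmS <- sweep(pwmS, 2, colSums(pwmS), "/")
      cand <- .zoopsRun(enc, width, maxIter, tol, pwmS, background)
      if (cand$logLik > best$logLik + 1e-9) {
        best <- cand
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  dec <- diff(best$objective)
  if (any(dec < -1e-6 * pmax(1, abs(best$objective[-1]))))
    stop("EM objective decreased; numerical failure")
  ll0 <- sum(vapply(enc, function(e) sum(log(background)[e]), numeric(1)))
  posts <- lapply(seq_along(enc), function(i) {
    z <- best$zs[[i]]
    list(present = 1 - z$none,
         site = if (length(z$site)) which.max(z$site) else NA_integer_)
  })
  names(posts) <- names(enc)
  pwm <- best$pwm
  dimnames(pwm) <- list(.AA20, NULL)
  methods::new("MotifModel", width = as.integer(width), pwm = pwm,
               prior = best$gamma, logLik = best$logLik,
               objective = best$objective,
               significance = best$logLik - ll0,
               background = background, posteriors = posts,
               seed = as.integer(seed))
}

#' Sequential motif discovery with occurrence masking
#'
#' Discovers up to `maxMotifs` motifs: each round fits a ZOOPS model per
#' candidate width, keeps the most significant, stops if its
#' log-likelihood-ratio falls below the retention threshold, and otherwise
#' masks its decoded occurrences (replacing them with background-sampled
#' residues) before the next round.
#'
#' @inheritParams zoopsEM
#' @param maxMotifs Maximum number of motifs (default 20).
#' @param widthRange Candidate widths (default 8).
#' @param retentionThreshold Minimal LLR to retain a motif; `NULL`
#'   calibrates it as the maximum LLR over `nShuffles` column-shuffled
#'   datasets times 1.2.
#' @param nShuffles Shuffled datasets for calibration (default 10).
#' @return list of retained [MotifModel-class] objects, ranked by
#'   significance.
#' @export
discoverMotifs <- function(seqs, maxMotifs = 20, widthRange = 8,
                           retentionThreshold = NULL, nStarts = 3,
                           maxIter = 100, tol = 1e-6, seed = 1L,
                           nShuffles = 10) {
  seqs <- toupper(.asNamedChar(seqs))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (any(nchar(seqs) < max(widthRange)))
    stop("widthRange exceeds the shortest sequence")
  if (is.null(retentionThreshold)) {
    retentionThreshold <- withr::with_seed(seed + 7L, {
      max(vapply(seq_len(nShuffles), function(r) {
        shuf <- vapply(seqs, function(s) {
          ch <- strsplit(s, "")[[1]]
          paste(ch[sample.int(length(ch))], collapse = "")
        }, character(1))
        m <- zoopsEM(shuf, min(widthRange), nStarts = 2,
                     maxIter = 50, tol = tol, seed = seed + r)
        m@significance
      }, numeric(1))) * 1.2
    })
  }
  found <- list()
  cur <- seqs
  for (k in seq_len(maxMotifs)) {
    cands <- lapply(widthRange, function(w)
      zoopsEM(cur, w, nStarts = nStarts, maxIter = maxIter, tol = tol,
              seed = seed + k))
    best <- cands[[which.max(vapply(cands, function(m) m@significance,
                                    numeric(1)))]]
    if (best@significance < retentionThreshold) break
    found[[length(found) + 1L]] <- best
    # mask decoded occurrences
    cur <- withr::with_seed(seed + 1000L + k, {
      vapply(seq_along(cur), function(i) {
        p <- best@posteriors[[i]]
        s <- cur[[i]]
        if (!is.na(p$site) && p$present >= 0.5) {
          repl <- paste(sample(.AA20, best@width, replace = TRUE,
                               prob = best@background), collapse = "")
          substr(s, p$site, p$site + best@width - 1L) <- repl
        }
        s
      }, character(1))
    })
    names(cur) <- names(seqs)
  }
  ord <- base::order(-vapply(found, function(m) m@significance, numeric(1)))
  found[ord]
}

#' Per-sequence motif composition table
#'
#' Posterior-decoded presence (posterior >= 0.5) and MAP position of each
#' motif in each sequence, evaluated under the fitted models.
#'
#' @param models list of [MotifModel-class] objects.
#' @param seqs The sequences to decode (the models' likelihoods are
#'   re-evaluated on these).
#' @return data.frame with one row per sequence x motif: `sequence`,
#'   `motif`, `present`, `posterior`, `start`.
#' @export
motifOccurrence <- function(models, seqs) {
  enc <- .encodeSeqs(seqs)
  rows <- list()
  for (mi in seq_along(models)) {
    m <- models[[mi]]
    lpwm <- log(m@pwm); lbg <- log(m@background)
    for (i in seq_along(enc)) {
      e <- enc[[i]]
      mlen <- length(e) - m@width + 1L
      if (mlen < 1) {
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = names(enc)[i], motif = mi, present = FALSE,
          posterior = 0, start = NA_integer_, stringsAsFactors = FALSE)
        next
      }
      lr <- vapply(seq_len(mlen), function(s) {
        win <- e[s:(s + m@width - 1L)]
        sum(lpwm[cbind(win, seq_len(m@width))]) - sum(lbg[win])
      }, numeric(1))
      lNum <- log(m@prior / mlen) + lr
      denom <- .logSumExp(c(log(1 - m@prior), lNum))
      present <- 1 - exp(log(1 - m@prior) - denom)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = names(enc)[i], motif = mi,
        present = present >= 0.5, posterior = present,
        start = which.max(lr), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Write motif models in a minimal MEME-like text format
#'
#' @param models list of [MotifModel-class].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeMotifs <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MYBKIT MOTIFS", paste("ALPHABET=",
                                      paste(.AA20, collapse = ""))), con)
  for (i in seq_along(models)) {
    m <- models[[i]]
    writeLines(sprintf("MOTIF %d width=%d prior=%.4f llr=%.2f consensus=%s",
                       i, m@width, m@prior, m@significance,
                       motifConsensus(m)), con)
    utils::write.table(t(m@pwm), con, col.names = FALSE,
                       row.names = FALSE, sep = "\t")
  }
  invisible(path)
}
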