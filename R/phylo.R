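#' Poisson-corrected protein distance matrix with pairwise deletion
#'
#' For each sequence pair, columns where either sequence is gapped are
#' excluded (pairwise deletion); the proportion of differing residues `p`
#' over the remaining shared columns is corrected to
#' `d = -log(1 - p)` substitutions per site. Saturated pairs (`p = 1`) are
#' flagged `NA` with a warning.
#'
#' @param msa Named character vector (or [Biostrings::AAStringSet]) of
#'   aligned sequences of equal length.
#' @return Symmetric numeric matrix of distances with taxon dimnames;
#'   saturated entries are `NA`.
#' @export
poissonDistMatrix <- function(msa) {
  msa <- .asNamedChar(msa)
  if (is.null(names(msa))) names(msa) <- paste0("seq", seq_along(msa))
  if (length(unique(nchar(msa))) != 1)
    stop("aligned sequences must have equal length")
  mat <- do.call(rbind, strsplit(toupper(msa), ""))
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  saturated <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(shared))
        stop("sequences ", names(msa)[i], " and ", names(msa)[j],
             " share no ungapped column")
      p <- sum(mat[i, shared] != mat[j, shared]) / sum(shared)
      if (p >= 1) {
        d[i, j] <- d[j, i] <- NA_real_
        saturated <- TRUE
      } else {
        d[i, j] <- d[j, i] <- -log(1 - p)
      }
    }
  }
  if (saturated)
    warning("saturated sequence pair(s) flagged NA in distance matrix")
  d
}

# Clamp negative NJ branch lengths to zero, transferring the deficit to the
# sister branch so that path lengths through the parent are preserved.
#' @noRd
.clampNegativeEdges <- function(tree) {
  for (pass in 1:3) {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0) break
    for (e in neg) {
      deficit <- -tree$edge.length[e]
      tree$edge.length[e] <- 0
      parent <- tree$edge[e, 1]
      sibs <- which(tree$edge[, 1] == parent)
      sibs <- setdiff(sibs, e)
      if (length(sibs) > 0) {
        k <- sibs[1]
        tree$edge.length[k] <- tree$edge.length[k] + deficit
      }
    }
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a distance matrix (via [ape::nj]),
#' followed by MEGA-style handling of negative branch lengths: negative
#' edges are clamped to zero and the deficit is transferred to the sister
#' branch.
#'
#' @param d Symmetric distance matrix (or `dist`) over at least 3 taxa;
#'   entries must be finite (saturated `NA` pairs must be resolved first).
#' @return An unrooted `phylo` tree.
#' @export
njTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  if (any(is.na(d)) || any(!is.finite(d)))
    stop("distance matrix contains NA/non-finite entries")
  tree <- ape::nj(stats::as.dist(d))
  .clampNegativeEdges(tree)
}

#' @noRd
.bootDistance <- function(mat, cols, taxa) {
  sub <- mat[, cols, drop = FALSE]
  n <- nrow(sub)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- sub[i, ] != "-" & sub[j, ] != "-"
      ns <- sum(shared)
      if (ns == 0) { d[i, j] <- d[j, i] <- 0; next }
      p <- sum(sub[i, shared] != sub[j, shared]) / ns
      # Cap saturated replicates just below 1 to keep the replicate usable
      p <- min(p, 1 - 1 / (2 * ns))
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  d
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' Poisson-distance NJ tree for each replicate, and reports for each
#' internal edge of the reference tree the percentage of replicates
#' containing the same bipartition.
#'
#' @param msa Aligned sequences (named character vector or AAStringSet),
#'   at least 4.
#' @param tree Optional reference `phylo`; defaults to
#'   `njTree(poissonDistMatrix(msa))`.
#' @param nReplicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; the replicate stream is reproducible.
#' @return The reference tree with `node.label` set to supports in
#'   `[0, 100]` (`NA` on the root node), plus attribute `seed`.
#' @export
bootstrapSupports <- function(msa, tree = NULL, nReplicates = 1000,
                              seed = 1L) {
  if (nReplicates < 1) stop("nReplicates must be >= 1")
  msa <- .asNamedChar(msa)
  if (is.null(names(msa))) names(msa) <- paste0("seq", seq_along(msa))
  if (length(msa) < 4) stop("bootstrap needs at least 4 sequences")
  mat <- do.call(rbind, strsplit(toupper(msa), ""))
  if (is.null(tree)) tree <- njTree(poissonDistMatrix(msa))
  L <- ncol(mat)
  reps <- withr::with_seed(seed, {
    lapply(seq_len(nReplicates), function(r) {
      cols <- sample.int(L, L, replace = TRUE)
      njTree(.bootDistance(mat, cols, names(msa)))
    })
  })
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  supports <- counts / nReplicates * 100
  tree$node.label <- supports
  attr(tree, "bootstrapSeed") <- seed
  attr(tree, "nReplicates") <- nReplicates
  tree
}

#' Cut a supported tree into subgroups
#'
#' Finds the maximal clades whose subtending edge has bootstrap support at
#' least `minSupport`; every such clade becomes one subgroup, and leaves
#' not covered by any supported clade become singleton subgroups. Labels
#' (`C1`, `C2`, ...) are assigned in tree traversal order.
#'
#' @param tree A `phylo` with numeric `node.label` supports (e.g. from
#'   [bootstrapSupports()]); `NA` supports are treated as unsupported.
#' @param minSupport Minimum support percentage (default 50).
#' @return data.frame with columns `taxon` and `subgroup`.
#' @export
cutSubgroups <- function(tree, minSupport = 50) {
  if (is.null(tree$node.label))
    stop("tree has no node supports; run bootstrapSupports() first")
  ntip <- length(tree$tip.label)
  supports <- suppressWarnings(as.numeric(tree$node.label))
  root <- ntip + 1L
  children <- split(tree$edge[, 2], tree$edge[, 1])
  assignment <- character(ntip)
  counter <- 0L
  tipsUnder <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(children[[as.character(node)]], tipsUnder))
  }
  visit <- function(node) {
    if (node <= ntip) {
      counter <<- counter + 1L
      assignment[node] <<- paste0("C", counter)
      return(invisible())
    }
    sup <- supports[node - ntip]
    if (node != root && !is.na(sup) && sup >= minSupport) {
      counter <<- counter + 1L
      assignment[tipsUnder(node)] <<- paste0("C", counter)
      return(invisible())
    }
    for (ch in children[[as.character(node)]]) visit(ch)
    invisible()
  }
  visit(root)
  data.frame(taxon = tree$tip.label, subgroup = assignment,
             stringsAsFactors = FALSE)
}
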