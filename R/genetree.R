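## Gene-tree estimation from aligned protein sequences: deterministic
## two-threshold alignment trimming, Kimura-corrected distances,
## Saitou-Nei neighbor joining with deterministic tie-breaking, bootstrap
## support, and outgroup rooting.

aln_matrix <- function(aln) {
  if (length(aln) < 2L) stop("alignment needs at least 2 sequences")
  if (length(unique(nchar(aln))) != 1L) {
    stop("alignment rows differ in length")
  }
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(m) <- names(aln)
  m
}

#' Deterministic alignment trimming
#'
#' Replaces manual curation with an explicit rule: a column is kept when
#' its gap fraction is at most \code{max_gap_fraction} and its most
#' frequent residue occurs in at least \code{min_identity} of the rows.
#'
#' @param aln named character vector of equal-length aligned sequences
#'   (gap character \code{-}).
#' @param max_gap_fraction maximum tolerated fraction of gaps per column
#'   (default 0.5).
#' @param min_identity minimum frequency of the majority residue
#'   (default 0.1).
#' @return list with \code{alignment} (trimmed, same names) and
#'   \code{kept} (indices of retained columns, ascending).
#' @export
trim_alignment <- function(aln, max_gap_fraction = 0.5, min_identity = 0.1) {
  stopifnot(max_gap_fraction >= 0, max_gap_fraction <= 1,
            min_identity >= 0, min_identity <= 1)
  m <- aln_matrix(aln)
  n <- nrow(m)
  gap_frac <- colMeans(m == "-")
  maj <- apply(m, 2, function(col) {
    res <- col[col != "-"]
    if (length(res) == 0L) 0 else max(table(res)) / n
  })
  kept <- which(gap_frac <= max_gap_fraction & maj >= min_identity)
  if (length(kept) == 0L) {
    stop("trimming removed every column; relax max_gap_fraction (",
         max_gap_fraction, ") or min_identity (", min_identity, ")")
  }
  trimmed <- apply(m[, kept, drop = FALSE], 1, paste, collapse = "")
  list(alignment = stats::setNames(trimmed, names(aln)), kept = kept)
}

#' Kimura-corrected protein distances
#'
#' Pairwise distance \eqn{d = -\ln(1 - p - 0.2 p^2)} where p is the
#' proportion of differing residues over columns where neither sequence
#' has a gap.  Saturated pairs (p beyond the correction's domain) are set
#' to \code{cap} with a warning.
#'
#' @param aln named character vector of aligned protein sequences.
#' @param cap saturation cap in substitutions/site (default 5).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
protein_distance <- function(aln, cap = 5) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) {
        stop("sequences ", rownames(m)[i], " and ", rownames(m)[j],
             " share no gap-free columns")
      }
      p <- mean(m[i, ok] != m[j, ok])
      arg <- 1 - p - 0.2 * p^2
      d <- if (arg <= 0) {
        warning("distance saturated for pair ", rownames(m)[i], "/",
                rownames(m)[j], "; capped at ", cap)
        cap
      } else {
        min(-log(arg), cap)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration.  Ties in the Q-criterion are broken
#' deterministically by the lexicographically smallest pair of cluster
#' representatives (the smallest leaf label each cluster contains).
#' Negative branch-length estimates are clamped to zero with the deficit
#' moved to the sibling branch, preserving the pair's summed length.
#'
#' @param dm symmetric distance matrix with unique dimnames.
#' @return unrooted \code{phylo}.
#' @export
nj_tree <- function(dm) {
  labels <- rownames(dm)
  n <- length(labels)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (any(abs(dm - t(dm)) > 1e-9)) stop("distance matrix is not symmetric")
  frag <- labels                 # newick fragment per active cluster
  rep_lab <- labels              # smallest leaf label per cluster
  d <- dm
  while (nrow(d) > 3L) {
    r <- nrow(d)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(k) {
      pr <- sort(c(rep_lab[cand[k, 1]], rep_lab[cand[k, 2]]))
      paste(pr, collapse = "\r")
    }, character(1))
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], li, frag[j], lj)
    newrep <- min(rep_lab[i], rep_lab[j])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    rep_lab <- c(rep_lab[keep], newrep)
    rownames(d2) <- colnames(d2) <- NULL
    d <- d2
  }
  ## closing star: three-point formulae
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  lens <- pmax(c(la, lb, lc), 0)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1], lens[1], frag[2], lens[2], frag[3], lens[3])
  ape::read.tree(text = txt)
}

## canonical bipartition keys of an unrooted tree: for each internal edge,
## the sorted tip set on the side NOT containing `anchor`
.split_keys <- function(tree, anchor) {
  nt <- length(tree$tip.label)
  keys <- character(0)
  for (nd in seq_len(tree$Nnode) + nt) {
    tips <- tree$tip.label[clade_nodes(tree, nd)[clade_nodes(tree, nd) <= nt]]
    side <- if (anchor %in% tips) setdiff(tree$tip.label, tips) else tips
    if (length(side) >= 2 && length(side) <= nt - 2) {
      keys <- c(keys, paste(sort(side), collapse = "\r"))
    }
  }
  unique(keys)
}

#' Bootstrap support for the NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate and reports, for every internal branch of the full-data
#' tree, the percentage of replicates containing the same bipartition.
#' Supports are stored as node labels.
#'
#' @param aln named character vector of aligned protein sequences
#'   (at least 4).
#' @param n_replicates number of bootstrap replicates (default 1000).
#' @param seed integer seed for reproducibility.
#' @return the full-data NJ \code{phylo} with support values (0--100) as
#'   \code{node.label}.
#' @export
bootstrap_support <- function(aln, n_replicates = 1000, seed = NULL) {
  if (length(aln) < 4L) stop("bootstrap needs at least 4 sequences")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  m <- aln_matrix(aln)
  anchor <- sort(rownames(m))[1]
  full <- nj_tree(protein_distance(aln))
  counts <- integer(0)
  tally <- new.env(parent = emptyenv())
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_aln <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
    rt <- nj_tree(protein_distance(stats::setNames(rep_aln, rownames(m))))
    for (k in .split_keys(rt, anchor)) {
      assign(k, (if (exists(k, tally)) get(k, tally) else 0L) + 1L, tally)
    }
  }
  nt <- length(full$tip.label)
  full$node.label <- vapply(seq_len(full$Nnode) + nt, function(nd) {
    tips <- full$tip.label[clade_nodes(full, nd)[clade_nodes(full, nd) <= nt]]
    side <- if (anchor %in% tips) setdiff(full$tip.label, tips) else tips
    if (length(side) < 2 || length(side) > nt - 2) return("")
    k <- paste(sort(side), collapse = "\r")
    cnt <- if (exists(k, tally)) get(k, tally) else 0L
    sprintf("%g", round(100 * cnt / n_replicates))
  }, character(1))
  full
}

#' Root an unrooted tree with an outgroup
#'
#' Places the root at the midpoint of the branch separating the outgroup
#' from the ingroup.
#'
#' @param tree unrooted \code{phylo}.
#' @param outgroup_labels tip labels of the outgroup (a proper, non-empty
#'   subset of the tips, monophyletic on some rooting).
#' @return rooted binary \code{phylo}.
#' @export
root_by_outgroup <- function(tree, outgroup_labels) {
  miss <- setdiff(outgroup_labels, tree$tip.label)
  if (length(miss)) {
    stop("outgroup labels not in tree: ", paste(miss, collapse = ", "))
  }
  if (length(outgroup_labels) >= length(tree$tip.label)) {
    stop("outgroup cannot contain every leaf")
  }
  og <- sort(unique(outgroup_labels))
  if (length(og) > 1L) {
    keys <- .split_keys(tree, anchor = setdiff(tree$tip.label, og)[1])
    ## also singleton/complement splits are trivially present; check split
    target <- paste(sort(og), collapse = "\r")
    trivial <- length(og) == 1 || length(og) == length(tree$tip.label) - 1
    if (!trivial && !(target %in% keys)) {
      stop("outgroup is not monophyletic on any rooting of the tree: ",
           paste(og, collapse = ", "))
    }
  }
  rooted <- ape::root(tree, outgroup = outgroup_labels,
                      resolve.root = TRUE, edgelabel = TRUE)
  ## midpoint the two branches incident to the new root
  nt <- length(rooted$tip.label)
  root_edges <- which(rooted$edge[, 1] == nt + 1L)
  total <- sum(rooted$edge.length[root_edges])
  rooted$edge.length[root_edges] <- total / 2
  rooted
}
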