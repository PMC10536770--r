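## Goldman-Yang style codon substitution model: rate matrix, matrix
## exponentials via eigendecomposition of the reversible generator, F3x4
## frequency estimation, and the pruning likelihood over codon sites.

#' Build a GY94-style codon rate matrix
#'
#' Constructs the 61x61 generator of a Goldman-Yang codon model.  The rate
#' from codon i to codon j is zero unless the codons differ at exactly one
#' position; otherwise it is proportional to the target-codon frequency
#' \eqn{\pi_j}, multiplied by \eqn{\kappa} for transitions and by
#' \eqn{\omega} for nonsynonymous changes.  The diagonal makes rows sum to
#' zero and the matrix is rescaled so that the expected substitution rate at
#' stationarity is one, i.e. branch lengths are measured in expected
#' substitutions per codon.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio dN/dS (> 0).
#' @param pi codon frequencies: numeric vector of length 61 summing to one,
#'   ordered as \code{genefam:::CODONS61} (alphabetical, stops removed).
#'   Names, if present, must be sense codons.
#' @return 61x61 generator matrix with attributes \code{pi}, \code{kappa},
#'   \code{omega}.
#' @seealso [transition_probs()], [log_likelihood()]
#' @export
build_rate_matrix <- function(kappa, omega, pi) {
  stopifnot(kappa > 0, omega > 0)
  if (length(pi) != 61L) {
    stop("pi must have 61 entries (one per sense codon), got ", length(pi))
  }
  if (!is.null(names(pi))) {
    if (any(names(pi) %in% STOP_CODONS)) {
      stop("pi contains stop codons: ",
           paste(intersect(names(pi), STOP_CODONS), collapse = ", "))
    }
    pi <- pi[CODONS61]
    if (anyNA(pi)) stop("pi names do not cover the 61 sense codons")
  }
  if (abs(sum(pi) - 1) > 1e-6) {
    stop("pi must sum to 1 (got ", format(sum(pi)), ")")
  }
  pr <- .codon_pairs
  n <- length(CODONS61)
  fac <- matrix(0, n, n)
  fac[pr$single] <- 1
  fac[pr$single & pr$transition] <- kappa
  fac[pr$single & !pr$synonymous] <-
    fac[pr$single & !pr$synonymous] * omega
  Q <- fac * rep(pi, each = n)   # q_ij = fac_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))    # expected substitutions per codon per unit t
  Q <- Q / scale
  dimnames(Q) <- list(CODONS61, CODONS61)
  structure(Q, pi = unname(pi), kappa = kappa, omega = omega)
}

## Eigendecomposition of a reversible generator through its symmetrised
## form; returns factors such that P(t) = A %*% diag(exp(lambda t)) %*% B.
codon_eigen <- function(Q, pi = attr(Q, "pi")) {
  if (is.null(pi)) stop("Q carries no 'pi' attribute")
  sq <- sqrt(pi)
  S <- Q * (sq %o% (1 / sq))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(A = e$vectors / sq, B = t(e$vectors) * rep(sq, each = length(sq)),
       lambda = e$values)
}

p_matrix <- function(eg, t) {
  P <- eg$A %*% (exp(eg$lambda * t) * eg$B)
  P[P < 0] <- 0
  P
}

#' Transition probability matrix of the codon model
#'
#' Computes \eqn{P(t) = \exp(Qt)} by eigendecomposition of the symmetrised
#' reversible generator.  Small negative entries arising from round-off are
#' clamped to zero.
#'
#' @param Q generator from [build_rate_matrix()].
#' @param t branch length in expected substitutions per codon, >= 0.
#' @return 61x61 stochastic matrix.
#' @export
transition_probs <- function(Q, t) {
  if (t < 0) stop("branch length t must be >= 0, got ", t)
  P <- p_matrix(codon_eigen(Q), t)
  dimnames(P) <- dimnames(Q)
  P
}

#' Estimate F3x4 codon frequencies from a codon alignment
#'
#' Empirical nucleotide frequencies are computed separately at each codon
#' position (with a pseudocount of 0.5 per nucleotide per position to guard
#' against zero frequencies), multiplied across positions, restricted to the
#' 61 sense codons and renormalised.
#'
#' @param alignment named character vector of equal-length in-frame
#'   nucleotide sequences; gaps (\code{-}) and ambiguous characters are
#'   ignored in the counts.
#' @return named numeric vector of 61 sense-codon frequencies summing to 1.
#' @export
estimate_f3x4 <- function(alignment) {
  if (length(alignment) == 0L) stop("empty alignment")
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) stop("alignment rows differ in length")
  if (lens[1] %% 3L != 0L) stop("alignment length not a multiple of 3")
  counts <- matrix(0.5, nrow = 3, ncol = 4,
                   dimnames = list(NULL, NUCS))
  for (s in alignment) {
    chars <- strsplit(toupper(s), "")[[1]]
    pos <- rep_len(1:3, length(chars))
    keep <- chars %in% NUCS
    if (any(keep)) {
      tab <- table(factor(pos[keep], 1:3), factor(chars[keep], NUCS))
      counts <- counts + as.matrix(tab)
    }
  }
  freq <- counts / rowSums(counts)
  pi <- freq[1, .codon_nuc(1)] * freq[2, .codon_nuc(2)] *
    freq[3, .codon_nuc(3)]
  pi <- pi / sum(pi)
  names(pi) <- CODONS61
  pi
}

## ---- alignment patterns ----------------------------------------------

## Convert a codon alignment into an integer matrix (sequences x sites) of
## sense-codon indices with NA for gap/ambiguous/stop codons, compressed to
## unique site patterns with weights.
codon_patterns <- function(alignment) {
  if (is.null(names(alignment)) || any(!nzchar(names(alignment)))) {
    stop("alignment sequences must be named")
  }
  idx <- lapply(alignment, codon_indices)
  lens <- lengths(idx)
  if (length(unique(lens)) != 1L) stop("alignment rows differ in length")
  M <- do.call(rbind, idx)
  key <- apply(M, 2, paste, collapse = ",")
  uk <- unique(key)
  first <- match(uk, key)
  list(states = M[, first, drop = FALSE],
       weights = as.numeric(table(factor(key, levels = uk))[uk]),
       n_sites = length(key))
}

## ---- pruning likelihood ----------------------------------------------

## Internal workhorse shared by log_likelihood() and the fitter.
## tree: rooted binary phylo; classes: character vector per edge row;
## eigens: named list of codon_eigen() results per class; lengths: edge
## lengths; pat: codon_patterns() output aligned to tip labels.
## Returns list(lnL, down = per-node partials, logscale).
.prune <- function(tree, lengths, classes, eigens, pi, pat,
                   keep_partials = FALSE, tipmats = NULL) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  down <- vector("list", nn)
  logsc <- numeric(nn)
  ord <- reorder_edges(tree)
  edge <- tree$edge
  if (is.null(tipmats)) tipmats <- .tip_partials(tree, pat)
  Pmats <- vector("list", nrow(edge))
  for (e in ord) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    eg <- eigens[[classes[e]]]
    if (is.null(eg)) stop("no eigensystem for branch class '", classes[e], "'")
    P <- p_matrix(eg, lengths[e])
    Pmats[[e]] <- P
    chmat <- if (ch <= nt) tipmats[[ch]] else down[[ch]]
    contrib <- P %*% chmat
    if (is.null(down[[par]])) {
      down[[par]] <- contrib
      logsc[par] <- logsc[par] + if (ch <= nt) 0 else logsc[ch]
    } else {
      down[[par]] <- down[[par]] * contrib
      logsc[par] <- logsc[par] + if (ch <= nt) 0 else logsc[ch]
      mx <- max(down[[par]])
      if (mx < 1e-200) stop("numerical underflow in pruning")
      if (mx < 1e-80) {
        down[[par]] <- down[[par]] / mx
        logsc[par] <- logsc[par] + log(mx)
      }
    }
  }
  root <- nt + 1L
  site <- as.vector(pi %*% down[[root]])
  lnL <- sum(pat$weights * (log(site) + logsc[root]))
  out <- list(lnL = lnL)
  if (keep_partials) {
    out$down <- down
    out$tipmats <- tipmats
    out$Pmats <- Pmats
    out$logsc <- logsc
  }
  out
}

## leaf partial-likelihood indicator matrices (all-ones where missing)
.tip_partials <- function(tree, pat) {
  nt <- length(tree$tip.label)
  npat <- length(pat$weights)
  rows <- match(tree$tip.label, rownames(pat$states))
  if (anyNA(rows)) {
    stop("alignment is missing sequences for tips: ",
         paste(tree$tip.label[is.na(rows)], collapse = ", "))
  }
  lapply(seq_len(nt), function(i) {
    m <- matrix(0, 61L, npat)
    st <- pat$states[rows[i], ]
    ok <- !is.na(st)
    m[cbind(st[ok], which(ok))] <- 1
    if (any(!ok)) m[, !ok] <- 1
    m
  })
}

## postorder edge ordering (children before parents)
reorder_edges <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  po
}

#' Phylogenetic log likelihood of a codon alignment
#'
#' Felsenstein pruning over codon sites under a GY94-style model with one
#' \eqn{\omega} per branch class.  Identical site patterns are collapsed and
#' computed once.  Alignment gaps and ambiguous codons are treated as
#' missing data (partial likelihood one for every state).
#'
#' @param alignment named character vector of equal-length in-frame codon
#'   sequences; names must match the tree's tip labels.
#' @param tree rooted binary \code{phylo} with branch lengths in expected
#'   substitutions per codon.  Branch classes are taken from
#'   \code{attr(tree, "edge_class")} (one label per edge row) and default to
#'   \code{"background"}.
#' @param params list with components \code{kappa}, \code{omega_by_class}
#'   (named numeric, one entry per branch class in the tree), and \code{pi}
#'   (61 sense-codon frequencies).
#' @return log likelihood (scalar).
#' @export
log_likelihood <- function(alignment, tree, params) {
  check_classed_tree(tree)
  extra <- setdiff(names(alignment), tree$tip.label)
  if (length(extra)) {
    stop("alignment sequences not in tree: ", paste(extra, collapse = ", "))
  }
  classes <- edge_classes(tree)
  omega <- params$omega_by_class
  miss <- setdiff(unique(classes), names(omega))
  if (length(miss)) {
    stop("no omega provided for branch class(es): ",
         paste(miss, collapse = ", "))
  }
  pi <- params$pi
  eigens <- lapply(omega[unique(classes)], function(w) {
    codon_eigen(build_rate_matrix(params$kappa, w, pi))
  })
  pat <- codon_patterns(alignment[tree$tip.label])
  .prune(tree, tree$edge.length, classes, eigens, unname(pi), pat)$lnL
}

## edge class vector of a tree (default background)
edge_classes <- function(tree) {
  cl <- attr(tree, "edge_class")
  if (is.null(cl)) cl <- rep("background", nrow(tree$edge))
  if (length(cl) != nrow(tree$edge)) {
    stop("edge_class attribute has length ", length(cl),
         " but tree has ", nrow(tree$edge), " edges")
  }
  cl
}

check_classed_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (!ape::is.binary.phylo(tree)) stop("tree must be binary")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  invisible(tree)
}
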