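## Forward simulation of codon sequences along a classed gene tree under
## the GY94-style branch model: the generative counterpart of the
## likelihood machinery, used to test parameter recovery.

#' Evolve codon sequences along a gene tree
#'
#' Draws a root sequence from the stationary distribution \code{pi} and
#' evolves it along every branch by sampling from the transition
#' probabilities of the branch-class rate matrix.  Branch lengths are in
#' expected substitutions per codon.
#'
#' @param gene_tree rooted binary classed \code{phylo} (see
#'   [set_branch_class()]); every branch class must appear in
#'   \code{omega_by_class}.
#' @param kappa transition/transversion rate ratio.
#' @param omega_by_class named numeric: dN/dS per branch class.
#' @param pi sense-codon frequencies (length 61, summing to one).
#' @param n_codons alignment length in codons.
#' @param seed integer seed; the alignment is reproducible given the seed.
#' @return named character vector: one gap-free in-frame sequence of
#'   \code{3 * n_codons} nucleotides per tip.
#' @export
evolve_codon_sequences <- function(gene_tree, kappa, omega_by_class, pi,
                                   n_codons, seed = NULL) {
  check_classed_tree(gene_tree)
  if (!is.null(seed)) set.seed(seed)
  classes <- edge_classes(gene_tree)
  miss <- setdiff(unique(classes), names(omega_by_class))
  if (length(miss)) {
    bad <- which(classes %in% miss)[1]
    stop("branch ", bad, " (into node ", gene_tree$edge[bad, 2],
         ") has unknown class '", classes[bad], "'")
  }
  if (length(pi) == 61L && !is.null(names(pi))) pi <- pi[CODONS61]
  Qs <- lapply(omega_by_class, function(w) build_rate_matrix(kappa, w, pi))
  nt <- length(gene_tree$tip.label)
  nn <- nt + gene_tree$Nnode
  states <- vector("list", nn)
  root <- nt + 1L
  states[[root]] <- sample.int(61L, n_codons, replace = TRUE,
                               prob = unname(pi))
  edge <- gene_tree$edge
  ord <- rev(reorder_edges(gene_tree))  # preorder: parents first
  for (e in ord) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    t <- gene_tree$edge.length[e]
    if (t == 0) {
      states[[ch]] <- states[[par]]
      next
    }
    P <- transition_probs(Qs[[classes[e]]], t)
    cum <- t(apply(P, 1, cumsum))
    s <- states[[par]]
    u <- stats::runif(n_codons) * cum[cbind(s, rep(61L, n_codons))]
    rows <- cum[s, , drop = FALSE]
    states[[ch]] <- as.integer(rowSums(rows < u) + 1L)
  }
  out <- vapply(seq_len(nt), function(i) {
    paste(CODONS61[states[[i]]], collapse = "")
  }, character(1))
  names(out) <- gene_tree$tip.label
  out
}
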