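## shared helpers for the test-suite: tiny trees, uniform frequencies,
## brute-force oracles

uniform_pi <- function() {
  stats::setNames(rep(1 / 61, 61), genefam:::CODONS61)
}

## species tree used by the hand-computed reconciliation examples
abc_tree <- function() ape::read.tree(text = "((A:1,B:1)ab:1,C:2)r;")

## brute-force codon log likelihood: sum over all internal-state
## assignments (independent of the pruning implementation)
brute_force_lnL <- function(alignment, tree, params) {
  Q <- lapply(params$omega_by_class, function(w)
    build_rate_matrix(params$kappa, w, params$pi))
  classes <- attr(tree, "edge_class")
  if (is.null(classes)) classes <- rep("background", nrow(tree$edge))
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    transition_probs(Q[[classes[e]]], tree$edge.length[e]))
  nt <- length(tree$tip.label)
  nint <- tree$Nnode
  idx <- lapply(alignment[tree$tip.label], genefam:::codon_indices)
  nsites <- length(idx[[1]])
  pi <- unname(params$pi)
  total <- 0
  for (s in seq_len(nsites)) {
    tipstate <- vapply(idx, `[`, integer(1), s)
    lik <- 0
    grid <- do.call(expand.grid, rep(list(1:61), nint))
    for (g in seq_len(nrow(grid))) {
      states <- c(tipstate, as.integer(grid[g, ]))
      p <- pi[states[nt + 1L]]
      for (e in seq_len(nrow(tree$edge))) {
        p <- p * P[[e]][states[tree$edge[e, 1]], states[tree$edge[e, 2]]]
        if (p == 0) break
      }
      lik <- lik + p
    }
    total <- total + log(lik)
  }
  total
}

## random codon alignment (gap-free) for io/selection tests
random_codon_aln <- function(ids, n_codons, seed) {
  set.seed(seed)
  sapply(stats::setNames(ids, ids), function(i)
    paste(sample(genefam:::CODONS61, n_codons, replace = TRUE),
          collapse = ""))
}

## zero-rate configuration (no duplications, no losses)
zero_rates <- function() {
  c(tandem = 0, triplication = 0, inverted = 0, segmental = 0,
    transposed = 0, loss = 0)
}

make_locus <- function(id, species = "S", scaffold = "scf1", start, end,
                       strand = "+") {
  gene_locus(id, species, scaffold, start, end, strand)
}
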