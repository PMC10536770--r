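## Gene-tree / species-tree reconciliation: LCA mapping, duplication
## flags, parsimony loss counts attached to species-tree branches, and
## ancestral gene copy numbers.
##
## Gene-tree tips are "species|gene_id". Both trees must be rooted and
## binary; polytomies are rejected rather than silently resolved because
## resolution changes the event counts that are the analysis's output.

tip_species <- function(labels) sub("\\|.*$", "", labels)
tip_gene <- function(labels) sub("^.*\\|", "", labels)

## per-node ancestor paths (self first, root last) of a rooted tree
.ancestor_paths <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  parent <- integer(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- nt + 1L
  lapply(seq_len(nn), function(v) {
    path <- v
    while (v != root) {
      v <- parent[v]
      path <- c(path, v)
    }
    path
  })
}

#' LCA mapping of a gene tree into a species tree
#'
#' Maps every gene-tree node to the species-tree most recent common
#' ancestor of the species of its descendant genes.
#'
#' @param gene_tree rooted binary \code{phylo}, tips \code{"species|gene"}.
#' @param species_tree rooted binary \code{phylo} whose tips cover every
#'   species occurring in the gene tree.
#' @return integer vector: species-tree node id for every gene-tree node
#'   (tips first, then internal nodes, in \code{phylo} order).
#' @export
lca_map <- function(gene_tree, species_tree) {
  .check_recon_input(gene_tree, species_tree)
  nt <- length(gene_tree$tip.label)
  nn <- nt + gene_tree$Nnode
  sp <- tip_species(gene_tree$tip.label)
  sp_idx <- match(sp, species_tree$tip.label)
  if (anyNA(sp_idx)) {
    stop("species not in species tree: ",
         paste(unique(sp[is.na(sp_idx)]), collapse = ", "))
  }
  paths <- .ancestor_paths(species_tree)
  depth <- lengths(paths)  # root has depth 1
  lca2 <- function(a, b) {
    pa <- paths[[a]]; pb <- paths[[b]]
    ca <- intersect(pa, pb)
    ca[1]
  }
  map <- integer(nn)
  map[seq_len(nt)] <- sp_idx
  for (e in reorder_edges(gene_tree)) {
    u <- gene_tree$edge[e, 1]; v <- gene_tree$edge[e, 2]
    map[u] <- if (map[u] == 0L) map[v] else lca2(map[u], map[v])
  }
  map
}

.check_recon_input <- function(gene_tree, species_tree) {
  for (t in list(gene_tree, species_tree)) {
    if (!inherits(t, "phylo")) stop("trees must be 'phylo' objects")
    if (!ape::is.rooted(t)) stop("trees must be rooted")
    if (!ape::is.binary(t)) {
      stop("polytomies are not supported; resolve them explicitly ",
           "before reconciling")
    }
  }
  genes <- tip_gene(gene_tree$tip.label)
  if (anyDuplicated(genes)) {
    stop("duplicate gene ids: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  invisible(TRUE)
}

#' Flag duplication nodes of a reconciled gene tree
#'
#' A gene-tree internal node is a duplication exactly when it maps to the
#' same species-tree node as at least one of its children.
#'
#' @param gene_tree rooted binary gene tree.
#' @param mapping output of [lca_map()].
#' @return integer vector of duplication node ids (possibly empty).
#' @export
infer_duplications <- function(gene_tree, mapping) {
  nt <- length(gene_tree$tip.label)
  dup <- logical(nt + gene_tree$Nnode)
  for (e in seq_len(nrow(gene_tree$edge))) {
    u <- gene_tree$edge[e, 1]; v <- gene_tree$edge[e, 2]
    if (mapping[u] == mapping[v]) dup[u] <- TRUE
  }
  which(dup)
}

#' Parsimony gene-loss counts per species-tree branch
#'
#' For every gene-tree edge (u, v), losses are implied wherever the copy
#' must have crossed a speciation without leaving descendants on the other
#' side: one loss on the "other child" branch of every species-tree node
#' strictly between the mappings of u and v, plus one at the mapping of u
#' itself when u is a duplication whose mapping differs from v's.
#'
#' @param gene_tree rooted binary gene tree.
#' @param species_tree rooted binary species tree.
#' @param mapping output of [lca_map()].
#' @param duplications output of [infer_duplications()].
#' @return data frame with one row per loss: \code{branch} (label of the
#'   species-tree node at the child end of the branch the loss occurred
#'   on), \code{species_node} (its id) and \code{gene_node} (the gene-tree
#'   edge's child node, the lineage responsible).
#' @export
count_losses <- function(gene_tree, species_tree, mapping, duplications) {
  species_tree <- ensure_node_labels(species_tree)
  paths <- .ancestor_paths(species_tree)
  kids <- split(species_tree$edge[, 2], species_tree$edge[, 1])
  rows <- list()
  add_loss <- function(sp_node_on_path, parent_sp, gene_node) {
    others <- setdiff(kids[[as.character(parent_sp)]], sp_node_on_path)
    for (o in others) {
      rows[[length(rows) + 1L]] <<-
        data.frame(branch = node_label(species_tree, o),
                   species_node = o, gene_node = gene_node)
    }
  }
  is_dup <- logical(length(mapping))
  is_dup[duplications] <- TRUE
  for (e in seq_len(nrow(gene_tree$edge))) {
    u <- gene_tree$edge[e, 1]; v <- gene_tree$edge[e, 2]
    mu <- mapping[u]; mv <- mapping[v]
    if (mu == mv) next
    ## path runs mv (first) .. mu; path nodes below mu, above mv:
    path <- paths[[mv]]
    stop_at <- match(mu, path)
    strict <- if (stop_at > 2L) path[2:(stop_at - 1L)] else integer()
    for (i in seq_along(strict)) {
      below <- path[i]          # the path node the copy continued into
      add_loss(below, strict[i], v)
    }
    if (is_dup[u]) {
      below <- path[stop_at - 1L]
      add_loss(below, mu, v)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(branch = character(), species_node = integer(),
                      gene_node = integer()))
  }
  do.call(rbind, rows)
}

#' Ancestral gene copy numbers on the species tree
#'
#' Counts, for every species-tree node, the gene lineages present at that
#' node's speciation: observed speciation/leaf nodes mapped there, copies
#' inferred to have crossed it on the way to a deeper mapping, and copies
#' born at a duplication mapped there.  Nothing is inferred above the
#' family root's mapping (standard LCA parsimony).
#'
#' @inheritParams count_losses
#' @return named integer vector: copy number per species-tree node
#'   (names are tip/node labels, order is \code{phylo} node order).
#' @export
ancestral_counts <- function(gene_tree, species_tree, mapping,
                             duplications) {
  species_tree <- ensure_node_labels(species_tree)
  nt_s <- length(species_tree$tip.label)
  nn_s <- nt_s + species_tree$Nnode
  nt_g <- length(gene_tree$tip.label)
  paths <- .ancestor_paths(species_tree)
  counts <- integer(nn_s)
  is_dup <- logical(length(mapping))
  is_dup[duplications] <- TRUE
  ## speciation and leaf gene nodes sit at their mapped species node
  for (v in seq_along(mapping)) {
    if (v <= nt_g || !is_dup[v]) counts[mapping[v]] <- counts[mapping[v]] + 1L
  }
  ## crossings along gene edges
  for (e in seq_len(nrow(gene_tree$edge))) {
    u <- gene_tree$edge[e, 1]; v <- gene_tree$edge[e, 2]
    mu <- mapping[u]; mv <- mapping[v]
    if (mu == mv) next
    path <- paths[[mv]]
    stop_at <- match(mu, path)
    strict <- if (stop_at > 2L) path[2:(stop_at - 1L)] else integer()
    counts[strict] <- counts[strict] + 1L
    if (is_dup[u]) counts[mu] <- counts[mu] + 1L
  }
  names(counts) <- vapply(seq_len(nn_s), function(n)
    node_label(species_tree, n), character(1))
  counts
}

#' Full reconciliation of a gene tree with a species tree
#'
#' Runs [lca_map()], [infer_duplications()], [count_losses()] and
#' [ancestral_counts()] and bundles the results.
#'
#' @inheritParams lca_map
#' @return object of class \code{reconciliation}: list with
#'   \code{mapping}, \code{duplications} (node ids),
#'   \code{duplication_branches} (per-duplication species branch label),
#'   \code{losses} (data frame), \code{ancestral_counts}, and the two
#'   trees.
#' @export
reconcile <- function(gene_tree, species_tree) {
  species_tree <- ensure_node_labels(species_tree)
  mapping <- lca_map(gene_tree, species_tree)
  dups <- infer_duplications(gene_tree, mapping)
  losses <- count_losses(gene_tree, species_tree, mapping, dups)
  counts <- ancestral_counts(gene_tree, species_tree, mapping, dups)
  obs <- table(tip_species(gene_tree$tip.label))
  leaf_counts <- counts[seq_len(length(species_tree$tip.label))]
  for (s in names(obs)) {
    if (leaf_counts[[s]] != obs[[s]]) {
      stop("internal flow-conservation error: species ", s, " reconciled ",
           leaf_counts[[s]], " copies but observes ", obs[[s]])
    }
  }
  structure(list(
    mapping = mapping,
    duplications = dups,
    duplication_branches = vapply(dups, function(d)
      node_label(species_tree, mapping[d]), character(1)),
    losses = losses,
    ancestral_counts = counts,
    gene_tree = gene_tree,
    species_tree = species_tree
  ), class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("reconciliation:", length(x$duplications), "duplications,",
      nrow(x$losses), "losses\n")
  cat("root copy number:",
      x$ancestral_counts[[length(x$species_tree$tip.label) + 1L]], "\n")
  invisible(x)
}

#' Collapse weakly supported branches to polytomies
#'
#' Optional preprocessing hook (off by default in the pipeline):
#' internal branches with bootstrap support below \code{threshold} are
#' collapsed.  The result usually contains polytomies, which
#' [reconcile()] deliberately rejects; callers must resolve them.
#'
#' @param tree \code{phylo} with numeric node labels (support values).
#' @param threshold minimum support to keep a branch.
#' @return \code{phylo}, possibly multifurcating.
#' @export
collapse_weak_branches <- function(tree, threshold) {
  if (is.null(tree$node.label)) stop("tree carries no support values")
  sup <- suppressWarnings(as.numeric(tree$node.label))
  nt <- length(tree$tip.label)
  drop <- which(!is.na(sup) & sup < threshold) + nt
  keep_edge <- !(tree$edge[, 2] %in% drop)
  tree$edge.length[!keep_edge] <- 0
  ape::di2multi(tree, tol = 1e-12)
}
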