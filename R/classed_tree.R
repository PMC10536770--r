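## Branch-class labelled trees. A "classed" tree is an ape phylo carrying
## attr(tree, "edge_class"): one label per edge row (e.g. FLC_sstr,
## MAF123, MAF45, background). On disk the class of a branch is written
## codeml-style as a "#class" suffix on the label of the branch's child
## node; unlabelled branches are background.

#' Assign one class to a set of branches
#'
#' @param tree a \code{phylo}.
#' @param edges integer indices into \code{tree$edge} rows.
#' @param class character scalar.
#' @return the tree with an updated \code{edge_class} attribute.
#' @export
set_branch_class <- function(tree, edges, class) {
  cl <- edge_classes(tree)
  cl[edges] <- class
  attr(tree, "edge_class") <- cl
  tree
}

#' Label every branch inside a crown clade
#'
#' Assigns \code{class} to all branches whose parent node lies within the
#' clade spanned by \code{tips} (i.e. the branches below the most recent
#' common ancestor of \code{tips}); the stem branch leading into the clade
#' keeps its previous class, matching the convention that stems between
#' clades are background.
#'
#' @param tree rooted \code{phylo}.
#' @param tips tip labels spanning the clade.
#' @param class class label to assign.
#' @return classed tree.
#' @export
label_crown_clade <- function(tree, tips, class) {
  miss <- setdiff(tips, tree$tip.label)
  if (length(miss)) stop("tips not in tree: ", paste(miss, collapse = ", "))
  if (length(tips) < 2) {
    return(set_branch_class(
      tree, which(tree$edge[, 2] == match(tips, tree$tip.label)), class))
  }
  mrca <- ape::getMRCA(tree, tips)
  desc <- clade_nodes(tree, mrca)
  edges <- which(tree$edge[, 1] %in% desc)
  set_branch_class(tree, edges, class)
}

## all nodes (internal + tips) in the clade rooted at `node`, inclusive
clade_nodes <- function(tree, node) {
  edge <- tree$edge
  res <- node
  frontier <- node
  while (length(frontier)) {
    kids <- edge[edge[, 1] %in% frontier, 2]
    res <- c(res, kids)
    frontier <- kids[kids > length(tree$tip.label)]
  }
  res
}

#' Write / read a classed tree as newick with #class suffixes
#'
#' @param tree classed \code{phylo}.
#' @param path file path.
#' @return \code{read_classed_newick} returns a classed \code{phylo}.
#' @export
write_classed_newick <- function(tree, path) {
  cl <- edge_classes(tree)
  nt <- length(tree$tip.label)
  out <- tree
  if (is.null(out$node.label)) out$node.label <- rep("", out$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    if (cl[e] != "background") {
      v <- tree$edge[e, 2]
      if (v <= nt) {
        out$tip.label[v] <- paste0(out$tip.label[v], "#", cl[e])
      } else {
        out$node.label[v - nt] <- paste0(out$node.label[v - nt], "#", cl[e])
      }
    }
  }
  ape::write.tree(out, file = path)
  invisible(path)
}

#' @rdname write_classed_newick
#' @param path file path.
#' @export
read_classed_newick <- function(path) {
  tree <- read_newick(path)
  nt <- length(tree$tip.label)
  cl <- rep("background", nrow(tree$edge))
  split_lab <- function(lab) {
    m <- regmatches(lab, regexpr("#[^#]*$", lab))
    if (length(m)) list(base = sub("#[^#]*$", "", lab), class = sub("^#", "", m))
    else list(base = lab, class = NA_character_)
  }
  for (v in seq_len(nt)) {
    sp <- split_lab(tree$tip.label[v])
    if (!is.na(sp$class)) {
      tree$tip.label[v] <- sp$base
      cl[tree$edge[, 2] == v] <- sp$class
    }
  }
  if (!is.null(tree$node.label)) {
    for (i in seq_len(tree$Nnode)) {
      sp <- split_lab(tree$node.label[i])
      if (!is.na(sp$class)) {
        tree$node.label[i] <- sp$base
        cl[tree$edge[, 2] == nt + i] <- sp$class
      }
    }
  }
  attr(tree, "edge_class") <- cl
  tree
}

#' A 12-taxon branch-class labelled demonstration tree
#'
#' A fixed rooted 12-taxon gene tree mirroring the structure of an
#' FLC-like gene family: an outgroup, a slowly evolving FLC s.str. crown
#' clade (4 tips, short branches), a MAF1/2/3 crown clade (3 tips,
#' intermediate branches) and a fast MAF4/5 crown clade (4 tips, long
#' branches).  Crown branches carry their clade's class; stems and the
#' outgroup are background.  Branch lengths are in expected substitutions
#' per codon and are used as simulation truth in recovery experiments.
#'
#' @return classed rooted \code{phylo} with 12 tips and 22 branches.
#' @export
selection_demo_tree <- function() {
  nwk <- paste0(
    "(out1:0.45,((flc1:0.10,(flc2:0.08,(flc3:0.06,flc4:0.06):0.04):0.05)",
    ":0.18,((m123a:0.15,(m123b:0.12,m123c:0.12):0.08):0.20,",
    "(m45a:0.25,(m45b:0.20,(m45c:0.18,m45d:0.18):0.10):0.12):0.22):0.08)",
    ":0.12);")
  tree <- ape::read.tree(text = nwk)
  tree <- label_crown_clade(tree, paste0("flc", 1:4), "FLC_sstr")
  tree <- label_crown_clade(tree, paste0("m123", c("a", "b", "c")), "MAF123")
  tree <- label_crown_clade(tree, paste0("m45", c("a", "b", "c", "d")),
                            "MAF45")
  tree
}
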