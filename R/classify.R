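## Mechanism classification of inferred duplications from genomic
## coordinates: tandem / inverted / segmental / transposed calls, collapse
## of nested duplication pairs into triplications, and polyploidy
## assignment on annotated WGD/WGT branches.

#' Classification thresholds
#'
#' @param tandem_max maximum boundary-to-boundary gap (bp) for a tandem or
#'   inverted call (default 100 kbp; observed tandem pairs in FLC-like
#'   families sit at 12--13 kbp).
#' @param segmental_min minimum gap (bp) for a confident same-scaffold
#'   segmental call (default 500 kbp); gaps between \code{tandem_max} and
#'   \code{segmental_min} are called segmental with a low-confidence flag.
#' @param simultaneity_max maximum length (in the gene tree's branch
#'   units) of the edge connecting two nested duplication nodes for them
#'   to count as one atomic triplication; a triplication is a single
#'   event, so its two binary nodes are (near-)simultaneous.
#' @return named list of thresholds.
#' @export
classify_thresholds <- function(tandem_max = 100000, segmental_min = 500000,
                                simultaneity_max = 0.001) {
  stopifnot(tandem_max > 0, segmental_min >= tandem_max)
  list(tandem_max = tandem_max, segmental_min = segmental_min,
       simultaneity_max = simultaneity_max)
}

## boundary-to-boundary gap between two loci rows (0 when overlapping)
.locus_gap <- function(a, b) {
  max(0L, max(a$start, b$start) - min(a$end, b$end))
}

## tips (gene ids) below each child of a gene-tree node
.child_clades <- function(gene_tree, node) {
  nt <- length(gene_tree$tip.label)
  kids <- gene_tree$edge[gene_tree$edge[, 1] == node, 2]
  lapply(kids, function(k) {
    nds <- clade_nodes(gene_tree, k)
    tip_gene(gene_tree$tip.label[nds[nds <= nt]])
  })
}

#' Classify one duplication node from genomic coordinates
#'
#' The witness pair is the two extant descendant loci, one from each child
#' clade of the duplication node, that lie in the same species with the
#' smallest genomic separation (same-scaffold pairs are preferred; the gap
#' is measured between the nearest gene boundaries).  Calls: same scaffold
#' with gap <= \code{tandem_max} -> tandem (same strand) or inverted
#' (opposite strands); gap > \code{segmental_min} -> segmental; gap in
#' between -> segmental with a low-confidence flag; no same-scaffold
#' witness in any shared species -> transposed; no shared species at all
#' -> unresolved.
#'
#' @param dup_node gene-tree node id flagged by [infer_duplications()].
#' @param gene_tree rooted binary gene tree (tips \code{"species|gene"}).
#' @param loci \code{loci_table} covering every descendant gene.
#' @param thresholds a [classify_thresholds()].
#' @return one-row data frame: node, type, witnesses, species,
#'   same_scaffold, distance, strands, low_confidence, note.
#' @export
classify_duplication <- function(dup_node, gene_tree, loci,
                                 thresholds = classify_thresholds()) {
  clades <- .child_clades(gene_tree, dup_node)
  if (length(clades) != 2L) stop("node ", dup_node, " is not binary")
  row_of <- function(g) {
    i <- match(g, loci$gene_id)
    if (is.na(i)) stop("no locus for descendant gene ", g)
    loci[i, ]
  }
  best <- NULL
  for (g1 in clades[[1]]) {
    a <- row_of(g1)
    for (g2 in clades[[2]]) {
      b <- row_of(g2)
      if (a$species != b$species) next
      same_scf <- a$scaffold == b$scaffold
      gap <- if (same_scf) .locus_gap(a, b) else Inf
      cand <- list(g1 = g1, g2 = g2, a = a, b = b, same_scf = same_scf,
                   gap = gap)
      if (is.null(best) || gap < best$gap ||
          (gap == best$gap && paste(g1, g2) < paste(best$g1, best$g2))) {
        best <- cand
      }
    }
  }
  mk <- function(type, same_scf, dist, strands, lowconf = FALSE,
                 note = "", wit = c(best$g1, best$g2), spp = NA_character_) {
    data.frame(node = dup_node, type = type,
               witnesses = paste(wit, collapse = ","),
               species = spp, same_scaffold = same_scf,
               distance = dist, strands = strands,
               low_confidence = lowconf, note = note,
               stringsAsFactors = FALSE)
  }
  if (is.null(best)) {
    return(mk("unresolved", NA, NA_real_, NA_character_,
              note = "child clades survive in disjoint species",
              wit = c(clades[[1]][1], clades[[2]][1])))
  }
  spp <- best$a$species
  if (!best$same_scf) {
    return(mk("transposed_duplication", FALSE, NA_real_,
              paste0(best$a$strand, "/", best$b$strand), spp = spp))
  }
  th <- thresholds
  strands <- paste0(best$a$strand, "/", best$b$strand)
  if (best$gap <= th$tandem_max) {
    type <- if (best$a$strand == best$b$strand) "tandem_duplication"
            else "inverted_duplication"
    return(mk(type, TRUE, best$gap, strands, spp = spp))
  }
  mk("segmental_duplication", TRUE, best$gap, strands,
     lowconf = best$gap <= th$segmental_min,
     note = if (best$gap <= th$segmental_min)
       "gap in gray zone between tandem_max and segmental_min" else "",
     spp = spp)
}

#' Merge nested same-branch tandem duplications into triplications
#'
#' Two nested tandem-type duplication nodes assigned to the same
#' species-tree branch whose three resulting copies lie mutually within
#' \code{tandem_max} on one scaffold are reported as a single atomic
#' tandem triplication.  Merging is greedy, oldest (most rootward) pair
#' first.
#'
#' @param calls data frame of per-node calls (see
#'   [classify_duplication()]) with a \code{branch} column.
#' @param gene_tree the reconciled gene tree.
#' @param loci \code{loci_table}.
#' @param thresholds a [classify_thresholds()].
#' @return calls with merged rows (type \code{tandem_triplication}).
#' @export
collapse_triplications <- function(calls, gene_tree, loci,
                                   thresholds = classify_thresholds()) {
  tandemish <- c("tandem_duplication", "inverted_duplication")
  idx <- which(calls$type %in% tandemish)
  if (length(idx) < 2L) return(calls)
  nt <- length(gene_tree$tip.label)
  depth <- lengths(.ancestor_paths(gene_tree))
  idx <- idx[order(depth[calls$node[idx]])]  # rootward first
  merged <- rep(FALSE, nrow(calls))
  nt <- length(gene_tree$tip.label)
  tips_below <- function(nd) {
    nds <- clade_nodes(gene_tree, nd)
    tip_gene(gene_tree$tip.label[nds[nds <= nt]])
  }
  for (k in seq_along(idx)) {
    i <- idx[k]
    if (merged[i]) next
    kids_i <- gene_tree$edge[gene_tree$edge[, 1] == calls$node[i], 2]
    for (j in idx[-seq_len(k)]) {
      if (merged[j] || calls$branch[j] != calls$branch[i]) next
      if (!(calls$node[j] %in% kids_i)) next  # inner must be a direct child
      if (!is.null(gene_tree$edge.length)) {
        elen <- gene_tree$edge.length[
          which(gene_tree$edge[, 2] == calls$node[j])]
        if (elen > thresholds$simultaneity_max) next
      }
      outer_side <- setdiff(kids_i, calls$node[j])
      kids_j <- gene_tree$edge[gene_tree$edge[, 1] == calls$node[j], 2]
      clades3 <- lapply(c(outer_side, kids_j), tips_below)
      trip <- .find_tandem_triple(clades3, loci, thresholds$tandem_max)
      if (is.null(trip)) next
      calls$type[i] <- "tandem_triplication"
      calls$witnesses[i] <- paste(trip$genes, collapse = ",")
      calls$species[i] <- trip$species
      calls$note[i] <- paste0("merged nested duplication node ",
                              calls$node[j])
      merged[j] <- TRUE
      break
    }
  }
  calls[!merged, , drop = FALSE]
}

## one locus from each of three clades, same species and scaffold, all
## pairwise boundary gaps <= tandem_max; NULL when no such triple exists
.find_tandem_triple <- function(clades3, loci, tandem_max) {
  rows <- lapply(clades3, function(g) loci[loci$gene_id %in% g, ,
                                           drop = FALSE])
  shared <- Reduce(intersect, lapply(rows, function(r) unique(r$species)))
  for (sp in sort(shared)) {
    r1 <- rows[[1]][rows[[1]]$species == sp, ]
    r2 <- rows[[2]][rows[[2]]$species == sp, ]
    r3 <- rows[[3]][rows[[3]]$species == sp, ]
    for (x in seq_len(nrow(r1))) for (y in seq_len(nrow(r2))) {
      for (z in seq_len(nrow(r3))) {
        a <- r1[x, ]; b <- r2[y, ]; c <- r3[z, ]
        if (a$scaffold != b$scaffold || a$scaffold != c$scaffold) next
        if (.locus_gap(a, b) <= tandem_max &&
            .locus_gap(a, c) <= tandem_max &&
            .locus_gap(b, c) <= tandem_max) {
          return(list(genes = c(a$gene_id, b$gene_id, c$gene_id),
                      species = sp))
        }
      }
    }
  }
  NULL
}

#' Relabel duplications on annotated polyploidy branches
#'
#' Duplication calls sitting on a WGD/WGT-annotated species branch whose
#' witness copies lie on different scaffolds become
#' \code{wgd_retention}/\code{wgt_retention}.  Cluster-scale
#' co-duplication (several cross-scaffold calls on one branch) is noted as
#' corroborating evidence; on unannotated branches it is flagged as a
#' possible unannotated WGD.
#'
#' @param calls data frame of calls with \code{branch} column.
#' @param species_tree species tree with polyploidy annotations.
#' @return calls with updated types/notes.
#' @export
assign_polyploidy <- function(calls, species_tree) {
  pp <- attr(species_tree, "polyploidy")
  cross <- !is.na(calls$same_scaffold) & !calls$same_scaffold
  if (!is.null(pp) && nrow(pp)) {
    pp$branch <- vapply(pp$node, function(n) node_label(species_tree, n),
                        character(1))
    for (r in seq_len(nrow(pp))) {
      hit <- cross & calls$branch == pp$branch[r]
      if (!any(hit)) next
      calls$type[hit] <- if (pp$type[r] == "WGT") "wgt_retention"
                         else "wgd_retention"
      if (sum(hit) >= 2) {
        calls$note[hit] <- paste0("cluster-scale co-duplication (",
                                  sum(hit), " genes) on ", pp$type[r],
                                  " branch")
      }
    }
  }
  ## unannotated branches with cluster-scale cross-scaffold co-duplication
  still <- cross & calls$type == "transposed_duplication"
  tab <- table(calls$branch[still])
  for (b in names(tab)[tab >= 2]) {
    hit <- still & calls$branch == b
    calls$note[hit] <- paste0("possible unannotated WGD: ", tab[[b]],
                              " cross-scaffold co-duplications on branch ",
                              b)
  }
  calls
}

#' Classify every duplication of a reconciliation
#'
#' Runs [classify_duplication()] on each duplication node, collapses
#' nested triplications and assigns polyploidy branches.
#'
#' @param recon a [reconcile()] result.
#' @param loci \code{loci_table} for the extant genes.
#' @param thresholds a [classify_thresholds()].
#' @return data frame of event calls (one per event, with event ids).
#' @export
classify_events <- function(recon, loci,
                            thresholds = classify_thresholds()) {
  gt <- recon$gene_tree
  if (length(recon$duplications) == 0L) {
    return(data.frame(event_id = character(), node = integer(),
                      type = character(), branch = character(),
                      witnesses = character(), species = character(),
                      same_scaffold = logical(), distance = numeric(),
                      strands = character(), low_confidence = logical(),
                      note = character(), stringsAsFactors = FALSE))
  }
  calls <- do.call(rbind, lapply(recon$duplications, function(nd) {
    classify_duplication(nd, gt, loci, thresholds)
  }))
  calls$branch <- recon$duplication_branches[
    match(calls$node, recon$duplications)]
  calls <- collapse_triplications(calls, gt, loci, thresholds)
  calls <- assign_polyploidy(calls, recon$species_tree)
  cbind(data.frame(event_id = sprintf("c%03d", seq_len(nrow(calls)))),
        calls[, c("node", "type", "branch", "witnesses", "species",
                  "same_scaffold", "distance", "strands",
                  "low_confidence", "note")],
        row.names = NULL)
}

#' Per-branch event table and per-species copy-number table
#'
#' @param calls output of [classify_events()].
#' @param losses loss data frame from [reconcile()].
#' @param gene_tree classed gene tree (terminal-branch classes define each
#'   extant gene's clade membership).
#' @param species_tree species tree.
#' @return list with \code{per_branch} (one row per species branch, one
#'   column per event type plus losses) and \code{copy_number} (species x
#'   clade-class counts with a totals row).
#' @export
summarize_events <- function(calls, losses, gene_tree, species_tree) {
  species_tree <- ensure_node_labels(species_tree)
  nn <- length(species_tree$tip.label) + species_tree$Nnode
  branches <- vapply(seq_len(nn), function(n) node_label(species_tree, n),
                     character(1))
  types <- c("tandem_duplication", "tandem_triplication",
             "inverted_duplication", "segmental_duplication",
             "transposed_duplication", "wgd_retention", "wgt_retention",
             "unresolved")
  per_branch <- matrix(0L, nrow = nn, ncol = length(types) + 1L,
                       dimnames = list(branches, c(types, "loss")))
  if (nrow(calls)) {
    t1 <- table(factor(calls$branch, branches),
                factor(calls$type, types))
    per_branch[, types] <- per_branch[, types] + as.matrix(t1)
  }
  if (nrow(losses)) {
    t2 <- table(factor(losses$branch, branches))
    per_branch[, "loss"] <- as.integer(t2)
  }
  per_branch <- as.data.frame(per_branch)
  per_branch <- cbind(branch = rownames(per_branch), per_branch,
                      row.names = NULL)
  ## copy numbers per species and clade class
  nt <- length(gene_tree$tip.label)
  cls <- edge_classes(gene_tree)
  term_class <- vapply(seq_len(nt), function(v)
    cls[match(v, gene_tree$edge[, 2])], character(1))
  spp <- tip_species(gene_tree$tip.label)
  class_levels <- sort(unique(term_class))
  cn <- table(factor(spp, sort(species_tree$tip.label)),
              factor(term_class, class_levels))
  cn <- as.data.frame.matrix(cn)
  cn <- rbind(cn, total = colSums(cn))
  cn <- cbind(species = rownames(cn), cn, row.names = NULL)
  list(per_branch = per_branch, copy_number = cn)
}
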