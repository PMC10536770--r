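## Forward simulator of gene-family evolution along a species tree.
##
## Each gene lineage evolves by independent Poisson processes for tandem,
## inverted, segmental and transposed duplication, tandem triplication and
## loss. Polyploidy (WGD/WGT) branches duplicate every gene, cluster-wise
## by scaffold, onto parallel sub-genome scaffolds with partial retention.
## The simulator records the true gene tree, an event log and genomic
## coordinates for every surviving locus, so downstream inference
## (reconciliation, mechanism classification, selection analysis) can be
## tested against known truth.

DUP_TYPES <- c("tandem_duplication", "tandem_triplication",
               "inverted_duplication", "segmental_duplication",
               "transposed_duplication")

#' Simulation configuration
#'
#' Collects every knob of the gene-family simulator.  Rates are per gene
#' lineage per unit branch length (time measured in the species tree's
#' units; with \code{subs_rate = 1} these are expected substitutions per
#' codon).
#'
#' @param rates named numeric: \code{tandem}, \code{triplication},
#'   \code{inverted}, \code{segmental}, \code{transposed}, \code{loss}.
#' @param tandem_offset_kbp range (kbp) of the gap between a tandem (or
#'   inverted) copy and its parent locus; default 2--50 kbp, bracketing the
#'   12--13 kbp tandem pairs seen in real FLC-like families.
#' @param segmental_offset_kbp range (kbp) of the same-scaffold offset of
#'   segmental duplicates; default 500--2000 kbp.
#' @param root_genes character vector naming the ancestral genes present at
#'   the family root (default one FLC-like and one MAF-like gene).
#' @param root_stem time before the species root at which the root genes
#'   join (the age of the ancestral duplication separating them).
#' @param kappa,omega_by_class,pi,n_codons codon-model parameters used to
#'   evolve coding sequences along the true gene tree (\code{pi = NULL}
#'   means uniform over the 61 sense codons).
#' @param subs_rate substitutions per codon per unit species-tree time;
#'   gene-tree branch lengths are time differences times this rate.
#' @param intron_bp intron length of the canonical 7-exon gene model.
#' @param n_exons number of coding exons per locus (canonical 7).
#' @param forced_events list of deterministic events, each a list with
#'   \code{branch} (species-tree node label at the child end of the
#'   branch), \code{time_frac} in (0,1), a target selector (\code{gene}:
#'   root-gene ancestor, and/or \code{class}: current branch class of the
#'   lineage), and optionally \code{classes}: the branch classes assigned
#'   to the daughter lineages.
#' @param class_activation list of lists with \code{gene}, \code{node},
#'   \code{class}: lineages descending from \code{gene} switch to
#'   \code{class} when they enter the species clade rooted at \code{node}.
#' @param root_class named character: initial branch class per root gene
#'   (default background).
#' @param rate_scale_by_class named numeric: multiplier applied to all
#'   duplication and loss rates for lineages of a given branch class
#'   (classes not listed use 1).  Default scales FLC s.str. lineages to
#'   0.15, reflecting the far lower duplication/loss turnover of FLC-like
#'   genes s.str. compared to MAF-like genes.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(rates = c(tandem = 1.2, triplication = 0.3,
                                 inverted = 0.25, segmental = 0.15,
                                 transposed = 0.25, loss = 0.9),
                       tandem_offset_kbp = c(2, 50),
                       segmental_offset_kbp = c(500, 2000),
                       root_genes = c("FLC", "MAF"),
                       root_stem = 0.1,
                       kappa = 1.99,
                       omega_by_class = c(background = 0.33, MAF45 = 0.41,
                                          MAF123 = 0.35, FLC_sstr = 0.21),
                       pi = NULL, n_codons = 196, subs_rate = 1,
                       intron_bp = 300, n_exons = 7,
                       forced_events = list(),
                       class_activation = list(),
                       root_class = NULL,
                       rate_scale_by_class = c(FLC_sstr = 0.15)) {
  need <- c("tandem", "triplication", "inverted", "segmental", "transposed",
            "loss")
  miss <- setdiff(need, names(rates))
  if (length(miss)) stop("rates lacks: ", paste(miss, collapse = ", "))
  if (any(rates < 0)) stop("rates must be >= 0")
  if (any(omega_by_class <= 0)) stop("omega values must be > 0")
  if (is.null(pi)) pi <- stats::setNames(rep(1 / 61, 61), CODONS61)
  if (abs(sum(pi) - 1) > 1e-6) stop("pi must sum to 1")
  if (length(root_genes) == 0) stop("need at least one root gene")
  if (is.null(root_class)) {
    root_class <- stats::setNames(rep("background", length(root_genes)),
                                  root_genes)
  }
  structure(list(rates = rates[need],
                 tandem_offset_kbp = tandem_offset_kbp,
                 segmental_offset_kbp = segmental_offset_kbp,
                 root_genes = root_genes, root_stem = root_stem,
                 kappa = kappa, omega_by_class = omega_by_class, pi = pi,
                 n_codons = n_codons, subs_rate = subs_rate,
                 intron_bp = intron_bp, n_exons = n_exons,
                 forced_events = forced_events,
                 class_activation = class_activation,
                 root_class = root_class,
                 rate_scale_by_class = rate_scale_by_class),
            class = "sim_config")
}

#' Annotate a species-tree branch as a polyploidy event
#'
#' @param tree species tree (\code{phylo} with node labels).
#' @param branch tip label or internal node label at the child end of the
#'   branch.
#' @param type \code{"WGD"} or \code{"WGT"}.
#' @param retention probability that a duplicated gene is retained in each
#'   extra sub-genome.
#' @return tree with an updated \code{polyploidy} attribute (data frame
#'   with columns node, type, retention).
#' @export
annotate_polyploidy <- function(tree, branch, type = c("WGD", "WGT"),
                                retention = 0.5) {
  type <- match.arg(type)
  if (retention < 0 || retention > 1) stop("retention must be in [0,1]")
  node <- .node_by_label(tree, branch)
  pp <- attr(tree, "polyploidy")
  if (is.null(pp)) {
    pp <- data.frame(node = integer(), type = character(),
                     retention = numeric())
  }
  pp <- rbind(pp, data.frame(node = node, type = type,
                             retention = retention))
  attr(tree, "polyploidy") <- pp
  tree
}

.node_by_label <- function(tree, label) {
  nt <- length(tree$tip.label)
  i <- match(label, tree$tip.label)
  if (!is.na(i)) return(i)
  j <- match(label, tree$node.label)
  if (is.na(j)) stop("no node labelled '", label, "' in the species tree")
  nt + j
}

node_label <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) tree$tip.label[node] else tree$node.label[node - nt]
}

#' Give every internal node of a tree a unique label
#' @param tree \code{phylo}.
#' @param prefix label prefix for unlabelled nodes.
#' @return tree with complete node labels.
#' @export
ensure_node_labels <- function(tree, prefix = "n") {
  if (is.null(tree$node.label)) tree$node.label <- rep("", tree$Nnode)
  blank <- !nzchar(tree$node.label)
  tree$node.label[blank] <- paste0(prefix, which(blank))
  tree
}

## ---- simulator core ---------------------------------------------------

#' Simulate a gene family along a species tree
#'
#' Forward simulation of the full gene-family history: Poisson duplication
#' and loss processes per lineage, deterministic forced events, and
#' polyploidy branches duplicating whole scaffold clusters.  Coding
#' sequences are evolved along the true gene tree under the configured
#' codon branch model.
#'
#' @param species_tree rooted binary \code{phylo} with unique tip labels;
#'   internal nodes are labelled automatically when unlabelled.  Polyploidy
#'   annotations from [annotate_polyploidy()] are honoured.
#' @param config a [sim_config()].
#' @param seed integer seed; identical seeds give identical output.
#' @return list with components \code{gene_tree} (classed \code{phylo},
#'   tips \code{"species|gene_id"}; \code{NULL} if the family went
#'   extinct), \code{events} (data frame: event_id, type, branch, time,
#'   parent_gene, child_genes), \code{loci} (a \code{loci_table} with CDS),
#'   \code{alignment} (named character vector of gap-free CDS keyed by tip
#'   label), \code{extinct} flag, plus the species tree and config used.
#' @export
simulate_gene_family <- function(species_tree, config = sim_config(),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  species_tree <- ensure_node_labels(species_tree)
  check_species_tree(species_tree)
  st <- new.env(parent = emptyenv())
  st$nodes <- list()
  st$events <- list()
  st$counter <- 0L
  st$scf_counter <- 0L
  st$tree <- species_tree
  st$cfg <- config
  st$depth <- ape::node.depth.edgelength(species_tree)

  cds_len <- 3L * config$n_codons
  span <- cds_len + (config$n_exons - 1L) * config$intron_bp
  ## root genes: one per ancestral family member, on separate scaffolds
  roots <- lapply(seq_along(config$root_genes), function(i) {
    g <- config$root_genes[i]
    list(id = g, birth = -config$root_stem, parent = "__root__",
         class = config$root_class[[g]], root_gene = g,
         scaffold = paste0("scf_", g), start = 1000000L,
         end = 1000000L + span, strand = "+")
  })
  st$nodes[["__root__"]] <- list(id = "__root__", time = -config$root_stem,
                                 parent = NA_character_,
                                 class = "background", type = "root",
                                 children = character())
  root_sp <- length(species_tree$tip.label) + 1L
  survivors <- .sim_node(st, root_sp, roots, t_now = 0)

  events <- .events_df(st)
  if (length(survivors) == 0L) {
    return(list(gene_tree = NULL, events = events, loci = NULL,
                alignment = NULL, extinct = TRUE,
                species_tree = species_tree, config = config))
  }
  gt <- .build_gene_tree(st, config)
  aln <- evolve_codon_sequences(gt$tree, config$kappa,
                                config$omega_by_class, config$pi,
                                config$n_codons)
  loci <- .build_loci(st, aln, config)
  list(gene_tree = gt$tree, events = events, loci = loci, alignment = aln,
       extinct = FALSE, species_tree = species_tree, config = config)
}

check_species_tree <- function(tree) {
  if (!ape::is.rooted(tree) || !ape::is.binary(tree)) {
    stop("species tree must be rooted and binary")
  }
  if (anyDuplicated(tree$tip.label)) stop("duplicate species names")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("species tree needs non-negative branch lengths")
  }
  invisible(tree)
}

.new_id <- function(st) {
  st$counter <- st$counter + 1L
  paste0("g", st$counter)
}

.log_event <- function(st, type, branch, time, parent, children) {
  st$events[[length(st$events) + 1L]] <-
    data.frame(type = type, branch = branch, time = time,
               parent_gene = parent,
               child_genes = paste(children, collapse = ","),
               stringsAsFactors = FALSE)
}

.events_df <- function(st) {
  if (length(st$events) == 0L) {
    return(data.frame(event_id = character(), type = character(),
                      branch = character(), time = numeric(),
                      parent_gene = character(), child_genes = character(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, st$events)
  df <- df[order(df$time), , drop = FALSE]
  cbind(data.frame(event_id = sprintf("e%03d", seq_len(nrow(df)))), df,
        row.names = NULL)
}

## close a lineage segment: it becomes a gene-tree node
.close <- function(st, lin, time, type, species = NA_character_) {
  node <- list(id = lin$id, time = time, parent = lin$parent,
               class = lin$class, type = type, children = character(),
               species = species, scaffold = lin$scaffold,
               start = lin$start, end = lin$end, strand = lin$strand,
               root_gene = lin$root_gene)
  st$nodes[[lin$id]] <- node
  p <- st$nodes[[lin$parent]]
  p$children <- c(p$children, lin$id)
  st$nodes[[lin$parent]] <- p
  invisible(node)
}

.child_of <- function(lin, st, id = NULL, ...) {
  upd <- list(...)
  out <- lin
  if (is.null(id)) id <- .new_id(st)
  out$id <- id
  out$parent <- lin$id
  for (nm in names(upd)) out[[nm]] <- upd[[nm]]
  out
}

## apply one random event to lineage `lin` at time `te` on species branch
## `branch`; returns the daughter lineages that continue evolving
.apply_event <- function(st, lin, te, branch, ev) {
  cfg <- st$cfg
  span <- lin$end - lin$start
  gap <- function(range_kbp) {
    round(stats::runif(1, range_kbp[1], range_kbp[2]) * 1000)
  }
  place_after <- function(l, offset, strand = l$strand) {
    s <- l$end + offset
    list(scaffold = l$scaffold, start = s, end = s + span, strand = strand)
  }
  flip <- function(s) if (s == "+") "-" else "+"
  switch(ev,
    loss = {
      .close(st, lin, te, "loss")
      .log_event(st, "loss", branch, te, lin$id, character())
      list()
    },
    tandem = {
      .close(st, lin, te, "dup")
      cont <- .child_of(lin, st)
      pos <- place_after(lin, gap(cfg$tandem_offset_kbp))
      copy <- .child_of(lin, st, scaffold = pos$scaffold, start = pos$start,
                        end = pos$end, strand = pos$strand)
      .log_event(st, "tandem_duplication", branch, te, lin$id,
                 c(cont$id, copy$id))
      list(cont, copy)
    },
    inverted = {
      .close(st, lin, te, "dup")
      cont <- .child_of(lin, st)
      pos <- place_after(lin, gap(cfg$tandem_offset_kbp),
                         strand = flip(lin$strand))
      copy <- .child_of(lin, st, scaffold = pos$scaffold, start = pos$start,
                        end = pos$end, strand = pos$strand)
      .log_event(st, "inverted_duplication", branch, te, lin$id,
                 c(cont$id, copy$id))
      list(cont, copy)
    },
    segmental = {
      .close(st, lin, te, "dup")
      cont <- .child_of(lin, st)
      pos <- place_after(lin, gap(cfg$segmental_offset_kbp))
      copy <- .child_of(lin, st, scaffold = pos$scaffold, start = pos$start,
                        end = pos$end, strand = pos$strand)
      .log_event(st, "segmental_duplication", branch, te, lin$id,
                 c(cont$id, copy$id))
      list(cont, copy)
    },
    transposed = {
      .close(st, lin, te, "dup")
      cont <- .child_of(lin, st)
      st$scf_counter <- st$scf_counter + 1L
      copy <- .child_of(lin, st,
                        scaffold = paste0("scf_t", st$scf_counter),
                        start = 1000000L, end = 1000000L + span)
      .log_event(st, "transposed_duplication", branch, te, lin$id,
                 c(cont$id, copy$id))
      list(cont, copy)
    },
    triplication = {
      ## atomic: one event, two extra adjacent copies; the true gene tree
      ## holds two nested binary nodes at the same instant
      .close(st, lin, te, "dup")
      cont <- .child_of(lin, st)
      inner <- .child_of(lin, st)
      .close(st, inner, te, "dup")
      p1 <- place_after(lin, gap(cfg$tandem_offset_kbp))
      c1 <- .child_of(inner, st, scaffold = p1$scaffold, start = p1$start,
                      end = p1$end, strand = p1$strand)
      gap2 <- gap(cfg$tandem_offset_kbp)
      c2 <- .child_of(inner, st, scaffold = p1$scaffold,
                      start = p1$end + gap2, end = p1$end + gap2 + span,
                      strand = p1$strand)
      .log_event(st, "tandem_triplication", branch, te, lin$id,
                 c(cont$id, c1$id, c2$id))
      list(cont, c1, c2)
    },
    stop("unknown event type ", ev))
}

## evolve one lineage from `t_from` to `t_to` on the branch whose child
## end is labelled `branch`; returns surviving lineages at t_to
.evolve_lineage <- function(st, lin, t_from, t_to, branch) {
  rates <- st$cfg$rates
  sc <- st$cfg$rate_scale_by_class
  if (!is.null(sc) && lin$class %in% names(sc)) {
    rates <- rates * sc[[lin$class]]
  }
  total <- sum(rates)
  t <- t_from
  repeat {
    if (total <= 0) return(list(lin))
    dt <- stats::rexp(1, total)
    if (t + dt >= t_to) return(list(lin))
    t <- t + dt
    ev <- sample(names(rates), 1, prob = rates)
    kids <- .apply_event(st, lin, t, branch, ev)
    if (length(kids) == 0L) return(list())
    out <- list()
    for (k in kids) {
      out <- c(out, .evolve_lineage(st, k, t, t_to, branch))
    }
    return(out)
  }
}

## whole-genome duplication/triplication at the start of a branch:
## cluster-wise (per scaffold) copy of every lineage with per-gene
## retention in each extra sub-genome
.apply_polyploidy <- function(st, lineages, t0, branch, type, retention) {
  n_extra <- if (type == "WGT") 2L else 1L
  ev_type <- if (type == "WGT") "wgt_retention" else "wgd_retention"
  cur <- lineages
  extras <- list()
  for (sg in seq_len(n_extra)) {
    tag <- paste0("_", tolower(type), sg + 1L)
    for (i in seq_along(cur)) {
      if (stats::runif(1) < retention) {
        lin <- cur[[i]]
        .close(st, lin, t0, "dup")
        cont <- .child_of(lin, st)
        copy <- .child_of(lin, st, scaffold = paste0(lin$scaffold, tag))
        .log_event(st, ev_type, branch, t0, lin$id, c(cont$id, copy$id))
        cur[[i]] <- cont
        extras <- c(extras, list(copy))
      }
    }
  }
  c(cur, extras)
}

## recurse into the subtree rooted at species node `sp`, with `lineages`
## alive at time `t_now` (the time of sp's parent end of the branch is
## handled by the caller; here t_now is sp's own time)
.sim_node <- function(st, sp, lineages, t_now) {
  tree <- st$tree
  nt <- length(tree$tip.label)
  if (sp <= nt) {
    species <- tree$tip.label[sp]
    for (lin in lineages) .close(st, lin, t_now, "leaf", species = species)
    return(lineages)
  }
  ## class activation at this species node
  for (ca in st$cfg$class_activation) {
    if (identical(node_label(tree, sp), ca$node)) {
      lineages <- lapply(lineages, function(l) {
        if (l$root_gene == ca$gene) l$class <- ca$class
        l
      })
    }
  }
  out <- list()
  for (e in which(tree$edge[, 1] == sp)) {
    child <- tree$edge[e, 2]
    t_child <- st$depth[child]
    branch <- node_label(tree, child)
    ## speciation: every live lineage bifurcates
    branch_lins <- lapply(lineages, function(l) {
      if (is.null(st$nodes[[l$id]])) .close(st, l, t_now, "spec")
      .child_of(l, st)
    })
    ## polyploidy annotated on this branch happens right after speciation
    pp <- attr(tree, "polyploidy")
    if (!is.null(pp) && child %in% pp$node) {
      row <- pp[match(child, pp$node), ]
      branch_lins <- .apply_polyploidy(st, branch_lins, t_now, branch,
                                       row$type, row$retention)
    }
    ## forced events split the branch into segments
    forced <- Filter(function(f) identical(f$branch, branch),
                     st$cfg$forced_events)
    seg_times <- t_now
    if (length(forced)) {
      fr <- vapply(forced, function(f) f$time_frac, numeric(1))
      o <- order(fr)
      forced <- forced[o]
      seg_times <- c(seg_times, t_now + sort(fr) * (t_child - t_now))
    }
    seg_times <- c(seg_times, t_child)
    cur <- branch_lins
    for (s in seq_len(length(seg_times) - 1L)) {
      nxt <- list()
      for (l in cur) {
        nxt <- c(nxt, .evolve_lineage(st, l, seg_times[s],
                                      seg_times[s + 1L], branch))
      }
      cur <- nxt
      if (s <= length(forced)) {
        cur <- .apply_forced(st, cur, forced[[s]], seg_times[s + 1L],
                             branch)
      }
    }
    out <- c(out, .sim_node(st, child, cur, t_child))
  }
  out
}

.apply_forced <- function(st, lineages, f, te, branch) {
  idx <- which(vapply(lineages, function(l) {
    (is.null(f[["gene"]]) || l$root_gene == f[["gene"]]) &&
      (is.null(f[["class"]]) || l$class == f[["class"]])
  }, logical(1)))
  if (length(idx) == 0L) return(lineages)  # target lineage already extinct
  lin <- lineages[[idx[1]]]
  kids <- .apply_event(st, lin, te, branch,
                       switch(f[["type"]] %||% "tandem_duplication",
                              tandem_duplication = "tandem",
                              inverted_duplication = "inverted",
                              segmental_duplication = "segmental",
                              transposed_duplication = "transposed",
                              tandem_triplication = "triplication"))
  if (!is.null(f[["classes"]])) {
    for (i in seq_along(kids)) {
      kids[[i]]$class <- f[["classes"]][min(i, length(f[["classes"]]))]
    }
  }
  c(lineages[-idx[1]], kids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- outputs ----------------------------------------------------------

## prune dead subtrees / suppress unary nodes; emit newick + class map
.build_gene_tree <- function(st, cfg) {
  nodes <- st$nodes
  prune <- function(id) {
    nd <- nodes[[id]]
    if (nd$type == "leaf") {
      return(list(id = id, label = paste0(nd$species, "|", id),
                  time = nd$time, class = nd$class, kids = NULL))
    }
    if (nd$type == "loss") return(NULL)
    kids <- Filter(Negate(is.null), lapply(nd$children, prune))
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) return(kids[[1]])
    list(id = id, label = id, time = nd$time, class = nd$class, kids = kids)
  }
  root <- prune("__root__")
  if (is.null(root)) return(list(tree = NULL))
  if (is.null(root$kids)) {
    stop("gene family reduced to a single gene; no tree to build")
  }
  nwk <- function(node, parent_time) {
    len <- (node$time - parent_time) * cfg$subs_rate
    if (is.null(node$kids)) {
      sprintf("%s:%.8f", node$label, len)
    } else {
      sprintf("(%s)%s:%.8f",
              paste(vapply(node$kids, nwk, character(1), node$time),
                    collapse = ","),
              node$label, len)
    }
  }
  txt <- sprintf("(%s)%s;",
                 paste(vapply(root$kids, nwk, character(1), root$time),
                       collapse = ","),
                 root$label)
  tree <- ape::read.tree(text = txt)
  ## per-edge class from the child node's (bottom) lineage segment
  classes <- character(nrow(tree$edge))
  ntt <- length(tree$tip.label)
  class_of <- function(lab) {
    id <- sub("^.*\\|", "", lab)
    nd <- nodes[[id]]
    if (is.null(nd)) "background" else nd$class
  }
  for (e in seq_len(nrow(tree$edge))) {
    v <- tree$edge[e, 2]
    lab <- if (v <= ntt) tree$tip.label[v] else tree$node.label[v - ntt]
    classes[e] <- class_of(lab)
  }
  attr(tree, "edge_class") <- classes
  list(tree = tree)
}

## exon structure of the canonical gene model: first exon carries the
## MADS-box-sized chunk, the remainder is split evenly
.exon_matrix <- function(start, cds_len, cfg) {
  k <- cfg$n_exons
  first <- min(180L, cds_len - (k - 1L))
  rest <- cds_len - first
  base <- rest %/% (k - 1L)
  lens <- c(first, rep(base, k - 1L))
  lens[k] <- lens[k] + rest - base * (k - 1L)
  starts <- start + cumsum(c(0L, lens[-k] + cfg$intron_bp))
  cbind(start = starts, end = starts + lens)
}

.build_loci <- function(st, aln, cfg) {
  leaf_ids <- names(st$nodes)[vapply(st$nodes, function(n)
    identical(n$type, "leaf"), logical(1))]
  loci <- lapply(leaf_ids, function(id) {
    nd <- st$nodes[[id]]
    lab <- paste0(nd$species, "|", id)
    cds <- unname(aln[lab])
    gene_locus(id, nd$species, nd$scaffold, nd$start, nd$end, nd$strand,
               exons = .exon_matrix(nd$start, nchar(cds), cfg), cds = cds)
  })
  loci_to_table(loci)
}
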