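test_that("LCA mapping on hand-computed examples", {
  sp <- abc_tree()
  gt <- ape::read.tree(text = "((A|a1:1,B|b1:1):1,C|c1:2);")
  m <- lca_map(gt, sp)
  ## species nodes: A=1, B=2, C=3, r=4, ab=5
  expect_identical(m[1:3], c(1L, 2L, 3L))
  expect_identical(m[4], 4L)  # gene root -> r
  expect_identical(m[5], 5L)  # (a1,b1) -> ab
  expect_length(infer_duplications(gt, m), 0)

  gt2 <- ape::read.tree(text = "((A|a1:1,B|b1:1):1,(A|a2:1,C|c1:1):1);")
  m2 <- lca_map(gt2, sp)   # 4 tips: root = 5, (a1,b1) = 6, (a2,c1) = 7
  expect_identical(m2[5], 4L)   # root -> r
  expect_identical(m2[6], 5L)   # (a1,b1) -> ab
  expect_identical(m2[7], 4L)   # (a2,c1) -> r
  expect_identical(infer_duplications(gt2, m2), 5L)  # only the gene root

  bad <- ape::read.tree(text = "((A|a1:1,X|x1:1):1,C|c1:2);")
  expect_error(lca_map(bad, sp), "X")
})

test_that("loss counting matches the hand-computed example", {
  sp <- abc_tree()
  gt2 <- ape::read.tree(text = "((A|a1:1,B|b1:1):1,(A|a2:1,C|c1:1):1);")
  r <- reconcile(gt2, sp)
  expect_identical(nrow(r$losses), 2L)
  expect_setequal(r$losses$branch, c("B", "C"))
  expect_identical(unname(r$ancestral_counts),
                   c(2L, 1L, 1L, 2L, 2L))  # A B C r ab

  ## duplication inside one species
  gt3 <- ape::read.tree(text = "((A|a1:1,A|a2:1):1,B|b1:2);")
  r3 <- reconcile(gt3, sp)
  expect_identical(r3$duplication_branches, "A")
  expect_identical(nrow(r3$losses), 0L)

  ## congruent tree: no losses, counts all 1
  gt1 <- ape::read.tree(text = "((A|a1:1,B|b1:1):1,C|c1:2);")
  r1 <- reconcile(gt1, sp)
  expect_identical(nrow(r1$losses), 0L)
  expect_true(all(r1$ancestral_counts == 1L))
})

test_that("terminal losses appear when a species lacks the family", {
  sp <- abc_tree()
  ## gene root maps to r because C has a copy; B lost it
  gt <- ape::read.tree(text = "((A|a1:1,C|c1:1):1,A|a2:2);")
  r <- reconcile(gt, sp)
  expect_true("B" %in% r$losses$branch)
})

test_that("polytomies are rejected", {
  sp <- abc_tree()
  gt <- ape::read.tree(text = "((A|a1:1,B|b1:1,C|c1:1)n:1,A|a2:2)r;")
  expect_error(reconcile(gt, sp), "polytom")
})

test_that("reconciliation recovers simulated histories at loss rate 0", {
  cfg <- sim_config(rates = c(tandem = 0.8, triplication = 0.2,
                              inverted = 0.2, segmental = 0.15,
                              transposed = 0.25, loss = 0),
                    root_genes = "G", n_codons = 3)
  tested <- 0
  for (s in 1:100) {
    sim <- simulate_gene_family(species_tree_preset("toy4"), cfg,
                                seed = 2000 + s)
    if (is.null(sim$gene_tree) || length(sim$gene_tree$tip.label) < 2) next
    r <- reconcile(sim$gene_tree, sim$species_tree)
    logged_binary <-
      sum(sim$events$type %in% c("tandem_duplication",
                                 "inverted_duplication",
                                 "segmental_duplication",
                                 "transposed_duplication")) +
      2L * sum(sim$events$type == "tandem_triplication")
    expect_identical(length(r$duplications), logged_binary)
    expect_identical(nrow(r$losses), 0L)
    tested <- tested + 1
  }
  expect_gte(tested, 80)
})

test_that("with losses, inferred counts never exceed logged counts", {
  cfg <- sim_config(rates = c(tandem = 0.8, triplication = 0.2,
                              inverted = 0.2, segmental = 0.1,
                              transposed = 0.2, loss = 0.8),
                    root_genes = "G", n_codons = 3)
  for (s in 1:30) {
    sim <- simulate_gene_family(species_tree_preset("toy4"), cfg,
                                seed = 3000 + s)
    if (is.null(sim$gene_tree) || length(sim$gene_tree$tip.label) < 2) next
    r <- reconcile(sim$gene_tree, sim$species_tree)
    logged_binary <-
      sum(sim$events$type %in% c("tandem_duplication",
                                 "inverted_duplication",
                                 "segmental_duplication",
                                 "transposed_duplication")) +
      2L * sum(sim$events$type == "tandem_triplication")
    expect_lte(length(r$duplications), logged_binary)
    expect_lte(nrow(r$losses), sum(sim$events$type == "loss"))
  }
})

test_that("ancestral counts equal the event-log replay at loss rate 0", {
  ## independent oracle: replay the event log along each root-to-node
  ## path, adding copies per duplication event on the path's branches
  cfg <- sim_config(rates = c(tandem = 0.7, triplication = 0.2,
                              inverted = 0.15, segmental = 0.1,
                              transposed = 0.2, loss = 0),
                    root_genes = c("F", "M"), n_codons = 3)
  for (s in 1:50) {
    sim <- simulate_gene_family(species_tree_preset("toy4"), cfg,
                                seed = 4000 + s)
    if (is.null(sim$gene_tree)) next
    r <- reconcile(sim$gene_tree, sim$species_tree)
    sp <- ensure_node_labels(sim$species_tree)
    paths <- genefam:::.ancestor_paths(sp)
    delta <- c(tandem_duplication = 1, inverted_duplication = 1,
               segmental_duplication = 1, transposed_duplication = 1,
               tandem_triplication = 2, wgd_retention = 1,
               wgt_retention = 1)
    nn <- length(sp$tip.label) + sp$Nnode
    for (node in seq_len(nn)) {
      on_path <- vapply(seq_len(nrow(sim$events)), function(i) {
        b <- genefam:::.node_by_label(sp, sim$events$branch[i])
        b %in% setdiff(paths[[node]], length(sp$tip.label) + 1L)
      }, logical(1))
      expected <- 2L + sum(delta[sim$events$type[on_path]])
      expect_identical(unname(r$ancestral_counts[node]),
                       as.integer(expected),
                       info = paste("seed", s, "node", node))
    }
  }
})

test_that("LCA mapping minimises duplications (brute force, <= 6 leaves)", {
  sp <- abc_tree()
  sp_paths <- genefam:::.ancestor_paths(sp)
  is_anc <- function(a, b) a %in% sp_paths[[b]]  # a ancestor-or-equal of b
  gene_trees <- c(
    "((A|g1:1,B|g2:1):1,(A|g3:1,C|g4:1):1);",
    "(((A|g1:1,C|g2:1):1,B|g3:1):1,(B|g4:1,C|g5:1):1);",
    "((A|g1:1,A|g2:1):1,((B|g3:1,C|g4:1):1,C|g5:1):1);",
    "(((A|g1:1,B|g2:1):1,(A|g3:1,B|g4:1):1):1,(C|g5:1,C|g6:1):1);")
  for (txt in gene_trees) {
    gt <- ape::read.tree(text = txt)
    m <- lca_map(gt, sp)
    lca_dups <- length(infer_duplications(gt, m))
    nt <- length(gt$tip.label)
    nint <- gt$Nnode
    ## enumerate all consistent mappings of internal nodes
    kids <- split(gt$edge[, 2], gt$edge[, 1])
    sp_kids <- split(sp$edge[, 2], sp$edge[, 1])
    grid <- do.call(expand.grid,
                    rep(list(seq_len(length(sp$tip.label) + sp$Nnode)),
                        nint))
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      M <- c(m[seq_len(nt)], as.integer(grid[g, ]))
      ok <- TRUE
      dups <- 0
      for (u in (nt + 1L):(nt + nint)) {
        ch <- kids[[as.character(u)]]
        if (!all(vapply(ch, function(v) is_anc(M[u], M[v]), logical(1)))) {
          ok <- FALSE
          break
        }
        ## u is a speciation only if its children descend through
        ## different children of M(u)
        sides <- vapply(ch, function(v) {
          if (M[v] == M[u]) return(NA_integer_)
          path <- sp_paths[[M[v]]]
          path[match(M[u], path) - 1L]
        }, integer(1))
        if (anyNA(sides) || sides[1] == sides[2]) dups <- dups + 1
      }
      if (ok) best <- min(best, dups)
    }
    expect_identical(lca_dups, as.integer(best), info = txt)
  }
})

test_that("leaf-level ancestral counts equal observed per-species counts", {
  sim <- make_fixture("brassicaceae_like", seed = 2)
  r <- reconcile(sim$gene_tree, sim$species_tree)
  obs <- table(genefam:::tip_species(sim$gene_tree$tip.label))
  for (spp in names(obs)) {
    expect_identical(unname(r$ancestral_counts[spp]),
                     as.integer(obs[[spp]]))
  }
})

test_that("the Brassicaceae-like ancestor holds one FLC and one MAF gene", {
  ## suppress the stochastic events: the ancestral copy numbers are then
  ## fixed by the preset's forced duplications alone
  cfg <- preset_config("brassicaceae_like", rates = zero_rates())
  sim <- make_fixture("brassicaceae_like", seed = 2, config = cfg)
  r <- reconcile(sim$gene_tree, sim$species_tree)
  expect_identical(unname(r$ancestral_counts[["root"]]), 1L)
  expect_identical(unname(r$ancestral_counts[["Tarenaya_like"]]), 1L)
  ## after the FLC/MAF split on the Brassicaceae stem: 2 copies
  expect_identical(unname(r$ancestral_counts[["brassicaceae"]]), 2L)
  ## after the MAF1/2/3-vs-MAF4/5 split on the core stem: 3 copies
  expect_identical(unname(r$ancestral_counts[["core"]]), 3L)
})
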