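## A small constructed family used by most classification tests: a
## duplication node in species S with configurable coordinates.
two_clade_tree <- function() {
  gt <- ape::read.tree(text = "((S|g1:1,S|g2:1)d:1,T|g3:2)r;")
  gt
}

test_that("classify_duplication applies the coordinate rules", {
  gt <- two_clade_tree()
  base <- function(start2, end2, strand2 = "+", scaffold2 = "scf1") {
    genefam:::loci_to_table(list(
      make_locus("g1", "S", "scf1", 100000L, 103000L),
      gene_locus("g2", "S", scaffold2, start2, end2, strand2),
      make_locus("g3", "T", "scf9", 1L, 3000L)))
  }
  nt <- 3L
  dup <- nt + 2L  # node "d"
  ## 12 kbp apart, same strand -> tandem
  call <- classify_duplication(dup, gt, base(115000L, 118000L))
  expect_identical(call$type, "tandem_duplication")
  expect_equal(call$distance, 12000)
  ## 13 kbp apart, opposite strands -> inverted
  call <- classify_duplication(dup, gt, base(116000L, 119000L, "-"))
  expect_identical(call$type, "inverted_duplication")
  ## > 500 kbp, same scaffold -> segmental (confident)
  call <- classify_duplication(dup, gt, base(700000L, 703000L))
  expect_identical(call$type, "segmental_duplication")
  expect_false(call$low_confidence)
  ## gray zone between 100 and 500 kbp -> segmental, low confidence
  call <- classify_duplication(dup, gt, base(300000L, 303000L))
  expect_identical(call$type, "segmental_duplication")
  expect_true(call$low_confidence)
  ## different scaffold -> transposed
  call <- classify_duplication(dup, gt, base(100000L, 103000L,
                                             scaffold2 = "scf2"))
  expect_identical(call$type, "transposed_duplication")
})

test_that("duplications without a shared species are unresolved", {
  gt <- ape::read.tree(text = "((S|g1:1,U|g2:1)d:1,T|g3:2)r;")
  loci <- genefam:::loci_to_table(list(
    make_locus("g1", "S", "scf1", 100L, 3100L),
    make_locus("g2", "U", "scf1", 100L, 3100L),
    make_locus("g3", "T", "scf1", 100L, 3100L)))
  call <- classify_duplication(5L, gt, loci)
  expect_identical(call$type, "unresolved")
  expect_match(call$note, "disjoint")
})

test_that("nested simultaneous tandem pairs collapse to a triplication", {
  gt <- ape::read.tree(
    text = "(((S|g1:1,S|g2:1)d2:0,S|g3:1)d1:1,T|g4:2)r;")
  loci <- genefam:::loci_to_table(list(
    make_locus("g1", "S", "scf1", 100000L, 103000L),
    make_locus("g2", "S", "scf1", 113000L, 116000L),
    make_locus("g3", "S", "scf1", 126000L, 129000L),
    make_locus("g4", "T", "scf9", 1L, 3000L)))
  sp <- ape::read.tree(text = "(S:1,T:1)r;")
  rec <- reconcile(gt, sp)
  calls <- classify_events(rec, loci)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$type, "tandem_triplication")
  expect_setequal(strsplit(calls$witnesses, ",")[[1]],
                  c("g1", "g2", "g3"))

  ## sequential (non-simultaneous) events stay two tandem duplications
  gt2 <- ape::read.tree(
    text = "(((S|g1:1,S|g2:1)d2:0.4,S|g3:1.4)d1:1,T|g4:2)r;")
  rec2 <- reconcile(gt2, sp)
  calls2 <- classify_events(rec2, loci)
  expect_identical(sort(calls2$type),
                   c("tandem_duplication", "tandem_duplication"))

  ## copies on different scaffolds never merge
  loci3 <- genefam:::loci_to_table(list(
    make_locus("g1", "S", "scf1", 100000L, 103000L),
    make_locus("g2", "S", "scf2", 113000L, 116000L),
    make_locus("g3", "S", "scf3", 126000L, 129000L),
    make_locus("g4", "T", "scf9", 1L, 3000L)))
  calls3 <- classify_events(rec, loci3)
  expect_false(any(calls3$type == "tandem_triplication"))
})

test_that("duplications on separate species branches never merge", {
  ## the outer duplication maps to the (S1,S2) ancestor, the nested one
  ## to S1: tandem-type calls on different branches must stay separate
  gt <- ape::read.tree(text = paste0(
    "(((S1|g1:1,S1|g2:1)d2:0,(S1|g5:1,S2|g3:1)x:0)d1:1,T|g4:2)r;"))
  sp <- ape::read.tree(text = "((S1:1,S2:1)s:1,T:2)r;")
  loci <- genefam:::loci_to_table(list(
    make_locus("g1", "S1", "scf1", 100000L, 103000L),
    make_locus("g2", "S1", "scf1", 113000L, 116000L),
    make_locus("g5", "S1", "scf1", 140000L, 143000L),
    make_locus("g3", "S2", "scf1", 126000L, 129000L),
    make_locus("g4", "T", "scf9", 1L, 3000L)))
  rec <- reconcile(gt, sp)
  calls <- classify_events(rec, loci)
  expect_false(any(calls$type == "tandem_triplication"))
  expect_identical(nrow(calls), 2L)
  expect_setequal(calls$branch, c("s", "S1"))
})

test_that("polyploidy assignment relabels cross-scaffold calls", {
  sp <- ensure_node_labels(ape::read.tree(text = "(S:1,T:1)r;"))
  sp_wgt <- annotate_polyploidy(sp, "S", "WGT", retention = 1)
  gt <- two_clade_tree()
  cross <- genefam:::loci_to_table(list(
    make_locus("g1", "S", "scf1", 100000L, 103000L),
    make_locus("g2", "S", "scf1_wgt2", 100000L, 103000L),
    make_locus("g3", "T", "scf9", 1L, 3000L)))
  rec <- reconcile(gt, sp_wgt)
  calls <- classify_events(rec, cross)
  expect_identical(calls$type, "wgt_retention")
  ## same-scaffold 8 kbp pair on a WGT branch stays tandem
  near <- genefam:::loci_to_table(list(
    make_locus("g1", "S", "scf1", 100000L, 103000L),
    make_locus("g2", "S", "scf1", 111000L, 114000L),
    make_locus("g3", "T", "scf9", 1L, 3000L)))
  calls2 <- classify_events(reconcile(gt, sp_wgt), near)
  expect_identical(calls2$type, "tandem_duplication")
})

test_that("unannotated cluster-scale co-duplication is flagged", {
  ## two family members duplicated cross-scaffold on the same unannotated
  ## branch, as when a whole MAF cluster doubles after a hidden WGD
  gt <- ape::read.tree(text = paste0(
    "(((S|a1:1,S|a2:1)da:1,(S|b1:1,S|b2:1)db:1)n:1,T|c1:3)r;"))
  sp <- ape::read.tree(text = "(S:1,T:1)r;")
  loci <- genefam:::loci_to_table(list(
    make_locus("a1", "S", "scf1", 100000L, 103000L),
    make_locus("a2", "S", "scf1_dup", 100000L, 103000L),
    make_locus("b1", "S", "scf1", 120000L, 123000L),
    make_locus("b2", "S", "scf1_dup", 120000L, 123000L),
    make_locus("c1", "T", "scf9", 1L, 3000L)))
  rec <- reconcile(gt, sp)
  calls <- classify_events(rec, loci)
  trans <- calls[calls$type == "transposed_duplication", ]
  expect_identical(nrow(trans), 2L)
  expect_true(all(grepl("possible unannotated WGD", trans$note)))
})

test_that("summaries tally events per branch and copies per class", {
  ## no events: zero table, copy number 1 per root gene
  cfg <- sim_config(rates = zero_rates(), root_genes = "FLC",
                    n_codons = 10)
  sim <- simulate_gene_family(species_tree_preset("toy4"), cfg, seed = 1)
  rec <- reconcile(sim$gene_tree, sim$species_tree)
  calls <- classify_events(rec, sim$loci)
  summ <- summarize_events(calls, rec$losses, sim$gene_tree,
                           sim$species_tree)
  expect_true(all(summ$per_branch[, -1] == 0))
  expect_true(all(summ$copy_number$background[1:4] == 1))

  ## column sums equal surviving loci
  sim2 <- make_fixture("brassicaceae_like", seed = 2)
  rec2 <- reconcile(sim2$gene_tree, sim2$species_tree)
  calls2 <- classify_events(rec2, sim2$loci)
  summ2 <- summarize_events(calls2, rec2$losses, sim2$gene_tree,
                            sim2$species_tree)
  totals <- summ2$copy_number[summ2$copy_number$species == "total", -1]
  expect_equal(sum(unlist(totals)), nrow(sim2$loci))
  ## a species that lost every gene of a clade shows 0 in that cell
  cn <- summ2$copy_number
  expect_true(all(c("FLC_sstr", "MAF123", "MAF45") %in% names(cn)))
})

test_that("raising tandem_max never converts tandem into transposed", {
  cfg <- sim_config(rates = c(tandem = 0.8, triplication = 0.2,
                              inverted = 0.2, segmental = 0.15,
                              transposed = 0.3, loss = 0),
                    root_genes = "G", n_codons = 5)
  sim <- simulate_gene_family(species_tree_preset("core16"), cfg, seed = 8)
  rec <- reconcile(sim$gene_tree, sim$species_tree)
  lo <- classify_events(rec, sim$loci,
                        classify_thresholds(tandem_max = 50000))
  hi <- classify_events(rec, sim$loci,
                        classify_thresholds(tandem_max = 200000,
                                            segmental_min = 500000))
  for (nd in lo$node[lo$type == "tandem_duplication"]) {
    hit <- hi$type[hi$node == nd]
    if (length(hit)) expect_false(hit == "transposed_duplication")
  }
})

test_that("classifier type agreement with the event log is >= 95%", {
  cfg <- sim_config(rates = c(tandem = 1.2, triplication = 0.3,
                              inverted = 0.25, segmental = 0.15,
                              transposed = 0.25, loss = 0),
                    root_genes = c("FLC", "MAF"), n_codons = 10)
  tot <- 0
  agree <- 0
  for (s in 1:15) {
    sim <- simulate_gene_family(species_tree_preset("core16"), cfg,
                                seed = s)
    if (is.null(sim$gene_tree) || length(sim$gene_tree$tip.label) < 2) next
    rec <- reconcile(sim$gene_tree, sim$species_tree)
    calls <- classify_events(rec, sim$loci)
    ev <- sim$events[sim$events$type != "loss", ]
    nt <- length(sim$gene_tree$tip.label)
    for (i in seq_len(nrow(ev))) {
      nd <- match(ev$parent_gene[i], sim$gene_tree$node.label) + nt
      hit <- which(calls$node == nd)
      tot <- tot + 1
      if (length(hit) == 1 && calls$type[hit] == ev$type[i]) {
        agree <- agree + 1
      }
    }
  }
  expect_gte(tot, 100)
  expect_gte(agree / tot, 0.95)
})

test_that("classification is total: every duplication gets one call", {
  sim <- make_fixture("brassicaceae_like", seed = 4)
  rec <- reconcile(sim$gene_tree, sim$species_tree)
  calls <- classify_events(rec, sim$loci)
  merged <- sum(grepl("merged nested duplication", calls$note))
  expect_identical(nrow(calls) + merged, length(rec$duplications))
  expect_true(all(nzchar(calls$type)))
})
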