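test_that("trim_alignment applies both thresholds exactly", {
  aln <- c(s1 = "A-AAA", s2 = "A-AAC", s3 = "AAAAG", s4 = "A--AT")
  ## column 2: 75% gaps -> dropped; column 3: one gap (25%) -> kept;
  ## column 5: majority residue frequency 1/4 = 0.25 -> kept at 0.1
  tr <- trim_alignment(aln, max_gap_fraction = 0.5, min_identity = 0.1)
  expect_identical(tr$kept, c(1L, 3L, 4L, 5L))
  tr2 <- trim_alignment(aln, max_gap_fraction = 0.5, min_identity = 0.3)
  expect_identical(tr2$kept, c(1L, 3L, 4L))

  clean <- c(a = "MKV", b = "MKV", c = "MKV")
  expect_identical(trim_alignment(clean)$alignment, clean)

  ## hand-built 4x10 with three designed failing columns (2, 5, 9)
  hand <- c(a = "M-KVA-LLWT", b = "M-KVC-LLYT", c = "MAKV-ALLFT",
            d = "M-KV-ALLVT")
  trh <- trim_alignment(hand, 0.5, 0.3)
  expect_identical(trh$kept, setdiff(1:10, c(2, 5, 9)))
  expect_error(trim_alignment(c(a = "-A", b = "A-"), 0, 0.6), "relax")
})

test_that("trimming is idempotent", {
  aln <- random_codon_aln(paste0("s", 1:6), 40, seed = 3)
  aln <- vapply(aln, function(s) translate_cds(substr(s, 1, 117)),
                character(1))
  tr <- trim_alignment(aln)
  tr2 <- trim_alignment(tr$alignment)
  expect_identical(tr2$alignment, tr$alignment)
  expect_identical(tr2$kept, seq_along(tr$kept))
})

test_that("protein_distance implements the Kimura correction", {
  ident <- c(a = "MKVLAWYTRE", b = "MKVLAWYTRE")
  expect_identical(protein_distance(ident)[1, 2], 0)
  ## p = 0.1 over 10 gap-free columns
  one_diff <- c(a = "MKVLAWYTRE", b = "MKVLAWYTRA")
  expect_equal(protein_distance(one_diff)[1, 2],
               -log(1 - 0.1 - 0.2 * 0.01), tolerance = 1e-12)
  ## symmetry on randomly perturbed sequences
  set.seed(4)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  base <- paste(sample(aas, 30, replace = TRUE), collapse = "")
  rnd <- vapply(stats::setNames(1:5, paste0("r", 1:5)), function(i) {
    x <- strsplit(base, "")[[1]]
    flip <- sample(30, 8)
    x[flip] <- sample(aas, 8, replace = TRUE)
    paste(x, collapse = "")
  }, character(1))
  D <- protein_distance(rnd)
  expect_identical(D, t(D))
  expect_true(all(diag(D) == 0))
  ## gapless overlap of zero is an error; saturation is capped
  expect_error(protein_distance(c(a = "MK--", b = "--VL")), "no gap-free")
  expect_warning(
    Ds <- protein_distance(c(a = "AAAAAAAAAA", b = "CDEFGHIKLM")),
    "saturated")
  expect_identical(Ds[1, 2], 5)
})

test_that("nj_tree solves the three-taxon case exactly", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  ## three-point solution: la = 1, lb = 2, lc = 3
  lens <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["a"]], 1)
  expect_equal(lens[["b"]], 2)
  expect_equal(lens[["c"]], 3)
  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3")
})

test_that("nj_tree recovers additive matrices exactly", {
  ## 4-taxon tree with known split and branch lengths
  ref4 <- ape::read.tree(text = "((a:1,b:2):1.5,(c:1,d:3):0.5);")
  dm4 <- ape::cophenetic.phylo(ref4)
  tr4 <- nj_tree(dm4)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr4),
                                         ape::unroot(ref4))), 0)
  ## 5-taxon: exact branch lengths
  ref5 <- ape::read.tree(
    text = "(((a:0.5,b:1):0.7,c:2):0.4,(d:0.9,e:1.1):0.6);")
  tr5 <- nj_tree(ape::cophenetic.phylo(ref5))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr5),
                                         ape::unroot(ref5))), 0)
  expect_equal(sort(tr5$edge.length), sort(ape::unroot(ref5)$edge.length),
               tolerance = 1e-8)
  ## property: random additive matrices up to 8 taxa
  for (s in 1:12) {
    set.seed(100 + s)
    n <- sample(4:8, 1)
    ref <- ape::rtree(n)
    ref$edge.length <- ref$edge.length + 0.1
    tr <- nj_tree(ape::cophenetic.phylo(ref))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                           ape::unroot(ref))), 0,
                 info = paste("seed", s))
  }
})

test_that("bootstrap support behaves on clean data and is deterministic", {
  ## strong signal: long internal branches, short terminal branches
  sig_tree <- ape::read.tree(text = paste0(
    "((a1:0.1,a2:0.1):0.8,((b1:0.1,b2:0.1):0.8,",
    "(c1:0.1,c2:0.1):0.8):0.8);"))
  attr(sig_tree, "edge_class") <- rep("background", nrow(sig_tree$edge))
  cds <- evolve_codon_sequences(sig_tree, 2, c(background = 1),
                                uniform_pi(), 200, seed = 13)
  aln <- vapply(cds, translate_cds, character(1))
  ## deep pairs can saturate the distance correction; that is expected
  bt <- suppressWarnings(bootstrap_support(aln, n_replicates = 100,
                                           seed = 1))
  sup <- suppressWarnings(as.numeric(bt$node.label))
  expect_true(all(sup[!is.na(sup)] >= 90))
  ## n_replicates = 1: supports are 0 or 100
  b1 <- suppressWarnings(bootstrap_support(aln, n_replicates = 1,
                                           seed = 3))
  s1 <- suppressWarnings(as.numeric(b1$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))
  expect_error(bootstrap_support(aln, 0), "n_replicates")
  ## determinism and row-order invariance
  b2 <- suppressWarnings(bootstrap_support(aln, n_replicates = 50,
                                           seed = 7))
  b3 <- suppressWarnings(bootstrap_support(aln, n_replicates = 50,
                                           seed = 7))
  expect_identical(ape::write.tree(b2), ape::write.tree(b3))
  perm <- aln[c(4, 2, 6, 1, 3, 5)]
  b4 <- suppressWarnings(bootstrap_support(perm, n_replicates = 50,
                                           seed = 7))
  key <- function(tr) {
    nt <- length(tr$tip.label)
    sup <- tr$node.label
    sapply(seq_len(tr$Nnode), function(i) {
      nds <- genefam:::clade_nodes(tr, nt + i)
      paste(paste(sort(tr$tip.label[nds[nds <= nt]]), collapse = ","),
            sup[i])
    })
  }
  expect_setequal(key(b4), key(b2))
})

test_that("root_by_outgroup places the root on the outgroup edge", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:4):1);")
  tr <- ape::unroot(tr)
  rooted <- root_by_outgroup(tr, "D")
  expect_true(ape::is.rooted(rooted))
  kids <- rooted$edge[rooted$edge[, 1] == length(rooted$tip.label) + 1L, 2]
  expect_true(match("D", rooted$tip.label) %in% kids)
  ## midpoint: the two root edges are equal halves
  root_edges <- which(rooted$edge[, 1] == length(rooted$tip.label) + 1L)
  expect_equal(rooted$edge.length[root_edges[1]],
               rooted$edge.length[root_edges[2]])
  expect_error(root_by_outgroup(tr, tr$tip.label), "every leaf")
  expect_error(root_by_outgroup(tr, c("A", "C")), "monophyletic")
  expect_error(root_by_outgroup(tr, "Z"), "not in tree")
})

test_that("outgroup rooting separates the clades in the big fixture", {
  sim <- make_fixture("brassicaceae_like", seed = 2)
  gt <- sim$gene_tree
  og <- gt$tip.label[genefam:::tip_species(gt$tip.label) == "Tarenaya_like"]
  expect_gt(length(og), 0)
  unrooted <- ape::unroot(gt)
  rooted <- root_by_outgroup(unrooted, og)
  ## the ingroup root must separate the FLC s.str. clade from the rest
  cls <- genefam:::edge_classes(gt)
  nt <- length(gt$tip.label)
  term <- vapply(seq_len(nt), function(v)
    cls[match(v, gt$edge[, 2])], character(1))
  flc_tips <- gt$tip.label[term == "FLC_sstr"]
  maf_tips <- gt$tip.label[term %in% c("MAF123", "MAF45")]
  expect_true(ape::is.monophyletic(rooted, flc_tips))
  mrca_flc <- ape::getMRCA(rooted, flc_tips)
  expect_false(any(match(maf_tips, rooted$tip.label) %in%
                     genefam:::clade_nodes(rooted, mrca_flc)))
})
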