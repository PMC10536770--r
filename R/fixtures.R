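## Canned species trees and fully simulated fixture bundles used by the
## test-suite and by `genefam simulate`.

#' Preset species trees
#'
#' \describe{
#'   \item{toy4}{four species, balanced, no polyploidy.}
#'   \item{core16}{sixteen species in four clades; one WGT branch.}
#'   \item{brassicaceae_like}{a synthetic 30-tip phylogeny shaped like the
#'     Brassicaceae: a Tarenaya-like outgroup, an Aethionema-like species
#'     branching before the core, three core lineages (10, 12 and 6
#'     species), a WGT on the Brassiceae-like stem and a WGT on a
#'     Camelina-like terminal branch.  Purely synthetic: topology and
#'     branch lengths are stylised, not measured.}
#' }
#'
#' @param preset preset name.
#' @return species tree (\code{phylo}, branch lengths in expected
#'   substitutions per codon) with node labels and polyploidy annotations.
#' @export
species_tree_preset <- function(preset) {
  presets <- c("toy4", "core16", "brassicaceae_like")
  if (!preset %in% presets) {
    stop("unknown preset '", preset, "'; available: ",
         paste(presets, collapse = ", "))
  }
  ladder <- function(tips, tip_len, int_len) {
    ## (((a,b),c),d)-style ladder clade, newick without trailing length
    s <- sprintf("%s:%.3f", tips[1], tip_len)
    for (i in seq_along(tips)[-1]) {
      s <- sprintf("(%s,%s:%.3f):%.3f", s, tips[i], tip_len, int_len)
    }
    sub(":[0-9.]+$", "", s)
  }
  tree <- switch(preset,
    toy4 = ape::read.tree(
      text = "((A:0.10,B:0.10):0.08,(C:0.10,D:0.10):0.08)root;"),
    core16 = {
      cl <- function(pfx) ladder(paste0(pfx, 1:4), 0.08, 0.025)
      txt <- sprintf(
        "((%sca:0.05,%scb:0.05)cab:0.06,(%scc:0.05,%scd:0.05)ccd:0.06)root;",
        cl("a"), cl("b"), cl("c"), cl("d"))
      t <- ape::read.tree(text = txt)
      annotate_polyploidy(t, "cd", "WGT", retention = 0.5)
    },
    brassicaceae_like = .brassicaceae_like_tree(ladder))
  ensure_node_labels(tree)
}

.brassicaceae_like_tree <- function(ladder) {
  l1 <- c("Nasturtium_like", "Cardamine_like", "Camelina_like",
          "Arabidopsis_like", "Capsella_like", "Lepidium_like",
          "Rorippa_like", "Barbarea_like", "Turritis_like", "Alliaria_like")
  brassiceae <- c("Brassica_like", "Sinapis_like", "Moricandia_like",
                  "Crambe_like")
  l2_other <- c("Eutrema_like", "Arabis_like", "Conringia_like",
                "Thlaspi_like", "Schrenkiella_like", "Isatis_like",
                "Myagrum_like", "Biscutella_like")
  l3 <- c("Euclidium_like", "Diptychocarpus_like", "Matthiola_like",
          "Chorispora_like", "Anastatica_like", "Hesperis_like")
  cl1 <- paste0(ladder(l1, 0.09, 0.022), "lineage1")
  cl_br <- paste0(ladder(brassiceae, 0.07, 0.020), "brassiceae")
  cl2o <- ladder(l2_other, 0.08, 0.020)
  cl2 <- sprintf("(%s:0.030,%s:0.035)lineage2", cl_br, cl2o)
  cl3 <- paste0(ladder(l3, 0.09, 0.022), "lineage3")
  txt <- sprintf(paste0(
    "(Tarenaya_like:0.45,(Aethionema_like:0.33,(%s:0.040,",
    "(%s:0.030,%s:0.040)core23:0.030)core:0.050)brassicaceae:0.120)root;"),
    cl1, cl2, cl3)
  t <- ape::read.tree(text = txt)
  t <- ensure_node_labels(t)
  t <- annotate_polyploidy(t, "brassiceae", "WGT", retention = 0.4)
  t <- annotate_polyploidy(t, "Camelina_like", "WGT", retention = 0.5)
  t
}

#' Default simulation configuration of a preset
#'
#' \code{toy4} and \code{core16} use the default [sim_config()] rates with
#' no forced events; \code{brassicaceae_like} starts from a single
#' ancestral FLC-like gene s.l., forces the FLC-s.str.-vs-MAF tandem
#' duplication onto the Brassicaceae stem (so the Tarenaya-like outgroup
#' genes stay outside both clades and can root the gene tree) and the
#' MAF1/2/3-vs-MAF4/5 tandem duplication onto the core stem (after the
#' Aethionema-like species branched off), gives FLC s.str. lineages
#' strongly reduced duplication/loss turnover, and uses rates calibrated
#' so that per-species MAF-like copy numbers span roughly one to nine.
#'
#' @param preset preset name.
#' @param ... overrides passed on to [sim_config()].
#' @return a [sim_config()].
#' @export
preset_config <- function(preset, ...) {
  dots <- list(...)
  if (preset %in% c("toy4", "core16")) return(do.call(sim_config, dots))
  if (preset != "brassicaceae_like") {
    stop("unknown preset '", preset, "'")
  }
  defaults <- list(
    rates = c(tandem = 0.7, triplication = 0.15, inverted = 0.15,
              segmental = 0.08, transposed = 0.15, loss = 0.6),
    root_genes = "FLCL",
    forced_events = list(
      ## the FLC-s.str.-vs-MAF split: a tandem duplication on the
      ## Brassicaceae stem, after the Tarenaya-like outgroup diverged
      list(branch = "brassicaceae", gene = "FLCL", time_frac = 0.4,
           type = "tandem_duplication",
           classes = c("FLC_sstr", "background")),
      ## the MAF1/2/3-vs-MAF4/5 split on the core stem, after the
      ## Aethionema-like species branched off; targets the MAF lineage
      ## (the only background-class lineage present on that branch)
      list(branch = "core", class = "background", time_frac = 0.5,
           type = "tandem_duplication",
           classes = c("MAF123", "MAF45"))),
    rate_scale_by_class = c(FLC_sstr = 0.15, background = 0.4))
  defaults[names(dots)] <- dots
  do.call(sim_config, defaults)
}

#' Build a complete simulated fixture
#'
#' Simulates a gene family under a preset and optionally writes the bundle
#' to a directory in the package's interchange formats: species tree and
#' true gene tree (newick, classes as \code{#class} suffixes), loci table
#' (TSV), CDS alignment (FASTA), event log (TSV) and a JSON snapshot of
#' the configuration.
#'
#' @param preset one of \code{toy4}, \code{core16},
#'   \code{brassicaceae_like}.
#' @param seed integer seed (byte-identical output for identical seeds).
#' @param dir output directory (created if needed); \code{NULL} = no files.
#' @param config optional [sim_config()] override.
#' @return the [simulate_gene_family()] bundle, invisibly when writing.
#' @export
make_fixture <- function(preset, seed, dir = NULL, config = NULL) {
  tree <- species_tree_preset(preset)
  if (is.null(config)) config <- preset_config(preset)
  sim <- simulate_gene_family(tree, config, seed = seed)
  sim$preset <- preset
  sim$seed <- seed
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_newick(sim$species_tree, file.path(dir, "species.nwk"))
    pp <- attr(sim$species_tree, "polyploidy")
    if (!is.null(pp) && nrow(pp)) {
      pp$branch <- vapply(pp$node, function(n)
        node_label(sim$species_tree, n), character(1))
      utils::write.table(pp[, c("branch", "type", "retention")],
                         file.path(dir, "polyploidy.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    if (!is.null(sim$gene_tree)) {
      write_classed_newick(sim$gene_tree,
                           file.path(dir, "gene_tree_true.nwk"))
      write_loci_table(sim$loci, file.path(dir, "loci.tsv"))
      write_fasta(sim$alignment, file.path(dir, "cds.fasta"))
    }
    utils::write.table(sim$events, file.path(dir, "events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cfg <- sim$config
    cfg$pi <- NULL  # bulky and derivable; keep the snapshot readable
    jsonlite::write_json(
      c(list(preset = preset, seed = seed), cfg),
      file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
    return(invisible(sim))
  }
  sim
}
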