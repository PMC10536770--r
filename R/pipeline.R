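## Pipeline orchestration: simulate -> (trim, tree, root) -> reconcile ->
## classify -> select -> report, with intermediate files as the sole
## inter-stage contract so real data can enter at any stage.

#' Transfer clade classes from a reference tree to another tree
#'
#' Takes the terminal-branch class of every tip in \code{ref} and labels
#' the corresponding crown clades of \code{tree} (the clade spanned by
#' each class's tips); branches outside those crowns stay background.
#'
#' @param tree rooted \code{phylo} whose tips are a subset of \code{ref}'s.
#' @param ref classed rooted \code{phylo}.
#' @return classed tree.
#' @export
transfer_tip_classes <- function(tree, ref) {
  cls <- edge_classes(ref)
  nt <- length(ref$tip.label)
  term <- vapply(seq_len(nt), function(v)
    cls[match(v, ref$edge[, 2])], character(1))
  for (cl in setdiff(unique(term), "background")) {
    tips <- intersect(ref$tip.label[term == cl], tree$tip.label)
    if (length(tips)) tree <- label_crown_clade(tree, tips, cl)
  }
  tree
}

.stage_msg <- function(quiet, ...) if (!quiet) message("[genefam] ", ...)

#' Run the full analysis pipeline
#'
#' Stages: \code{simulate} (preset fixtures), \code{tree} (translate,
#' trim, NJ with bootstrap, outgroup rooting), \code{reconcile},
#' \code{classify}, \code{select} (M0 + Mb fits and LRT), plus a run
#' manifest.  Every stage reads its inputs from and writes its outputs to
#' \code{out_dir}, so externally produced files in the same formats can
#' replace any stage.
#'
#' @param config list (or path to a JSON file) with entries:
#'   \describe{
#'     \item{preset / seed}{simulation preset and seed, or}
#'     \item{cds_fasta, species_newick, gene_tree_newick, loci_tsv}{paths
#'       to user inputs (gene_tree_newick optional: when absent the tree
#'       stage builds one),}
#'     \item{outgroup_species}{species whose genes root the gene tree,}
#'     \item{n_bootstrap}{bootstrap replicates (default 100),}
#'     \item{trim_max_gap, trim_min_identity}{trimming thresholds,}
#'     \item{tandem_max, segmental_min}{classification thresholds (bp),}
#'     \item{use_true_tree}{for preset runs: reconcile the simulator's
#'       true gene tree instead of the NJ estimate (default FALSE),}
#'     \item{starts}{initial omega values for model fitting,}
#'     \item{run_selection}{fit codon models (default TRUE; the fit cost
#'       grows quickly with the number of genes).}
#'   }
#' @param out_dir output directory.
#' @param stages character vector of stages to run, or \code{"all"}.
#' @param quiet suppress progress messages.
#' @return list with the stage results (invisible).
#' @export
run_pipeline <- function(config, out_dir, stages = "all", quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  all_stages <- c("simulate", "tree", "reconcile", "classify", "select")
  if (identical(stages, "all")) {
    stages <- if (is.null(config$preset)) all_stages[-1] else all_stages
  }
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!is.null(config$preset) && !is.null(config$cds_fasta)) {
    stop("supply either a preset or input paths, not both")
  }
  if (is.null(config$preset) && "simulate" %in% stages) {
    stop("stage 'simulate' needs a preset")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = config)
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t0) as.numeric(Sys.time() - t0, units = "secs")

  paths <- list(
    species = config$species_newick %||% file.path(out_dir, "species.nwk"),
    cds = config$cds_fasta %||% file.path(out_dir, "cds.fasta"),
    loci = config$loci_tsv %||% file.path(out_dir, "loci.tsv"),
    gene_tree = config$gene_tree_newick %||%
      file.path(out_dir, "gene_tree.nwk"),
    true_tree = file.path(out_dir, "gene_tree_true.nwk")
  )

  if ("simulate" %in% stages) {
    t0 <- tic()
    .stage_msg(quiet, "simulate: preset ", config$preset, ", seed ",
               config$seed)
    if (is.null(config$seed)) stop("simulation requires a seed")
    sim_cfg <- if (is.null(config$rates)) NULL else
      preset_config(config$preset, rates = unlist(config$rates))
    sim <- make_fixture(config$preset, config$seed, dir = out_dir,
                        config = sim_cfg)
    if (sim$extinct) stop("gene family went extinct under this seed; ",
                          "pick another seed")
    res$sim <- sim
    timings["simulate"] <- toc(t0)
  }

  if ("tree" %in% stages) {
    t0 <- tic()
    cds <- read_fasta(paths$cds)
    prot <- vapply(cds, translate_cds, character(1))
    tr <- trim_alignment(prot,
                         config$trim_max_gap %||% 0.5,
                         config$trim_min_identity %||% 0.1)
    utils::write.table(
      data.frame(column = seq_along(strsplit(prot[[1]], "")[[1]]),
                 kept = seq_along(strsplit(prot[[1]], "")[[1]]) %in%
                   tr$kept),
      file.path(out_dir, "trimming.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    .stage_msg(quiet, "tree: NJ + ", config$n_bootstrap %||% 100,
               " bootstrap replicates on ", length(prot), " sequences")
    boot <- bootstrap_support(tr$alignment, config$n_bootstrap %||% 100,
                              seed = config$seed %||% 1)
    og_sp <- config$outgroup_species %||%
      if (identical(config$preset, "brassicaceae_like")) "Tarenaya_like"
      else NULL
    if (!is.null(og_sp)) {
      og <- boot$tip.label[tip_species(boot$tip.label) %in% og_sp]
      if (length(og) == 0) stop("no genes from outgroup species ",
                                paste(og_sp, collapse = ","),
                                " in the tree")
      rooted <- root_by_outgroup(boot, og)
    } else {
      .stage_msg(quiet, "tree: no outgroup configured, midpoint rooting")
      rooted <- phangorn::midpoint(boot)
    }
    ape::write.tree(rooted, file.path(out_dir, "gene_tree.nwk"))
    paths$gene_tree <- file.path(out_dir, "gene_tree.nwk")
    res$gene_tree <- rooted
    timings["tree"] <- toc(t0)
  }

  get_gene_tree <- function() {
    if (isTRUE(config$use_true_tree)) {
      read_classed_newick(paths$true_tree)
    } else {
      read_classed_newick(paths$gene_tree)
    }
  }

  if ("reconcile" %in% stages) {
    t0 <- tic()
    gt <- get_gene_tree()
    sp <- read_newick(paths$species)
    pp_path <- file.path(out_dir, "polyploidy.tsv")
    if (file.exists(pp_path)) {
      pp <- utils::read.delim(pp_path)
      for (i in seq_len(nrow(pp))) {
        sp <- annotate_polyploidy(ensure_node_labels(sp), pp$branch[i],
                                  pp$type[i], pp$retention[i])
      }
    }
    .stage_msg(quiet, "reconcile: ", length(gt$tip.label), " genes into ",
               length(sp$tip.label), " species")
    rec <- reconcile(gt, sp)
    utils::write.table(
      data.frame(node = rec$duplications,
                 branch = rec$duplication_branches),
      file.path(out_dir, "duplications.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(rec$losses, file.path(out_dir, "losses.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(node = names(rec$ancestral_counts),
                 copies = as.integer(rec$ancestral_counts)),
      file.path(out_dir, "ancestral_counts.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    res$reconciliation <- rec
    timings["reconcile"] <- toc(t0)
  }

  if ("classify" %in% stages) {
    t0 <- tic()
    if (is.null(res$reconciliation)) {
      stop("stage 'classify' needs the reconcile stage results")
    }
    loci <- read_loci_table(paths$loci)
    th <- classify_thresholds(config$tandem_max %||% 100000,
                              config$segmental_min %||% 500000)
    .stage_msg(quiet, "classify: ",
               length(res$reconciliation$duplications), " duplications")
    calls <- classify_events(res$reconciliation, loci, th)
    utils::write.table(calls, file.path(out_dir, "event_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summ <- summarize_events(calls, res$reconciliation$losses,
                             res$reconciliation$gene_tree,
                             res$reconciliation$species_tree)
    utils::write.table(summ$per_branch,
                       file.path(out_dir, "events_per_branch.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summ$copy_number,
                       file.path(out_dir, "copy_number.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$calls <- calls
    res$summary <- summ
    timings["classify"] <- toc(t0)
  }

  if ("select" %in% stages && !isFALSE(config$run_selection)) {
    t0 <- tic()
    cds <- read_fasta(paths$cds)
    gt <- if (file.exists(paths$true_tree)) {
      read_classed_newick(paths$true_tree)
    } else {
      get_gene_tree()
    }
    .stage_msg(quiet, "select: fitting M0 and Mb on ",
               length(gt$tip.label), " sequences")
    starts <- config$starts %||% c(0.5, 1, 2)
    fit0 <- fit_model(cds, gt, "M0", starts = starts)
    if (length(unique(edge_classes(gt))) > 1L) {
      fitb <- fit_model(cds, gt, "Mb", starts = starts)
      test <- lrt(fit0, fitb)
    } else {
      .stage_msg(quiet, "select: single branch class, M0 only")
      fitb <- NULL
      test <- NULL
    }
    tab <- selection_table(fit0, fitb, test)
    utils::write.table(tab, file.path(out_dir, "selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$selection <- list(M0 = fit0, Mb = fitb, lrt = test, table = tab)
    timings["select"] <- toc(t0)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("genefam")),
    r_version = R.version.string,
    stages = stages,
    seed = config$seed,
    timings_sec = as.list(round(timings, 3)),
    config = config[setdiff(names(config), "pi")]
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(res)
}

#' Selection results in the canonical table layout
#'
#' One row per model with columns model, lnL, np, omega0 (background),
#' omega1 (MAF4/5), omega2 (MAF1/2/3), omega3 (FLC s.str.), kappa, and the
#' LRT columns (2dlnL, dnp, p) on the null-model row.
#'
#' @param fit0,fitb fits from [fit_model()] (M0 and Mb).
#' @param test [lrt()] result (optional).
#' @return data frame.
#' @export
selection_table <- function(fit0, fitb = NULL, test = NULL) {
  omega_cols <- function(fit) {
    om <- fit$params$omega_by_class
    if (fit$model == "M0") {
      c(omega0 = unname(om[1]), omega1 = NA, omega2 = NA, omega3 = NA)
    } else {
      c(omega0 = unname(om["background"]),
        omega1 = unname(om["MAF45"]),
        omega2 = unname(om["MAF123"]),
        omega3 = unname(om["FLC_sstr"]))
    }
  }
  row <- function(fit) {
    data.frame(model = fit$model, lnL = fit$lnL, np = fit$np,
               t(omega_cols(fit)), kappa = fit$params$kappa,
               X2dlnL = NA_real_, dnp = NA_integer_, p = NA_real_)
  }
  tab <- row(fit0)
  if (!is.null(fitb)) tab <- rbind(tab, row(fitb))
  if (!is.null(test)) {
    tab$X2dlnL[1] <- test$stat
    tab$dnp[1] <- test$df
    tab$p[1] <- test$p
  }
  names(tab)[names(tab) == "X2dlnL"] <- "2dlnL"
  tab
}

#' Render the pipeline's headline tables
#'
#' @param results list returned by [run_pipeline()].
#' @return character vector of formatted lines (also printed).
#' @export
report_tables <- function(results) {
  lines <- character()
  if (!is.null(results$selection)) {
    lines <- c(lines, "Selection models (Table-1 layout):",
               utils::capture.output(print(results$selection$table,
                                           row.names = FALSE)))
  }
  if (!is.null(results$summary)) {
    lines <- c(lines, "", "Copy numbers per species and clade:",
               utils::capture.output(print(results$summary$copy_number,
                                           row.names = FALSE)))
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
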