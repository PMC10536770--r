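## Readers/writers for the standard formats the pipeline touches (FASTA,
## newick, TSV locus tables, GFF3 export) plus sequence-level utilities.
## Internal coordinates are 0-based half-open; on-disk tables are 1-based
## inclusive (GFF convention).

#' Read / write FASTA
#'
#' Thin wrappers around Biostrings with the validation this pipeline
#' relies on: ids must be unique and sequences non-empty.
#'
#' @param path file path.
#' @return \code{read_fasta}: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  if (any(Biostrings::width(set) == 0L)) {
    stop("empty sequence record(s): ",
         paste(ids[Biostrings::width(set) == 0L], collapse = ", "))
  }
  stats::setNames(as.character(set), ids)
}

#' @rdname read_fasta
#' @param records named character vector of sequences.
#' @param line_width characters per sequence line (default 60).
#' @export
write_fasta <- function(records, path, line_width = 60) {
  if (length(records) == 0L) stop("no records to write")
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    stop("all records must be named")
  }
  dup <- names(records)[duplicated(names(records))]
  if (length(dup)) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(!nzchar(records))) {
    stop("empty sequence record(s): ",
         paste(names(records)[!nzchar(records)], collapse = ", "))
  }
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, filepath = path, width = line_width)
  invisible(path)
}

#' Conceptually translate a coding sequence
#'
#' Standard genetic code.  A single terminal stop codon is stripped
#' silently; an internal stop is an error (pseudogene calling is out of
#' scope here).
#'
#' @param cds nucleotide string over A/C/G/T, length a multiple of 3.
#' @return protein string, one amino acid per codon.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n == 0L) stop("empty coding sequence")
  if (n %% 3L != 0L) {
    stop("coding sequence length ", n, " is not a multiple of 3")
  }
  starts <- seq.int(1L, n, by = 3L)
  cods <- substring(cds, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[cods])
  if (anyNA(aa)) {
    bad <- which(is.na(aa))[1]
    stop("unrecognised codon '", cods[bad], "' at codon ", bad)
  }
  ncod <- length(aa)
  if (aa[ncod] == "*") {
    aa <- aa[-ncod]
    cods <- cods[-ncod]
  }
  if (any(aa == "*")) {
    stop("internal stop codon at codon ", which(aa == "*")[1])
  }
  paste(aa, collapse = "")
}

## ---- gene loci --------------------------------------------------------

#' Construct a gene locus
#'
#' Coordinates are 0-based half-open internally.  Exons are CDS segments
#' given as a two-column matrix (start, end), non-overlapping, sorted and
#' contained in \code{[start, end)}.
#'
#' @param gene_id unique identifier.
#' @param species species name.
#' @param scaffold scaffold / chromosome name.
#' @param start,end locus span (integers, \code{start < end}).
#' @param strand \code{"+"} or \code{"-"}.
#' @param exons two-column integer matrix of CDS segments, or \code{NULL}.
#' @param cds coding sequence (A/C/G/T, length a positive multiple of 3),
#'   or \code{NA}.
#' @return object of class \code{gene_locus} (a named list).
#' @export
gene_locus <- function(gene_id, species, scaffold, start, end, strand,
                       exons = NULL, cds = NA_character_) {
  if (!is.character(gene_id) || !nzchar(gene_id)) stop("invalid gene_id")
  if (start >= end) {
    stop("locus ", gene_id, ": start (", start, ") must be < end (", end, ")")
  }
  if (!strand %in% c("+", "-")) {
    stop("locus ", gene_id, ": strand must be '+' or '-', got '", strand, "'")
  }
  if (!is.null(exons)) {
    exons <- matrix(as.integer(exons), ncol = 2,
                    dimnames = list(NULL, c("start", "end")))
    if (nrow(exons) == 0L) stop("locus ", gene_id, ": empty exon list")
    if (any(exons[, 1] >= exons[, 2])) {
      stop("locus ", gene_id, ": exon with start >= end")
    }
    if (is.unsorted(exons[, 1], strictly = TRUE) ||
        any(exons[-1, 1] < exons[-nrow(exons), 2])) {
      stop("locus ", gene_id, ": exons must be sorted and non-overlapping")
    }
    if (exons[1, 1] < start || exons[nrow(exons), 2] > end) {
      stop("locus ", gene_id, ": exons outside the locus span")
    }
  }
  if (!is.na(cds)) {
    nc <- nchar(cds)
    if (nc == 0L || nc %% 3L != 0L) {
      stop("locus ", gene_id, ": cds length ", nc,
           " is not a positive multiple of 3")
    }
    if (!is.null(exons) && sum(exons[, 2] - exons[, 1]) != nc) {
      stop("locus ", gene_id, ": cds length ", nc,
           " != total exon length ", sum(exons[, 2] - exons[, 1]))
    }
  }
  structure(list(gene_id = gene_id, species = species, scaffold = scaffold,
                 start = as.integer(start), end = as.integer(end),
                 strand = strand, exons = exons, cds = cds),
            class = "gene_locus")
}

#' Number of coding exons of a locus
#' @param locus a [gene_locus()].
#' @return integer exon count.
#' @export
exon_count <- function(locus) {
  if (!inherits(locus, "gene_locus")) stop("not a gene_locus")
  if (is.null(locus$exons) || nrow(locus$exons) == 0L) {
    stop("locus ", locus$gene_id, " has no exon list")
  }
  nrow(locus$exons)
}

## Assemble a list of gene_locus objects into the internal loci table:
## a data.frame with one row per locus and a list-column of exon matrices.
loci_to_table <- function(loci) {
  stopifnot(all(vapply(loci, inherits, logical(1), "gene_locus")))
  ids <- vapply(loci, `[[`, character(1), "gene_id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate gene_id(s): ", paste(dup, collapse = ", "))
  df <- data.frame(
    gene_id = ids,
    species = vapply(loci, `[[`, character(1), "species"),
    scaffold = vapply(loci, `[[`, character(1), "scaffold"),
    start = vapply(loci, `[[`, integer(1), "start"),
    end = vapply(loci, `[[`, integer(1), "end"),
    strand = vapply(loci, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE
  )
  df$exons <- lapply(loci, `[[`, "exons")
  df$cds <- vapply(loci, `[[`, character(1), "cds")
  class(df) <- c("loci_table", "data.frame")
  df
}

table_to_loci <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    gene_locus(df$gene_id[i], df$species[i], df$scaffold[i], df$start[i],
               df$end[i], df$strand[i], df$exons[[i]], df$cds[i])
  })
}

.exons_to_disk <- function(ex) {
  if (is.null(ex)) return("")
  paste(sprintf("%d-%d", ex[, 1] + 1L, ex[, 2]), collapse = ";")
}

.exons_from_disk <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  parts <- strsplit(strsplit(s, ";")[[1]], "-")
  m <- do.call(rbind, lapply(parts, as.integer))
  cbind(start = m[, 1] - 1L, end = m[, 2])
}

#' Read / write the tabular locus format
#'
#' The on-disk format is a TSV with header \code{gene_id, species,
#' scaffold, start, end, strand, exons}; coordinates are 1-based inclusive
#' and exons are semicolon-joined \code{start-end} pairs.  Internally all
#' coordinates are 0-based half-open.
#'
#' @param path file path.
#' @return \code{read_loci_table}: a \code{loci_table} data.frame (internal
#'   coordinates, exon list-column).
#' @export
read_loci_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("gene_id", "species", "scaffold", "start", "end", "strand",
            "exons")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("loci table lacks column(s): ", paste(miss, collapse = ", "))
  }
  loci <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    line <- i + 1L  # header is line 1
    start1 <- suppressWarnings(as.integer(raw$start[i]))
    end1 <- suppressWarnings(as.integer(raw$end[i]))
    if (is.na(start1) || is.na(end1)) {
      stop("line ", line, ": non-numeric coordinates")
    }
    if (start1 > end1) {
      stop("line ", line, ": start (", start1, ") > end (", end1, ")")
    }
    if (!raw$strand[i] %in% c("+", "-")) {
      stop("line ", line, ": malformed strand '", raw$strand[i], "'")
    }
    loci[[i]] <- gene_locus(
      raw$gene_id[i], raw$species[i], raw$scaffold[i],
      start = start1 - 1L, end = end1, strand = raw$strand[i],
      exons = .exons_from_disk(raw$exons[i]),
      cds = if ("cds" %in% names(raw) && nzchar(raw$cds[i])) raw$cds[i]
            else NA_character_)
  }
  loci_to_table(loci)
}

#' @rdname read_loci_table
#' @param loci a \code{loci_table} data.frame or list of [gene_locus()].
#' @export
write_loci_table <- function(loci, path) {
  if (is.data.frame(loci)) loci <- table_to_loci(loci)
  df <- data.frame(
    gene_id = vapply(loci, `[[`, character(1), "gene_id"),
    species = vapply(loci, `[[`, character(1), "species"),
    scaffold = vapply(loci, `[[`, character(1), "scaffold"),
    start = vapply(loci, `[[`, integer(1), "start") + 1L,
    end = vapply(loci, `[[`, integer(1), "end"),
    strand = vapply(loci, `[[`, character(1), "strand"),
    exons = vapply(loci, function(l) .exons_to_disk(l$exons), character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export loci as GFF3 (gene + CDS features)
#' @param loci \code{loci_table} or list of [gene_locus()].
#' @param path file path.
#' @export
write_gff3 <- function(loci, path) {
  if (is.data.frame(loci)) loci <- table_to_loci(loci)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (l in loci) {
    writeLines(sprintf("%s\tgenefam\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       l$scaffold, l$start + 1L, l$end, l$strand, l$gene_id),
               con)
    if (!is.null(l$exons)) {
      for (k in seq_len(nrow(l$exons))) {
        writeLines(sprintf(
          "%s\tgenefam\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
          l$scaffold, l$exons[k, 1] + 1L, l$exons[k, 2], l$strand,
          l$gene_id, k, l$gene_id), con)
      }
    }
  }
  invisible(path)
}

## ---- newick -----------------------------------------------------------

#' Read / write newick trees
#'
#' ape-backed with extra validation: unbalanced parentheses are reported
#' with their character position and duplicate leaf labels are an error.
#'
#' @param path file path.
#' @return \code{read_newick}: a \code{phylo}.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  .check_parens(txt)
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("newick parse error in ", path)
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup)) {
    stop("duplicate leaf label(s): ", paste(unique(dup), collapse = ", "))
  }
  tree
}

.check_parens <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop("newick parse error: unmatched ')' at position ", i)
  }
  if (depth != 0L) {
    stop("newick parse error: ", depth, " unclosed '(' at end of input")
  }
  invisible(TRUE)
}

#' @rdname read_newick
#' @param tree a \code{phylo}.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
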