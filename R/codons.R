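## Genetic-code tables shared by the codon model and the simulator.
## Universal (standard) code only; 61 sense codons, stops excluded.

NUCS <- c("A", "C", "G", "T")
PURINES <- c("A", "G")

.codon_universe <- function() {
  cods <- as.vector(t(outer(
    as.vector(t(outer(NUCS, NUCS, paste0))), NUCS, paste0)))
  sort(cods)
}

CODONS64 <- .codon_universe()
STOP_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"]
CODONS61 <- setdiff(CODONS64, STOP_CODONS)
CODON_AA <- unname(Biostrings::GENETIC_CODE[CODONS61])

## nucleotide composition of each sense codon, split by position
.codon_nuc <- function(pos) substr(CODONS61, pos, pos)

## Pairwise structure of single-nucleotide codon changes, precomputed once:
## for each ordered pair (i, j) of sense codons differing at exactly one
## position, whether the change is a transition and whether it is synonymous.
.codon_pairs <- local({
  n <- length(CODONS61)
  m1 <- .codon_nuc(1)
  m2 <- .codon_nuc(2)
  m3 <- .codon_nuc(3)
  d1 <- outer(m1, m1, "!=")
  d2 <- outer(m2, m2, "!=")
  d3 <- outer(m3, m3, "!=")
  ndiff <- d1 + d2 + d3
  single <- ndiff == 1L
  is_transition <- function(a, b) {
    (a %in% PURINES) == (b %in% PURINES)
  }
  ti <- matrix(FALSE, n, n)
  idx <- which(single, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    pos <- which(c(d1[i, j], d2[i, j], d3[i, j]))
    a <- substr(CODONS61[i], pos, pos)
    b <- substr(CODONS61[j], pos, pos)
    ti[i, j] <- is_transition(a, b)
  }
  syn <- outer(CODON_AA, CODON_AA, "==") & single
  list(single = single, transition = ti, synonymous = syn)
})

#' Index codons of a nucleotide string
#'
#' Splits an in-frame nucleotide string into codons and maps each to its
#' index among the 61 sense codons. Codons containing characters outside
#' A/C/G/T, gap codons (\code{---}) and stop codons yield \code{NA}.
#'
#' @param seq nucleotide string, length a multiple of 3.
#' @return integer vector of codon indices (1..61) with \code{NA} for
#'   missing/ambiguous/stop codons.
#' @keywords internal
codon_indices <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    stop("sequence length ", n, " is not a multiple of 3")
  }
  starts <- seq.int(1L, n, by = 3L)
  cods <- substring(seq, starts, starts + 2L)
  match(cods, CODONS61)
}

codons_of <- function(idx) CODONS61[idx]
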