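#' Generate a random reference genome
#'
#' Draws one or more contigs of i.i.d. bases at a target GC content. The
#' result is a small stand-in for a real fungal assembly so that every
#' downstream stage (mapping, pileup, screening) can be exercised with full
#' ground truth.
#'
#' @param n_contigs number of contigs.
#' @param lengths integer vector of contig lengths in bases (recycled to
#'   `n_contigs` if length 1).
#' @param gc target GC fraction, strictly between 0 and 1.
#' @param seed optional integer; when given, `set.seed(seed)` is called so the
#'   genome is reproducible.
#' @return a named character vector of contig sequences (names
#'   `contig_1`, `contig_2`, ...) of class `ref_genome`.
#' @examples
#' g <- generate_genome(2, c(5000, 3000), gc = 0.5, seed = 1)
#' genome_length(g)
#' @export
generate_genome <- function(n_contigs, lengths, gc = 0.5, seed = NULL) {
  if (length(lengths) == 1L) lengths <- rep(lengths, n_contigs)
  if (length(lengths) != n_contigs)
    ps_input_error("lengths must have length 1 or n_contigs")
  lengths <- as.integer(lengths)
  if (any(is.na(lengths)) || any(lengths <= 0L))
    ps_input_error("contig lengths must be positive")
  if (!is.numeric(gc) || gc <= 0 || gc >= 1)
    ps_input_error("gc must be strictly between 0 and 1")
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  contigs <- vapply(lengths, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
  names(contigs) <- paste0("contig_", seq_len(n_contigs))
  class(contigs) <- "ref_genome"
  contigs
}

#' Total genome length in bases
#' @param genome a named character vector of contig sequences.
#' @export
genome_length <- function(genome) sum(nchar(genome))

#' @export
print.ref_genome <- function(x, ...) {
  cat(sprintf("reference genome: %d contig(s), %s bases\n",
              length(x), format(genome_length(x), big.mark = ",")))
  for (nm in names(x))
    cat(sprintf("  %s  %s b\n", nm, format(nchar(x[[nm]]), big.mark = ",")))
  invisible(x)
}

validate_genome <- function(genome, allow_n = TRUE) {
  if (length(genome) == 0L || genome_length(genome) == 0L)
    ps_input_error("empty reference")
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    ps_input_error("contig names must be present and unique")
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  if (any(grepl(pat, genome)))
    ps_input_error("genome contains characters outside the %s alphabet",
                   if (allow_n) "A/C/G/T/N" else "A/C/G/T")
  invisible(genome)
}

#' Read a reference genome from FASTA
#' @param path FASTA file.
#' @return named character vector of class `ref_genome` (uppercased; names
#'   truncated at the first whitespace).
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  g <- toupper(as.character(ss))
  names(g) <- sub("\\s.*$", "", names(g))
  class(g) <- "ref_genome"
  g
}

#' Write a genome to FASTA
#' @param genome named character vector of contigs.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# fast substring of a contig, 0-based half-open
sub0 <- function(seq, start, end) substr(seq, start + 1L, end)

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
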