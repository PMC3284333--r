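# Independent oracles used to validate the pipeline's optimized paths.
# These deliberately reimplement the quantities being tested with the most
# direct (brute-force) method available, sharing no code with the package
# internals they check.

# Brute-force pileup: tally read bases position-by-position by direct string
# comparison of every (ungapped) alignment against the reference.
oracle_pileup_counts <- function(alignments, genome) {
  counts <- lapply(genome, function(s)
    matrix(0L, 5, nchar(s), dimnames = list(c("A", "C", "G", "T", "N"), NULL)))
  for (i in seq_len(nrow(alignments))) {
    cc <- alignments$contig[i]
    p0 <- alignments$pos[i]
    chars <- strsplit(alignments$seq[i], "")[[1]]
    for (j in seq_along(chars)) {
      b <- chars[j]
      if (!b %in% c("A", "C", "G", "T")) b <- "N"
      counts[[cc]][b, p0 + j] <- counts[[cc]][b, p0 + j] + 1L
    }
  }
  counts
}

# Brute-force in-frame stop scan: extension length of a stop-loss allele by
# walking codons of the downstream genomic sequence.
oracle_stop_scan <- function(genome, contig, strand, cds_end_fwd, cds_start_fwd) {
  seq <- genome[[contig]]
  down <- if (strand == "+") {
    substr(seq, cds_end_fwd + 1L, nchar(seq))
  } else {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(substr(seq, 1L, cds_start_fwd), "")[[1]]),
                 collapse = ""))
  }
  i <- 1L
  n <- 0L
  while (i + 2L <= nchar(down)) {
    codon <- substr(down, i, i + 2L)
    if (codon %in% c("TAA", "TAG", "TGA")) return(n + 1L)  # + mutated codon
    n <- n + 1L
    i <- i + 3L
  }
  NA_integer_
}

# Count mismatches of an alignment by direct character comparison.
oracle_mismatches <- function(alignment_seq, genome, contig, pos) {
  a <- strsplit(alignment_seq, "")[[1]]
  b <- strsplit(substr(genome[[contig]], pos + 1L, pos + length(a)), "")[[1]]
  sum(a != b)
}

# small deterministic scenario used by several suites
small_scenario <- function(seed, genome_length = 2e5, n_background = 8) {
  set.seed(seed)
  study_scenario(genome_length = genome_length, n_background = n_background)
}

pattern_candidates_of <- function(screen) {
  screen[screen$classification == "pattern_candidate", , drop = FALSE]
}
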