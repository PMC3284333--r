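#' Map reads to a reference with the internal unique-best mapper
#'
#' A minimal seed-and-extend, ungapped mapper for desk-scale analyses: a
#' read is placed iff it has a unique best placement with at most
#' `max_mismatches` mismatches, found from exact `seed_len`-mer seed matches
#' at staggered offsets. Ambiguous reads (two or more placements tied at the
#' best mismatch count, e.g. from exactly duplicated sequence) and
#' unplaceable reads are left unmapped. Real-data users should map
#' externally and use [import_sam()] instead; this mapper exists so the whole
#' pipeline runs self-contained on simulated data.
#'
#' @param reads a `ps_reads` set, or the result of [simulate_reads()] /
#'   [clean_reads()] (mates and singles are all mapped; mate links retained).
#' @param genome reference genome (named character vector).
#' @param seed_len seed k-mer length (default 20).
#' @param max_mismatches maximum mismatches for a valid placement (default 3).
#' @param sample_id sample label stored in the alignment records.
#' @return data.frame of alignment records (one row per mapped read):
#'   `read_id`, `sample_id`, `contig`, `pos` (0-based leftmost), `strand`,
#'   `length`, `nm`, `seq` (reference-oriented), `cigar` (`NA` = ungapped
#'   full-length match), `mate_contig`, `mate_pos`, `insert` (outer
#'   distance; `NA` unless both mates mapped to the same contig).
#'   Attribute `counts`: input/mapped/ambiguous/unmapped totals.
#' @export
map_reads <- function(reads, genome, seed_len = 20L, max_mismatches = 3L,
                      sample_id = "sample") {
  validate_genome(genome)
  sets <- read_batches(reads)
  seqs <- unlist(lapply(sets, function(s) s$reads$seq), use.names = FALSE)
  ids <- unlist(lapply(sets, function(s) s$reads$id), use.names = FALSE)
  batch <- rep(vapply(sets, `[[`, character(1), "role"),
               vapply(sets, function(s) n_reads(s$reads), integer(1)))
  if (length(seqs) == 0L)
    return(empty_alignments(sample_id, n_input = 0L))
  hit <- .ps_map_reads(unclass(genome), seqs, as.integer(seed_len),
                       as.integer(max_mismatches), 256L)
  mapped <- hit$status == 1L
  nmap <- sum(mapped)
  aln <- list(
    read_id = ids[mapped],
    sample_id = rep(sample_id, nmap),
    contig = names(genome)[hit$contig[mapped]],
    pos = hit$pos[mapped],
    strand = c("+", "-")[hit$minus[mapped] + 1L],
    length = nchar(seqs[mapped]),
    nm = hit$nm[mapped],
    seq = hit$seq[mapped],
    cigar = rep(NA_character_, nmap),
    role = batch[mapped])
  attr(aln, "row.names") <- .set_row_names(nmap)
  class(aln) <- "data.frame"
  aln <- pair_alignments(aln)
  attr(aln, "counts") <- c(n_input = length(seqs),
                           n_mapped = sum(mapped),
                           n_ambiguous = sum(hit$status == 2L),
                           n_unmapped = sum(hit$status == 0L))
  aln
}

read_batches <- function(reads) {
  if (inherits(reads, "ps_reads")) {
    return(list(list(role = "single", reads = reads)))
  }
  if (inherits(reads, "ps_readsim") || inherits(reads, "ps_cleaned") || is.list(reads)) {
    out <- list()
    if (!is.null(reads$mate1)) out <- c(out, list(list(role = "mate1", reads = reads$mate1)))
    if (!is.null(reads$mate2)) out <- c(out, list(list(role = "mate2", reads = reads$mate2)))
    if (!is.null(reads$singles)) out <- c(out, list(list(role = "single", reads = reads$singles)))
    if (length(out) > 0L) return(out)
  }
  ps_input_error("unsupported reads object")
}

empty_alignments <- function(sample_id, n_input = 0L) {
  aln <- data.frame(read_id = character(0), sample_id = character(0),
                    contig = character(0), pos = integer(0),
                    strand = character(0), length = integer(0),
                    nm = integer(0), seq = character(0),
                    cigar = character(0), role = character(0),
                    mate_contig = character(0), mate_pos = integer(0),
                    mate_strand = character(0),
                    insert = integer(0), stringsAsFactors = FALSE)
  attr(aln, "counts") <- c(n_input = n_input, n_mapped = 0L,
                           n_ambiguous = 0L, n_unmapped = n_input)
  aln
}

# Fill mate_contig/mate_pos/insert by joining mate1 and mate2 rows on read id.
# Insert is the outer distance: rightmost end minus leftmost start, defined
# only when both mates mapped to the same contig.
pair_alignments <- function(aln) {
  aln$mate_contig <- rep(NA_character_, nrow(aln))
  aln$mate_pos <- rep(NA_integer_, nrow(aln))
  aln$mate_strand <- rep(NA_character_, nrow(aln))
  aln$insert <- rep(NA_integer_, nrow(aln))
  i1 <- which(aln$role == "mate1")
  i2 <- which(aln$role == "mate2")
  if (length(i1) > 0L && length(i2) > 0L) {
    m <- match(aln$read_id[i1], aln$read_id[i2])
    ok <- !is.na(m)
    a <- i1[ok]; b <- i2[m[ok]]
    aln$mate_contig[a] <- aln$contig[b]; aln$mate_contig[b] <- aln$contig[a]
    aln$mate_pos[a] <- aln$pos[b]; aln$mate_pos[b] <- aln$pos[a]
    aln$mate_strand[a] <- aln$strand[b]; aln$mate_strand[b] <- aln$strand[a]
    same <- aln$contig[a] == aln$contig[b]
    ins <- pmax(aln$pos[a] + aln$length[a], aln$pos[b] + aln$length[b]) -
      pmin(aln$pos[a], aln$pos[b])
    aln$insert[a[same]] <- ins[same]
    aln$insert[b[same]] <- ins[same]
  }
  aln
}

#' Import alignments from a SAM file
#'
#' Reads the 11 mandatory columns of a SAM file produced by an external
#' mapper (e.g. BWA). Only primary, mapped records are converted; SAM's
#' 1-based `POS` becomes the 0-based `pos` used throughout. Gapped
#' alignments keep their CIGAR so pileup construction records insertion and
#' deletion evidence.
#'
#' @param path SAM file.
#' @param sample_id sample label for the records.
#' @return alignment data.frame as in [map_reads()].
#' @export
import_sam <- function(path, sample_id = "sample") {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@"))
  out <- vector("list", length(body))
  for (j in seq_along(body)) {
    ln <- body[j]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L)
      ps_format_error("SAM line %d: %d fields (11 required)", ln, length(f))
    flag <- suppressWarnings(as.integer(f[2]))
    if (is.na(flag)) ps_format_error("SAM line %d: non-numeric FLAG", ln)
    if (bitwAnd(flag, 4L) > 0L) next                       # unmapped
    if (bitwAnd(flag, 256L) > 0L || bitwAnd(flag, 2048L) > 0L) next  # secondary/suppl.
    pos1 <- suppressWarnings(as.integer(f[4]))
    if (is.na(pos1) || pos1 < 1L) ps_format_error("SAM line %d: bad POS", ln)
    nm <- NA_integer_
    if (length(f) > 11L) {
      tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
      if (length(tag) > 0L) nm <- as.integer(sub("^NM:i:", "", tag[1]))
    }
    cigar <- f[6]
    rlen <- cigar_ref_span(cigar, nchar(f[10]))
    tlen <- suppressWarnings(as.integer(f[9]))
    paired <- bitwAnd(flag, 1L) > 0L
    mate_mapped <- paired && bitwAnd(flag, 8L) == 0L
    mate_contig <- if (mate_mapped) {
      if (f[7] == "=") f[3] else f[7]
    } else NA_character_
    role <- if (!paired) "single" else if (bitwAnd(flag, 64L) > 0L) "mate1" else "mate2"
    out[[j]] <- data.frame(
      read_id = f[1], sample_id = sample_id, contig = f[3], pos = pos1 - 1L,
      strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+",
      length = rlen, nm = nm, seq = f[10],
      cigar = if (cigar == "*") NA_character_ else cigar,
      role = role,
      mate_contig = mate_contig,
      mate_pos = if (mate_mapped) suppressWarnings(as.integer(f[8])) - 1L else NA_integer_,
      mate_strand = if (mate_mapped) {
        if (bitwAnd(flag, 32L) > 0L) "-" else "+"
      } else NA_character_,
      insert = if (mate_mapped && !is.na(tlen) && tlen != 0L &&
                   identical(mate_contig, f[3])) abs(tlen) else NA_integer_,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) res <- empty_alignments(sample_id)
  res
}

# reference span of a CIGAR string (M/=/X/D/N consume reference)
cigar_ref_span <- function(cigar, seq_len) {
  if (is.na(cigar) || cigar == "*") return(seq_len)
  ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  if (ops[1] == -1L) ps_format_error("malformed CIGAR '%s'", cigar)
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  sum(n[op %in% c("M", "=", "X", "D", "N")])
}

#' Write alignments as a minimal SAM file
#'
#' Emits `@SQ` headers and the 11 mandatory columns (qualities as `*`),
#' including pairing flags, mate coordinates and a signed `TLEN` when mate
#' links are present; enough for `samtools`-style downstream tools and for
#' round-tripping through [import_sam()] with inserts preserved.
#'
#' @param alignments alignment data.frame.
#' @param genome reference genome the records refer to.
#' @param path output file.
#' @export
write_sam <- function(alignments, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)), con)
  if (nrow(alignments) > 0L) {
    a <- alignments
    has_role <- "role" %in% names(a)
    paired <- has_role & if (has_role) a$role %in% c("mate1", "mate2") else FALSE
    mate_ok <- paired & !is.na(a$mate_contig)
    flag <- ifelse(a$strand == "-", 16L, 0L) +
      ifelse(paired, 1L, 0L) +
      ifelse(paired & !mate_ok, 8L, 0L) +
      ifelse(mate_ok & !is.na(a$mate_strand) & a$mate_strand == "-", 32L, 0L) +
      ifelse(has_role & paired & a$role == "mate1", 64L, 0L) +
      ifelse(has_role & paired & a$role == "mate2", 128L, 0L)
    cig <- ifelse(is.na(a$cigar), paste0(a$length, "M"), a$cigar)
    rnext <- ifelse(mate_ok, ifelse(a$mate_contig == a$contig, "=",
                                    a$mate_contig), "*")
    pnext <- ifelse(mate_ok, a$mate_pos + 1L, 0L)
    tlen <- ifelse(mate_ok & !is.na(a$insert),
                   ifelse(a$pos <= a$mate_pos, a$insert, -a$insert), 0L)
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t%s\t%d\t%d\t%s\t*\tNM:i:%d",
                       a$read_id, flag, a$contig, a$pos + 1L, cig,
                       rnext, pnext, tlen, a$seq,
                       ifelse(is.na(a$nm), 0L, a$nm)), con)
  }
  invisible(path)
}
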