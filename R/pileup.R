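#' Build a per-position pileup from alignments
#'
#' Counts, for every reference position, the read bases aligned over it
#' (A/C/G/T/N), and collects insertion evidence (keyed by the string inserted
#' after a position) and deletion evidence (keyed by deleted length starting
#' at a position) from gapped CIGARs of imported alignments. The internal
#' mapper is ungapped, so its records contribute base counts only; indel
#' evidence for it comes from planted-truth comparisons or imported SAM.
#'
#' @param alignments alignment data.frame from [map_reads()] or
#'   [import_sam()].
#' @param genome reference genome.
#' @return object of class `ps_pileup`: `counts` (per contig, a `5 x len`
#'   integer matrix with rows A/C/G/T/N), `depth` (per contig integer
#'   vector, the column sums), `ins`/`del` (data.frames of indel evidence),
#'   `sample_id`, `contigs`.
#' @export
build_pileup <- function(alignments, genome) {
  validate_genome(genome)
  cidx <- match(alignments$contig, names(genome))
  if (anyNA(cidx))
    ps_consistency_error("alignments refer to contigs not in the reference")
  res <- tryCatch(
    .ps_pileup(unclass(genome), cidx, alignments$pos, alignments$seq,
               alignments$cigar),
    error = function(e) ps_consistency_error("%s", conditionMessage(e)))
  names(res$counts) <- names(genome)
  for (i in seq_along(res$counts))
    rownames(res$counts[[i]]) <- c("A", "C", "G", "T", "N")
  res$ins$contig <- names(genome)[res$ins$contig]
  res$del$contig <- names(genome)[res$del$contig]
  structure(list(
    counts = res$counts,
    depth = lapply(res$counts, colSums),
    ins = res$ins, del = res$del,
    sample_id = if (nrow(alignments) > 0L) alignments$sample_id[1] else "sample",
    contigs = setNames(nchar(genome), names(genome))),
    class = "ps_pileup")
}

#' @export
print.ps_pileup <- function(x, ...) {
  cov <- mean_coverage(x)
  cat(sprintf("pileup [%s]: %d contig(s), mean coverage %.1fx over covered positions\n",
              x$sample_id, length(x$counts), cov))
  invisible(x)
}

#' Mean coverage of a sample
#'
#' Computed over positions with depth >= 1 (not the whole genome), matching
#' the per-sample average coverage that the 40%-coverage screen threshold
#' refers to under incomplete mapping. Set `covered_only = FALSE` to average
#' over all positions instead.
#'
#' @param pileup a `ps_pileup`.
#' @param covered_only average over covered positions only (default TRUE).
#' @return mean fold coverage (0 for an empty pileup).
#' @export
mean_coverage <- function(pileup, covered_only = TRUE) {
  tot <- sum(vapply(pileup$depth, function(d) sum(as.numeric(d)), numeric(1)))
  den <- if (covered_only)
    sum(vapply(pileup$depth, function(d) sum(d > 0L), numeric(1)))
  else sum(pileup$contigs)
  if (den == 0) 0 else tot / den
}

#' Per-position coverage track of a sample
#' @param pileup a `ps_pileup`.
#' @return named list (per contig) of integer depth vectors.
#' @export
coverage_track <- function(pileup) pileup$depth

#' Sequencing summary statistics (run-report table rows)
#'
#' The per-sample summary mirrors the standard pooled-sequencing report:
#' total reads after cleaning, read length, total megabases
#' (`round(total_reads * read_length / 1e6)`), fold coverage
#' (total bases / genome length, one decimal), mapped reads and mapped
#' percentage (one decimal). Zero reads yield a zero row, not an error.
#'
#' @param total_reads reads after cleaning (vectorised over samples).
#' @param read_length read length in bases.
#' @param mapped_reads reads mapped to the reference.
#' @param genome_length reference length in bases.
#' @param sample_id sample label(s).
#' @return data.frame with one row per sample.
#' @examples
#' # wild-type pool arithmetic: 28,760,231 reads of 76 b -> 2186 Mb, 60.2% mapped
#' sequencing_summary(28760231, 76, 17322318, 40e6)
#' @export
sequencing_summary <- function(total_reads, read_length, mapped_reads,
                               genome_length, sample_id = "sample") {
  if (any(genome_length <= 0)) ps_input_error("genome_length must be > 0")
  total_mb <- round(total_reads * read_length / 1e6)
  data.frame(
    sample_id = sample_id,
    total_reads = total_reads,
    read_length = read_length,
    total_mb = total_mb,
    coverage = round(total_reads * read_length / genome_length, 1),
    mapped_reads = mapped_reads,
    mapped_pct = ifelse(total_reads == 0, 0,
                        round(100 * mapped_reads / total_reads, 1)),
    stringsAsFactors = FALSE)
}
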