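#' Simulate mate-pair (or single-end) reads from a pool of haplotypes
#'
#' Fragments are drawn uniformly across the supplied haplotype genomes (so a
#' mutation carried by k of n isolates is sampled at frequency k/n), with
#' fragment length `Normal(insert_mean, insert_sd)` truncated at `read_len`,
#' and `read_len` bases read inward from both fragment ends. Substitution
#' errors are i.i.d. per base at `error_rate`; each base is independently
#' replaced by `N` at `n_rate` (this models the undetermined-base calls the
#' read-cleaning stage removes). Read names record the source haplotype,
#' contig, 0-based fragment start and fragment length
#' (`f<i>|h<hap>|<contig>|<start>|<fraglen>`) for oracle checks.
#'
#' @param haplotypes a single genome (named character vector) or a list of
#'   genomes, one per isolate.
#' @param coverage target fold coverage; emitted bases are
#'   `coverage * genome_length` up to rounding of the read count.
#' @param read_len read length in bases (default 76).
#' @param insert_mean,insert_sd fragment ("insert") size distribution,
#'   outer-distance convention (defaults 2000 and 200, emulating a 2-kb
#'   jumping library).
#' @param error_rate per-base substitution error rate in `[0, 1)`.
#' @param n_rate per-base probability of an undetermined `N` call.
#' @param paired if `FALSE`, single-end reads of `read_len` are emitted.
#' @param seed optional integer seed.
#' @return list of class `ps_readsim`: `mate1`, `mate2` (each a `ps_reads`
#'   list with `id` and `seq`; `mate2` is `NULL` for single-end), and
#'   `truth` (data.frame of fragment origins).
#' @export
simulate_reads <- function(haplotypes, coverage, read_len = 76L,
                           insert_mean = 2000, insert_sd = 200,
                           error_rate = 0, n_rate = 0, paired = TRUE,
                           seed = NULL) {
  if (!is.list(haplotypes)) haplotypes <- list(haplotypes)
  haplotypes <- lapply(haplotypes, unclass)
  if (!is.numeric(coverage) || coverage <= 0) ps_input_error("coverage must be > 0")
  if (paired && read_len > insert_mean)
    ps_input_error("read_len must not exceed insert_mean")
  for (r in c(error_rate, n_rate))
    if (r < 0 || r >= 1) ps_input_error("rates must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  g <- mean(vapply(haplotypes, function(h) sum(nchar(h)), numeric(1)))
  bases_per_frag <- if (paired) 2L * read_len else read_len
  n_frags <- as.integer(round(coverage * g / bases_per_frag))
  if (n_frags < 1L) ps_input_error("coverage too low: no fragments to draw")
  out <- .ps_sim_reads(haplotypes, n_frags, as.integer(read_len),
                       insert_mean, insert_sd, error_rate, n_rate, paired)
  res <- list(
    mate1 = ps_reads(out$id, out$seq1),
    mate2 = if (paired) ps_reads(out$id, out$seq2) else NULL,
    truth = data.frame(id = out$id, hap = out$hap,
                       contig = names(haplotypes[[1]])[out$contig],
                       start = out$start, frag = out$frag,
                       stringsAsFactors = FALSE))
  class(res) <- "ps_readsim"
  res
}

ps_reads <- function(id, seq) {
  structure(list(id = id, seq = seq), class = "ps_reads")
}

#' @export
print.ps_reads <- function(x, ...) {
  cat(sprintf("read set: %d reads\n", length(x$id)))
  invisible(x)
}

n_reads <- function(x) if (is.null(x)) 0L else length(x$id)

#' Write a read set to FASTQ
#'
#' Qualities are written as a constant placeholder (`I`): the simulator has
#' no base-quality model and none of the downstream stages consume
#' qualities.
#'
#' @param reads a `ps_reads` set.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  if (n_reads(reads) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  qual <- strrep("I", nchar(reads$seq))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(rbind(paste0("@", reads$id), reads$seq, "+", qual)), con)
  invisible(path)
}

#' Read a FASTQ file into a read set
#' @param path FASTQ file.
#' @return a `ps_reads` list with `id` and `seq`.
#' @export
read_fastq <- function(path) {
  if (file.size(path) == 0L) return(ps_reads(character(0), character(0)))
  ss <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq"),
                 error = function(e) ps_format_error("bad FASTQ '%s': %s",
                                                     path, conditionMessage(e)))
  ps_reads(sub("\\s.*$", "", names(ss)), as.character(ss))
}

#' Remove reads containing undetermined bases
#'
#' Any read with one or more `N` bases is dropped. A read whose mate was
#' dropped survives as a single read; intact pairs are kept paired. This is
#' the read-cleaning rule applied before mapping; total reads after cleaning
#' is the figure summarised per sample in the run report.
#'
#' @param mate1,mate2 `ps_reads` sets or FASTQ paths, record-aligned by
#'   read id (`mate2 = NULL` for single-end input).
#' @param out_prefix optional path prefix; when given, cleaned mates and
#'   singles are written to `<prefix>_1.fastq`, `<prefix>_2.fastq`,
#'   `<prefix>_singles.fastq`.
#' @return list of class `ps_cleaned`: `mate1`, `mate2`, `singles`
#'   (`ps_reads`), and `counts` with `input_reads`, `retained_pairs`,
#'   `singles`, `dropped`. Conservation: `2*retained_pairs + singles +
#'   dropped == input_reads`.
#' @export
clean_reads <- function(mate1, mate2 = NULL, out_prefix = NULL) {
  if (is.character(mate1) && length(mate1) == 1L) mate1 <- read_fastq(mate1)
  if (is.character(mate2) && length(mate2) == 1L) mate2 <- read_fastq(mate2)
  if (is.null(mate2)) {
    has_n <- grepl("N", mate1$seq, fixed = TRUE)
    res <- list(mate1 = NULL, mate2 = NULL,
                singles = ps_reads(mate1$id[!has_n], mate1$seq[!has_n]),
                counts = c(input_reads = length(mate1$id),
                           retained_pairs = 0L,
                           singles = sum(!has_n), dropped = sum(has_n)))
  } else {
    if (n_reads(mate1) != n_reads(mate2))
      ps_format_error("mate files are not record-aligned (%d vs %d reads)",
                      n_reads(mate1), n_reads(mate2))
    if (n_reads(mate1) > 0L && !all(strip_mate_suffix(mate1$id) ==
                                    strip_mate_suffix(mate2$id)))
      ps_format_error("mate files are not record-aligned (read ids differ)")
    n1 <- grepl("N", mate1$seq, fixed = TRUE)
    n2 <- grepl("N", mate2$seq, fixed = TRUE)
    keep <- !n1 & !n2
    s1 <- !n1 & n2
    s2 <- n1 & !n2
    res <- list(
      mate1 = ps_reads(mate1$id[keep], mate1$seq[keep]),
      mate2 = ps_reads(mate2$id[keep], mate2$seq[keep]),
      singles = ps_reads(c(mate1$id[s1], mate2$id[s2]),
                         c(mate1$seq[s1], mate2$seq[s2])),
      counts = c(input_reads = 2L * length(keep),
                 retained_pairs = sum(keep),
                 singles = sum(s1) + sum(s2),
                 dropped = sum(n1) + sum(n2)))
  }
  class(res) <- "ps_cleaned"
  if (!is.null(out_prefix)) {
    if (!is.null(res$mate1)) {
      write_fastq(res$mate1, paste0(out_prefix, "_1.fastq"))
      write_fastq(res$mate2, paste0(out_prefix, "_2.fastq"))
    }
    write_fastq(res$singles, paste0(out_prefix, "_singles.fastq"))
  }
  res
}

strip_mate_suffix <- function(id) sub("/[12]$", "", id)
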