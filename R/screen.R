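#' Screen configuration
#'
#' Houses the filtering constants of the small-variant screen. The defaults
#' are the literal published rules: a site in a sample counts only with
#' depth at least `coverage_fraction` (40%) of that sample's average
#' coverage, full penetrance means alt fraction `penetrance_min` (exactly
#' 1.0: every read carries the variant), and absence in another sample
#' tolerates at most `absence_max_alt` (0) variant reads. For error-prone
#' data (real reads, or simulated reads with substitution errors)
#' `penetrance_min` and `absence_max_alt` are the documented relaxation
#' knobs; a site's penetrance is then "all reads up to sequencing error".
#'
#' @param coverage_fraction fraction of the sample mean coverage required
#'   for a sample's evidence to count (default 0.4).
#' @param penetrance_min minimum alt fraction counted as full penetrance
#'   (default 1.0).
#' @param absence_max_alt maximum alt reads tolerated in a sample that must
#'   lack the variant (default 0).
#' @param min_absent_depth minimum depth required before a sample can assert
#'   absence (default 1); an uncovered sample cannot, and the site is
#'   classified `inconsistent`.
#' @param homopolymer_min_run minimum single-base run length for the
#'   homopolymer flag on 1-base indels (default 3).
#' @param strict_all_samples require the coverage rule in every sample at
#'   the site, not only the pattern samples (default FALSE).
#' @param max_indel_len longest indel treated as a small variant (default 3,
#'   i.e. indels under 4 bases).
#' @return object of class `screen_config`.
#' @export
screen_config <- function(coverage_fraction = 0.4, penetrance_min = 1.0,
                          absence_max_alt = 0L, min_absent_depth = 1L,
                          homopolymer_min_run = 3L,
                          strict_all_samples = FALSE, max_indel_len = 3L) {
  if (coverage_fraction < 0 || coverage_fraction > 1)
    ps_config_error("coverage_fraction must be in [0, 1]")
  if (penetrance_min <= 0 || penetrance_min > 1)
    ps_config_error("penetrance_min must be in (0, 1]")
  if (absence_max_alt < 0 || min_absent_depth < 0)
    ps_config_error("absence_max_alt and min_absent_depth must be >= 0")
  structure(list(coverage_fraction = coverage_fraction,
                 penetrance_min = penetrance_min,
                 absence_max_alt = as.integer(absence_max_alt),
                 min_absent_depth = as.integer(min_absent_depth),
                 homopolymer_min_run = as.integer(homopolymer_min_run),
                 strict_all_samples = isTRUE(strict_all_samples),
                 max_indel_len = as.integer(max_indel_len)),
            class = "screen_config")
}

BASES <- c("A", "C", "G", "T")

# Left-align an indel within a homopolymer/repeat context so identical
# events share a (contig, pos, ref, alt) key across samples.
normalize_indel <- function(seq, type, pos, allele) {
  if (type == "del") {
    len <- nchar(allele)
    while (pos > 0L &&
           substr(seq, pos, pos) == substr(seq, pos + len, pos + len)) {
      pos <- pos - 1L
      allele <- sub0(seq, pos, pos + len)
    }
  } else { # ins, anchored after pos
    while (pos >= 1L &&
           substr(seq, pos + 1L, pos + 1L) ==
           substr(allele, nchar(allele), nchar(allele))) {
      allele <- paste0(substr(seq, pos + 1L, pos + 1L),
                       substr(allele, 1L, nchar(allele) - 1L))
      pos <- pos - 1L
    }
  }
  list(pos = pos, allele = allele)
}

#' Call small variants across samples from pileups
#'
#' Emits every site at which any sample shows at least `min_alt_reads`
#' reads supporting a non-reference allele, restricted to SNPs and indels of
#' at most `cfg$max_indel_len` bases (longer events are the structural
#' screen's task). Per-sample evidence is merged on shared
#' (contig, pos, allele) keys; indels are left-aligned first so identical
#' events coincide.
#'
#' @param pileups named list of `ps_pileup` objects, one per sample, all
#'   built against the same reference.
#' @param genome the shared reference genome.
#' @param cfg a [screen_config()].
#' @param min_alt_reads minimum alt reads for a sample to contribute
#'   evidence (default 1).
#' @return data.frame of site calls: `contig`, `pos` (0-based), `type`
#'   (`snp`/`ins`/`del`), `ref`, `alt`, and per sample `depth_<s>` and
#'   `alt_<s>` columns. Class `ps_site_calls`.
#' @export
call_small_variants <- function(pileups, genome, cfg = screen_config(),
                                min_alt_reads = 1L) {
  validate_genome(genome)
  samples <- names(pileups)
  if (is.null(samples) || any(samples == ""))
    ps_input_error("pileups must be a named list (sample ids)")
  for (p in pileups) {
    if (!identical(unname(p$contigs), unname(nchar(genome))) ||
        !identical(names(p$contigs), names(genome)))
      ps_consistency_error("pileups cover different references")
  }
  ref_idx <- lapply(seq_along(genome), function(i) {
    match(strsplit(genome[[i]], "")[[1]], c(BASES, "N"))
  })
  names(ref_idx) <- names(genome)

  ev <- list()
  for (s in samples) {
    p <- pileups[[s]]
    for (cc in names(genome)) {
      m <- p$counts[[cc]]
      ri <- ref_idx[[cc]]
      for (b in 1:4) {
        idx <- which(m[b, ] >= min_alt_reads & ri != b & ri <= 4L)
        if (length(idx) == 0L) next
        ev[[length(ev) + 1L]] <- data.table(
          contig = cc, pos = idx - 1L, type = "snp",
          ref = BASES[ri[idx]], alt = BASES[b],
          sample = s, alt_count = m[b, idx])
      }
    }
    ins <- p$ins[nchar(p$ins$seq) <= cfg$max_indel_len &
                   nchar(p$ins$seq) >= 1L & p$ins$count >= min_alt_reads, ]
    if (nrow(ins) > 0L) {
      for (j in seq_len(nrow(ins))) {
        nz <- normalize_indel(genome[[ins$contig[j]]], "ins",
                              as.integer(ins$pos[j]), ins$seq[j])
        ev[[length(ev) + 1L]] <- data.table(
          contig = ins$contig[j], pos = nz$pos, type = "ins",
          ref = "", alt = nz$allele, sample = s, alt_count = ins$count[j])
      }
    }
    del <- p$del[p$del$len <= cfg$max_indel_len & p$del$len >= 1L &
                   p$del$count >= min_alt_reads, ]
    if (nrow(del) > 0L) {
      for (j in seq_len(nrow(del))) {
        allele <- sub0(genome[[del$contig[j]]], as.integer(del$pos[j]),
                       as.integer(del$pos[j]) + del$len[j])
        nz <- normalize_indel(genome[[del$contig[j]]], "del",
                              as.integer(del$pos[j]), allele)
        ev[[length(ev) + 1L]] <- data.table(
          contig = del$contig[j], pos = nz$pos, type = "del",
          ref = nz$allele, alt = "", sample = s, alt_count = del$count[j])
      }
    }
  }
  if (length(ev) == 0L) {
    w <- data.table(contig = character(0), pos = integer(0),
                    type = character(0), ref = character(0),
                    alt = character(0))
    for (s in samples) {
      w[, paste0("depth_", s) := integer(0)]
      w[, paste0("alt_", s) := integer(0)]
    }
    return(finish_calls(w, samples))
  }
  ev <- rbindlist(ev)
  # identical normalized events within a sample merge
  ev <- ev[, .(alt_count = sum(alt_count)),
           by = .(contig, pos, type, ref, alt, sample)]
  w <- dcast(ev, contig + pos + type + ref + alt ~ sample,
             value.var = "alt_count", fill = 0L)
  for (s in setdiff(samples, names(w))) w[, (s) := 0L]
  setnames(w, samples, paste0("alt_", samples))
  for (s in samples) {
    d <- integer(nrow(w))
    for (cc in unique(w$contig)) {
      i <- which(w$contig == cc)
      # depth at the site; deletion sites use the anchor base one position
      # left, which every spanning read covers exactly once (reads
      # supporting the deletion leave no base at the deleted position
      # itself, and after left-alignment may or may not cover it)
      at <- ifelse(w$type[i] == "del", pmax(w$pos[i] - 1L, 0L), w$pos[i])
      d[i] <- pileups[[s]]$depth[[cc]][at + 1L]
    }
    w[, paste0("depth_", s) := d]
  }
  setorder(w, contig, pos, type, alt)
  finish_calls(w, samples)
}

finish_calls <- function(w, samples) {
  data.table::setDF(w)
  ord <- c("contig", "pos", "type", "ref", "alt",
           paste0("depth_", samples), paste0("alt_", samples))
  w <- w[, c(ord, setdiff(names(w), ord))]
  attr(w, "samples") <- samples
  class(w) <- c("ps_site_calls", "data.frame")
  w
}

call_samples <- function(calls) {
  s <- attr(calls, "samples")
  if (is.null(s)) s <- sub("^alt_", "", grep("^alt_", names(calls), value = TRUE))
  s
}

#' Annotate site calls with per-sample coverage sufficiency
#'
#' A sample's evidence at a site is sufficient iff its depth is at least
#' `cfg$coverage_fraction` of that sample's mean coverage (the 40% rule).
#'
#' @param calls a `ps_site_calls` data.frame.
#' @param mean_cov named numeric vector of per-sample mean coverage
#'   (see [mean_coverage()]).
#' @param cfg a [screen_config()].
#' @return `calls` with logical `suff_<s>` columns added.
#' @export
apply_coverage_filter <- function(calls, mean_cov, cfg = screen_config()) {
  samples <- call_samples(calls)
  if (!all(samples %in% names(mean_cov)))
    ps_input_error("mean_cov must name every sample")
  if (any(mean_cov[samples] <= 0))
    ps_input_error("mean coverage must be > 0 per sample")
  for (s in samples)
    calls[[paste0("suff_", s)]] <-
      calls[[paste0("depth_", s)]] >= cfg$coverage_fraction * mean_cov[[s]]
  calls
}

#' Classify sites by cross-sample presence pattern
#'
#' The screen's core rule set. Per site the fully-penetrant sample set is
#' computed (alt fraction >= `penetrance_min`); then:
#' \itemize{
#'   \item penetrant with sufficient coverage in \emph{all} samples:
#'     `reference_error` (a defect of the reference assembly, not a
#'     mutation);
#'   \item fully penetrant in a sample set that equals the expected pattern
#'     of a design lineage, with sufficient coverage in those samples and at
#'     most `absence_max_alt` variant reads in every other sample that has
#'     depth >= `min_absent_depth`: `pattern_candidate`, tagged with the
#'     matched lineage;
#'   \item pattern matches but a pattern sample fails the coverage rule:
#'     `low_coverage`;
#'   \item a sample that must lack the variant has no usable depth, so
#'     absence cannot be asserted: `inconsistent`;
#'   \item variant present but below full penetrance somewhere (a
#'     segregating background mutation or error noise):
#'     `partial_penetrance`;
#'   \item anything else: `inconsistent`.
#' }
#'
#' @param calls coverage-annotated site calls (run [apply_coverage_filter()]
#'   first).
#' @param design the [pool_design()]; a lineage's expected pattern is the
#'   set of samples in which it is `fixed`.
#' @param cfg a [screen_config()].
#' @return data.frame of class `ps_screen`: the calls plus
#'   `classification`, `pattern`, `matched_lineage` and `homopolymer_flag`
#'   columns.
#' @export
screen_patterns <- function(calls, design, cfg = screen_config()) {
  samples <- design$samples
  have <- call_samples(calls)
  if (!setequal(samples, have))
    ps_consistency_error("design samples and call samples differ")
  if (!all(paste0("suff_", samples) %in% names(calls)))
    ps_input_error("calls lack coverage annotation; run apply_coverage_filter()")
  k <- length(samples)
  if (k > 30L) ps_config_error("at most 30 samples supported")
  n <- nrow(calls)
  D <- as.matrix(calls[, paste0("depth_", samples), drop = FALSE])
  A <- as.matrix(calls[, paste0("alt_", samples), drop = FALSE])
  S <- as.matrix(calls[, paste0("suff_", samples), drop = FALSE])
  frac <- A / pmax(D, 1L)
  full <- D > 0L & frac >= cfg$penetrance_min
  pen <- full & S
  partial <- A > 0L & !full
  bits <- 2^(seq_len(k) - 1L)
  all_mask <- sum(bits)
  bm <- function(m) as.integer(m %*% bits)
  fullbm <- bm(full); penbm <- bm(pen); suffbm <- bm(S)
  coverbm <- bm(D >= cfg$min_absent_depth)
  leakbm <- bm(A > cfg$absence_max_alt)

  lin_mask <- vapply(design$lineages, function(l) {
    sum(bits[samples %in% expected_pattern(design, l)])
  }, numeric(1))
  if (anyDuplicated(lin_mask))
    ps_config_error("two lineages share the same expected pattern")

  cls <- rep("inconsistent", n)
  lineage <- rep(NA_character_, n)

  is_ref <- penbm == all_mask
  cls[is_ref] <- "reference_error"
  full_all <- !is_ref & fullbm == all_mask
  cls[full_all] <- "low_coverage"

  mi <- match(fullbm, lin_mask)
  matched <- !is.na(mi) & !is_ref & !full_all
  nonpat <- all_mask - fullbm
  patt_suff <- bitwAnd(fullbm, suffbm) == fullbm
  if (cfg$strict_all_samples) patt_suff <- patt_suff & suffbm == all_mask
  abs_cover <- bitwAnd(nonpat, coverbm) == nonpat
  abs_clean <- bitwAnd(nonpat, leakbm) == 0L

  cand <- matched & patt_suff & abs_cover & abs_clean
  cls[cand] <- "pattern_candidate"
  lineage[cand] <- design$lineages[mi[cand]]
  lowc <- matched & !patt_suff
  cls[lowc] <- "low_coverage"
  noabs <- matched & patt_suff & !abs_cover
  cls[noabs] <- "inconsistent"

  rest <- !(is_ref | full_all | cand | lowc | noabs)
  has_partial <- rowSums(partial) > 0L
  cls[rest & has_partial] <- "partial_penetrance"

  pat_str <- vapply(unique(fullbm), function(m) {
    paste(samples[bitwAnd(m, bits) > 0], collapse = "+")
  }, character(1))
  names(pat_str) <- as.character(unique(fullbm))

  out <- calls
  out$classification <- cls
  out$pattern <- unname(pat_str[as.character(fullbm)])
  out$matched_lineage <- lineage
  out$homopolymer_flag <- FALSE
  attr(out, "samples") <- samples
  attr(out, "design") <- design
  class(out) <- c("ps_screen", "data.frame")
  out
}

#' @export
print.ps_screen <- function(x, ...) {
  cat(sprintf("variant screen: %d sites\n", nrow(x)))
  print(table(x$classification))
  pc <- as.data.frame(x)[x$classification == "pattern_candidate", , drop = FALSE]
  if (nrow(pc) > 0L) {
    cat("pattern candidates:\n")
    print(pc[, c("contig", "pos", "type", "ref", "alt", "pattern",
                 "matched_lineage")], row.names = FALSE)
  }
  invisible(x)
}

# longest single-base run containing 0-based position pos
hp_run <- function(seq, pos) {
  b <- substr(seq, pos + 1L, pos + 1L)
  l <- pos
  while (l > 0L && substr(seq, l, l) == b) l <- l - 1L
  r <- pos + 2L
  while (r <= nchar(seq) && substr(seq, r, r) == b) r <- r + 1L
  r - l - 1L
}

#' Flag 1-base indels inside homopolymer runs
#'
#' Single-base indels within runs of one base are the signature error mode
#' of pyrosequencing-derived reference assemblies; flagged sites are the
#' prime suspects among shared reference errors. SNPs are exempt.
#'
#' @param screen a `ps_screen` (or `ps_site_calls`) data.frame.
#' @param genome reference genome.
#' @param cfg a [screen_config()]; flag requires a run of at least
#'   `homopolymer_min_run` bases.
#' @return the input with `homopolymer_flag` set.
#' @export
flag_homopolymers <- function(screen, genome, cfg = screen_config()) {
  flag <- rep(FALSE, nrow(screen))
  idx <- which(screen$type %in% c("ins", "del") &
                 nchar(paste0(screen$ref, screen$alt)) == 1L)
  for (i in idx) {
    seq <- genome[[screen$contig[i]]]
    p <- screen$pos[i]
    run <- if (screen$type[i] == "del") hp_run(seq, p)
    else max(hp_run(seq, p), if (p + 2L <= nchar(seq)) hp_run(seq, p + 1L) else 0L)
    flag[i] <- run >= cfg$homopolymer_min_run
  }
  screen$homopolymer_flag <- flag
  screen
}

#' Correct shared reference errors in the assembly
#'
#' Substitutes the consensus alternate allele at every supplied site,
#' applying corrections in descending coordinate order so positions refer to
#' the uncorrected reference throughout.
#'
#' @param genome reference genome.
#' @param errors data.frame with `contig`, `pos`, `type`, `ref`, `alt`
#'   (typically the `reference_error` rows of a `ps_screen`).
#' @return list with `genome` (corrected) and `log` (data.frame mapping each
#'   correction to its cumulative downstream coordinate shift per contig).
#' @export
apply_reference_corrections <- function(genome, errors) {
  if (nrow(errors) == 0L) return(list(genome = genome, log = NULL))
  specs <- lapply(seq_len(nrow(errors)), function(i) {
    r <- errors[i, ]
    switch(r$type,
           snp = mutation_spec("snp", r$contig, r$pos, ref = r$ref, alt = r$alt),
           ins = mutation_spec("small_insertion", r$contig, r$pos, alt = r$alt),
           del = mutation_spec("small_deletion", r$contig, r$pos, ref = r$ref),
           ps_input_error("unknown correction type '%s'", r$type))
  })
  corrected <- tryCatch(plant_mutations(genome, specs),
                        ps_input_error = function(e)
                          ps_consistency_error("overlapping corrections: %s",
                                               conditionMessage(e)))
  log <- errors[, c("contig", "pos", "type", "ref", "alt")]
  delta <- nchar(errors$alt) - nchar(errors$ref)
  delta[errors$type == "snp"] <- 0L
  log <- log[order(log$contig, log$pos), ]
  log$shift_after <- stats::ave(delta[order(errors$contig, errors$pos)],
                                log$contig, FUN = cumsum)
  list(genome = corrected$genome, log = log)
}

#' Per-genotype screen summary (report table)
#'
#' Mirrors the published summary layout: per lineage, the number of small
#' variants whose consensus presence (alt fraction >= 0.5) matches the
#' lineage's expected sample pattern with sufficient coverage there, and how
#' many of those survive the full-penetrance rule.
#'
#' @param screen a `ps_screen`.
#' @param design the [pool_design()].
#' @return data.frame with one row per lineage.
#' @export
screen_summary <- function(screen, design) {
  samples <- design$samples
  D <- as.matrix(screen[, paste0("depth_", samples), drop = FALSE])
  A <- as.matrix(screen[, paste0("alt_", samples), drop = FALSE])
  S <- as.matrix(screen[, paste0("suff_", samples), drop = FALSE])
  occ <- D > 0L & A / pmax(D, 1L) >= 0.5
  bits <- 2^(seq_along(samples) - 1L)
  occbm <- as.integer(occ %*% bits)
  suffbm <- as.integer(S %*% bits)
  rows <- lapply(design$lineages, function(l) {
    patt <- expected_pattern(design, l)
    m <- sum(bits[samples %in% patt])
    ncov <- sum(occbm == m & bitwAnd(suffbm, m) == m)
    npen <- sum(screen$classification == "pattern_candidate" &
                  !is.na(screen$matched_lineage) & screen$matched_lineage == l)
    data.frame(lineage = l, sequenced_samples = paste(patt, collapse = "+"),
               n_variants_coverage_pass = ncov,
               n_full_penetrance = npen, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write screened sites as VCF-like records
#'
#' One record per site with 1-based `POS`, anchored indel alleles, the
#' classification/pattern/lineage/homopolymer annotations in `INFO`, and
#' per-sample `DP:AC` genotype fields.
#'
#' @param screen a `ps_screen`.
#' @param genome reference genome (for indel anchor bases).
#' @param path output file.
#' @export
write_screen_vcf <- function(screen, genome, path) {
  samples <- call_samples(screen)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2-like",
               "##INFO=CLASS,PATTERN,LINEAGE,HP",
               "##FORMAT=DP:AC",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  if (nrow(screen) == 0L) return(invisible(path))
  pos1 <- ref <- alt <- character(nrow(screen))
  for (i in seq_len(nrow(screen))) {
    seq <- genome[[screen$contig[i]]]
    p <- screen$pos[i]
    if (screen$type[i] == "snp") {
      pos1[i] <- p + 1L; ref[i] <- screen$ref[i]; alt[i] <- screen$alt[i]
    } else if (screen$type[i] == "ins") {
      anchor <- substr(seq, p + 1L, p + 1L)
      pos1[i] <- p + 1L; ref[i] <- anchor; alt[i] <- paste0(anchor, screen$alt[i])
    } else {
      anchor <- if (p > 0L) substr(seq, p, p) else "N"
      pos1[i] <- max(p, 1L); ref[i] <- paste0(anchor, screen$ref[i]); alt[i] <- anchor
    }
  }
  info <- sprintf("CLASS=%s;PATTERN=%s;LINEAGE=%s;HP=%d",
                  screen$classification, screen$pattern,
                  ifelse(is.na(screen$matched_lineage), ".",
                         screen$matched_lineage),
                  as.integer(screen$homopolymer_flag))
  gt <- do.call(paste, c(lapply(samples, function(s) {
    sprintf("%d:%d", screen[[paste0("depth_", s)]], screen[[paste0("alt_", s)]])
  }), sep = "\t"))
  writeLines(paste(screen$contig, pos1, ".", ref, alt, ".", "PASS", info,
                   "DP:AC", gt, sep = "\t"), con)
  invisible(path)
}
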