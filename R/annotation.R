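#' Construct a gene model
#'
#' A minimal coding gene model: ordered CDS exon intervals on a contig. The
#' first exon starts at the ATG and the last exon ends with the stop codon;
#' introns are the inter-exon gaps. Coordinates are 0-based half-open in
#' genomic (forward-strand) orientation; transcription direction is given by
#' `strand`.
#'
#' @param gene_id gene identifier.
#' @param contig contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame/matrix with columns `start`, `end` (0-based
#'   half-open, ascending, non-overlapping).
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, contig, strand, exons) {
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) == 0L || any(exons$end <= exons$start))
    ps_input_error("exons must be non-empty half-open intervals")
  if (nrow(exons) > 1L && any(exons$start[-1] < exons$end[-nrow(exons)]))
    ps_input_error("exons overlap")
  if (!strand %in% c("+", "-")) ps_input_error("strand must be + or -")
  structure(list(gene_id = gene_id, contig = contig, strand = strand,
                 exons = exons),
            class = "gene_model")
}

gene_span <- function(model) c(min(model$exons$start), max(model$exons$end))

# Express a model in transcription-local coordinates over its genomic span.
# Returns the span pre-mRNA (reverse-complemented for minus-strand genes)
# plus exon/intron intervals local to it, ordered 5'->3'.
localize_model <- function(model, genome) {
  if (!model$contig %in% names(genome))
    ps_consistency_error("gene '%s' on contig '%s' absent from genome",
                         model$gene_id, model$contig)
  sp <- gene_span(model)
  seq <- sub0(genome[[model$contig]], sp[1], sp[2])
  ex <- model$exons
  if (model$strand == "+") {
    loc <- data.frame(start = ex$start - sp[1], end = ex$end - sp[1])
  } else {
    seq <- revcomp_chr(seq)
    loc <- data.frame(start = sp[2] - rev(ex$end), end = sp[2] - rev(ex$start))
  }
  introns <- if (nrow(loc) > 1L) {
    data.frame(start = loc$end[-nrow(loc)], end = loc$start[-1])
  } else data.frame(start = integer(0), end = integer(0))
  list(seq = seq, exons = loc, introns = introns, span = sp,
       span_len = sp[2] - sp[1])
}

# genomic 0-based position -> transcription-local coordinate
localize_pos <- function(model, pos) {
  sp <- gene_span(model)
  if (model$strand == "+") pos - sp[1] else sp[2] - 1L - pos
}

# translate from position 1 of `seq` until a stop codon or sequence end
peptide_to_stop <- function(seq) {
  n3 <- nchar(seq) %/% 3L
  if (n3 == 0L) return(list(peptide = "", has_stop = FALSE, cds_len = 0L))
  codons <- substring(seq, 3L * (seq_len(n3) - 1L) + 1L, 3L * seq_len(n3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at) == 0L) {
    list(peptide = paste(aa, collapse = ""), has_stop = FALSE,
         cds_len = 3L * n3)
  } else {
    k <- stop_at[1]
    list(peptide = paste(aa[seq_len(k - 1L)], collapse = ""),
         has_stop = TRUE, cds_len = 3L * k)
  }
}

spliced_cds <- function(model, genome) {
  loc <- localize_model(model, genome)
  paste(substring(loc$seq, loc$exons$start + 1L, loc$exons$end), collapse = "")
}

#' Validate a gene model against the genome
#'
#' Checks the canonical splice dinucleotides (introns begin `GT` and end
#' `AG` on the coding strand), an `ATG` start, a terminal stop codon and a
#' CDS length divisible by 3. Problems produce warnings, not errors — real
#' annotations contain exceptions.
#'
#' @param model a [gene_model()].
#' @param genome reference genome.
#' @return invisible logical: TRUE if all checks pass.
#' @export
validate_gene_model <- function(model, genome) {
  loc <- localize_model(model, genome)
  ok <- TRUE
  for (i in seq_len(nrow(loc$introns))) {
    d <- substring(loc$seq, loc$introns$start[i] + 1L, loc$introns$start[i] + 2L)
    a <- substring(loc$seq, loc$introns$end[i] - 1L, loc$introns$end[i])
    if (d != "GT" || a != "AG") {
      warning(sprintf("gene %s intron %d is %s..%s, not GT..AG",
                      model$gene_id, i, d, a))
      ok <- FALSE
    }
  }
  cds <- spliced_cds(model, genome)
  if (nchar(cds) %% 3L != 0L) {
    warning(sprintf("gene %s CDS length %d not a multiple of 3",
                    model$gene_id, nchar(cds)))
    ok <- FALSE
  } else {
    pep <- peptide_to_stop(cds)
    if (substr(cds, 1, 3) != "ATG")
      warning(sprintf("gene %s does not start with ATG", model$gene_id))
    if (!pep$has_stop || pep$cds_len != nchar(cds)) {
      warning(sprintf("gene %s: internal or missing stop codon", model$gene_id))
      ok <- FALSE
    }
  }
  invisible(ok)
}

#' Load gene models from GFF3
#'
#' Reads `CDS` features grouped by their `Parent` transcript; 1-based
#' inclusive GFF coordinates become the 0-based half-open intervals used
#' internally.
#'
#' @param path GFF3 file.
#' @param genome optional genome; when given each model is checked with
#'   [validate_gene_model()] (warnings only).
#' @return named list of [gene_model()] objects.
#' @export
load_gene_models <- function(path, genome = NULL) {
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) ps_format_error("bad GFF3 '%s': %s", path,
                                                     conditionMessage(e)))
  md <- as.data.frame(gr)
  cds <- md[md$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) ps_format_error("no CDS features in '%s'", path)
  parent <- vapply(cds$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                   character(1))
  parent[is.na(parent)] <- cds$ID[is.na(parent)]
  models <- lapply(split(seq_len(nrow(cds)), parent), function(i) {
    rows <- cds[i, ]
    gene_model(gene_id = sub("^(mRNA|transcript)[:.]", "", rows$Parent[[1]][1]),
               contig = as.character(rows$seqnames[1]),
               strand = as.character(rows$strand[1]),
               exons = data.frame(start = rows$start - 1L, end = rows$end))
  })
  names(models) <- vapply(models, `[[`, character(1), "gene_id")
  if (!is.null(genome)) for (m in models) validate_gene_model(m, genome)
  models
}

#' Write gene models as GFF3
#' @param models list of [gene_model()].
#' @param path output file.
#' @export
write_gene_models_gff <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (m in models) {
    sp <- gene_span(m)
    writeLines(sprintf("%s\tpoolscreen\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s",
                       m$contig, sp[1] + 1L, sp[2], m$strand, m$gene_id), con)
    writeLines(sprintf("%s\tpoolscreen\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=gene:%s",
                       m$contig, sp[1] + 1L, sp[2], m$strand, m$gene_id,
                       m$gene_id), con)
    phase <- 0L
    ex <- m$exons
    ord <- if (m$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
    for (i in ord) {
      writeLines(sprintf("%s\tpoolscreen\tCDS\t%d\t%d\t.\t%s\t%d\tID=cds:%s;Parent=%s",
                         m$contig, ex$start[i] + 1L, ex$end[i], m$strand,
                         phase, m$gene_id, m$gene_id), con)
      phase <- (3L - (ex$end[i] - ex$start[i] - phase) %% 3L) %% 3L
    }
  }
  invisible(path)
}

#' Classify the molecular consequence of a variant
#'
#' Category is determined solely by coordinates, alleles and the gene model:
#' a SNP in the first two bases of an intron is `splice_donor` (last two:
#' `splice_acceptor`), a SNP converting the CDS stop codon to a sense codon
#' is `stop_loss`, large deletions and complex replacements overlapping
#' coding exons are `cds_deletion`, small indels in coding exons are
#' `frameshift_indel` or `inframe_indel` by length, and exonic SNPs are
#' classified by codon comparison on the coding strand. Variants outside
#' every model are `intergenic`.
#'
#' @param variant list or one-row data.frame with `contig`, `pos` (0-based),
#'   `type` (`snp`/`ins`/`del`/`large_deletion`/`complex_replacement`),
#'   `ref`, `alt`, and `len` for deletions.
#' @param models list of [gene_model()].
#' @param genome reference genome.
#' @return list of class `ps_consequence`: `category`, `gene_id`, `detail`.
#' @export
classify_variant <- function(variant, models, genome) {
  v <- as.list(variant)
  if (!v$contig %in% names(genome))
    ps_consistency_error("variant contig '%s' absent from genome", v$contig)
  v$pos <- as.integer(v$pos)
  vlen <- if (!is.null(v$len) && !is.na(v$len)) as.integer(v$len)
  else max(nchar(v$ref), 1L)
  v_end <- if (v$type %in% c("del", "large_deletion", "complex_replacement"))
    v$pos + vlen else v$pos + 1L

  res <- function(category, gene_id = NA_character_, detail = "")
    structure(list(category = category, gene_id = gene_id, detail = detail),
              class = "ps_consequence")

  hits <- Filter(function(m) {
    m$contig == v$contig && {
      sp <- gene_span(m); v$pos < sp[2] && v_end > sp[1]
    }
  }, models)
  if (length(hits) == 0L) return(res("intergenic"))
  m <- hits[[1]]
  loc <- localize_model(m, genome)

  if (v$type %in% c("large_deletion", "complex_replacement") ||
      (v$type == "del" && vlen > 3L)) {
    cds_hit <- any(v$pos < m$exons$end & v_end > m$exons$start)
    return(res(if (cds_hit) "cds_deletion" else "intronic", m$gene_id,
               sprintf("%d b deleted", vlen)))
  }

  lp <- localize_pos(m, v$pos)
  in_exon <- which(lp >= loc$exons$start & lp < loc$exons$end)
  if (length(in_exon) == 0L) {
    ii <- which(lp >= loc$introns$start & lp < loc$introns$end)
    if (length(ii) == 0L) return(res("intergenic"))  # within span gaps cannot occur
    off5 <- lp - loc$introns$start[ii]
    off3 <- loc$introns$end[ii] - 1L - lp
    if (v$type == "snp" && off5 <= 1L)
      return(res("splice_donor", m$gene_id,
                 sprintf("intron %d, donor base %d", ii, off5 + 1L)))
    if (v$type == "snp" && off3 <= 1L)
      return(res("splice_acceptor", m$gene_id,
                 sprintf("intron %d, acceptor base %d", ii, 2L - off3)))
    return(res("intronic", m$gene_id, sprintf("intron %d", ii)))
  }

  if (v$type %in% c("ins", "del")) {
    ilen <- if (v$type == "ins") nchar(v$alt) else vlen
    cat <- if (ilen %% 3L == 0L) "inframe_indel" else "frameshift_indel"
    return(res(cat, m$gene_id, sprintf("%s of %d b in exon", v$type, ilen)))
  }

  # exonic SNP: codon comparison on the coding strand
  ei <- in_exon[1]
  cp <- sum(loc$exons$end[seq_len(ei - 1L)] - loc$exons$start[seq_len(ei - 1L)]) +
    (lp - loc$exons$start[ei])
  cds <- spliced_cds(m, genome)
  ci <- cp %/% 3L
  codon <- substr(cds, 3L * ci + 1L, 3L * ci + 3L)
  alt_local <- if (m$strand == "+") v$alt else revcomp_chr(v$alt)
  ref_local <- if (m$strand == "+") v$ref else revcomp_chr(v$ref)
  if (substr(cds, cp + 1L, cp + 1L) != ref_local)
    ps_consistency_error("variant ref does not match CDS at %s:%d",
                         v$contig, v$pos)
  mcodon <- codon
  substr(mcodon, cp %% 3L + 1L, cp %% 3L + 1L) <- alt_local
  ref_aa <- unname(Biostrings::GENETIC_CODE[codon])
  alt_aa <- unname(Biostrings::GENETIC_CODE[mcodon])
  detail <- sprintf("codon %d %s>%s (%s>%s)", ci + 1L, codon, mcodon,
                    ref_aa, alt_aa)
  if (ref_aa == "*" && alt_aa != "*") return(res("stop_loss", m$gene_id, detail))
  if (alt_aa == "*" && ref_aa != "*") return(res("nonsense", m$gene_id, detail))
  if (ref_aa == alt_aa) return(res("synonymous", m$gene_id, detail))
  res("missense", m$gene_id, detail)
}

#' @export
print.ps_consequence <- function(x, ...) {
  cat(sprintf("%s%s%s\n", x$category,
              if (!is.na(x$gene_id)) paste0(" [", x$gene_id, "]") else "",
              if (nzchar(x$detail)) paste0(": ", x$detail) else ""))
  invisible(x)
}

#' C-terminal extension length of a stop-loss mutant
#'
#' Translates the mutant gene in frame from the (former) stop codon through
#' downstream genomic sequence to the next in-frame stop and returns the
#' number of residues added to the protein. Under the default `inclusive`
#' convention the residue now encoded by the mutated stop codon counts and
#' the new terminal stop does not; `exclusive` counts only residues beyond
#' the mutated codon (the conventions differ by exactly 1).
#'
#' @param model the [gene_model()] (wild-type coordinates).
#' @param genome genome carrying the stop-loss mutation.
#' @param convention `"inclusive"` (default) or `"exclusive"`.
#' @return list of class `ps_stoploss`: `extension_aa`, `added_peptide`,
#'   `runs_off_contig` (TRUE when no downstream in-frame stop exists before
#'   the contig end, in which case `extension_aa` is `NA`).
#' @export
stop_loss_extension <- function(model, genome,
                                convention = c("inclusive", "exclusive")) {
  convention <- match.arg(convention)
  cds <- spliced_cds(model, genome)
  last_codon <- substr(cds, nchar(cds) - 2L, nchar(cds))
  last_aa <- unname(Biostrings::GENETIC_CODE[last_codon])
  if (is.na(last_aa) || last_aa == "*")
    ps_input_error("terminal codon '%s' is still a stop; not a stop-loss allele",
                   last_codon)
  sp <- gene_span(model)
  contig_seq <- genome[[model$contig]]
  downstream <- if (model$strand == "+") {
    sub0(contig_seq, sp[2], nchar(contig_seq))
  } else {
    revcomp_chr(sub0(contig_seq, 0L, sp[1]))
  }
  scan <- peptide_to_stop(downstream)
  if (!scan$has_stop) {
    return(structure(list(extension_aa = NA_integer_,
                          added_peptide = paste0(last_aa, scan$peptide),
                          runs_off_contig = TRUE), class = "ps_stoploss"))
  }
  n_down <- nchar(scan$peptide)
  structure(list(
    extension_aa = n_down + if (convention == "inclusive") 1L else 0L,
    added_peptide = paste0(last_aa, scan$peptide),
    runs_off_contig = FALSE), class = "ps_stoploss")
}

#' Mis-splicing outcomes of a disrupted splice donor
#'
#' Emits the transcripts a broken 5' splice site produces: (a) the
#' retention transcript, in which the disrupted intron is kept while all
#' other introns splice normally, and (b), when a cryptic donor coordinate
#' is supplied, the transcript spliced from that donor to the intron's
#' normal acceptor. Each transcript is translated from the model's start
#' codon; frameshifted transcripts typically hit a premature stop and yield
#' a shorter peptide that diverges from the wild type at the frameshift.
#' Cryptic donors are taken as given (they are established experimentally),
#' not predicted.
#'
#' @param model the [gene_model()].
#' @param genome reference (or mutant) genome.
#' @param disrupted_intron 1-based intron index.
#' @param cryptic_donor optional genomic 0-based coordinate of the cryptic
#'   donor (first base of the new intron); must lie within the gene span
#'   and before the disrupted intron's acceptor.
#' @return data.frame with one row per transcript (`wild_type`,
#'   `retention`, `cryptic`): coding length to the stop codon (`cds_len`),
#'   peptide, peptide length, premature-stop flag, and the first amino-acid
#'   position diverging from wild type (`NA` if identical or a pure
#'   truncation).
#' @export
splice_defect_transcripts <- function(model, genome, disrupted_intron,
                                      cryptic_donor = NULL) {
  loc <- localize_model(model, genome)
  di <- as.integer(disrupted_intron)
  if (di < 1L || di > nrow(loc$introns))
    ps_input_error("gene %s has no intron %d", model$gene_id, di)
  n_ex <- nrow(loc$exons)

  transcript_from <- function(kept) {
    paste(substring(loc$seq, kept$start + 1L, kept$end), collapse = "")
  }
  wt <- transcript_from(loc$exons)
  keep_ret <- data.frame(
    start = c(loc$exons$start[seq_len(di)], loc$introns$start[di],
              loc$exons$start[seq(di + 1L, n_ex)]),
    end = c(loc$exons$end[seq_len(di)], loc$introns$end[di],
            loc$exons$end[seq(di + 1L, n_ex)]))
  keep_ret <- keep_ret[order(keep_ret$start), ]
  # retained intron is contiguous with its exons; merge for substring safety
  ret <- transcript_from(keep_ret)

  rows <- list(transcript_row("wild_type", wt, wt),
               transcript_row("retention", ret, wt))

  if (!is.null(cryptic_donor)) {
    cd <- localize_pos(model, as.integer(cryptic_donor))
    if (cd <= loc$exons$start[di] || cd >= loc$introns$end[di])
      ps_input_error("cryptic donor outside gene span or past the acceptor")
    keep <- data.frame(
      start = c(loc$exons$start[seq_len(di - 1L)], loc$exons$start[di],
                loc$exons$start[seq(di + 1L, n_ex)]),
      end = c(loc$exons$end[seq_len(di - 1L)], cd,
              loc$exons$end[seq(di + 1L, n_ex)]))
    rows <- c(rows, list(transcript_row("cryptic", transcript_from(keep), wt)))
  }
  do.call(rbind, rows)
}

transcript_row <- function(name, seq, wt_seq) {
  p <- peptide_to_stop(seq)
  wt <- peptide_to_stop(wt_seq)
  div <- NA_integer_
  if (p$peptide != wt$peptide) {
    n <- min(nchar(p$peptide), nchar(wt$peptide))
    if (n > 0L) {
      a <- strsplit(substr(p$peptide, 1, n), "")[[1]]
      b <- strsplit(substr(wt$peptide, 1, n), "")[[1]]
      d <- which(a != b)
      div <- if (length(d) > 0L) d[1] else n + 1L
    } else div <- 1L
  }
  data.frame(transcript = name, transcript_len = nchar(seq),
             cds_len = p$cds_len, peptide = p$peptide,
             peptide_len = nchar(p$peptide),
             premature_stop = p$has_stop & nchar(p$peptide) < nchar(wt$peptide),
             divergence_aa = div, stringsAsFactors = FALSE)
}
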