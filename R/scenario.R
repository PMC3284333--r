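#' Embed a synthetic coding gene in a genome
#'
#' Overwrites a stretch of the genome with a well-formed coding gene:
#' an ATG start, internal-stop-free sense codons, a terminal stop codon
#' (`TGA`, so a single transition in its last base creates a stop-loss
#' allele), and GT..AG introns. Used by the study scenarios so that
#' splice-site and stop-codon lesions can be planted with known
#' consequences.
#'
#' @param genome reference genome (modified copy is returned).
#' @param contig contig to place the gene on.
#' @param start 0-based genomic start of the gene.
#' @param gene_id identifier for the model.
#' @param strand `"+"` or `"-"`.
#' @param exon_lens CDS exon lengths 5'->3' (sum must be divisible by 3).
#' @param intron_lens intron lengths (one fewer than exons).
#' @return list with `genome` (gene written in) and `model`
#'   (the [gene_model()]).
#' @export
synthesize_gene <- function(genome, contig, start, gene_id, strand = "+",
                            exon_lens = c(301, 143, 219), intron_lens = c(63, 58)) {
  if (length(intron_lens) != length(exon_lens) - 1L)
    ps_input_error("need one fewer intron than exons")
  if (sum(exon_lens) %% 3L != 0L)
    ps_input_error("total CDS length must be divisible by 3")
  sense <- setdiff(names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"],
                   character(0))
  n_codons <- sum(exon_lens) / 3L
  cds <- paste0("ATG",
                paste(sample(sense, n_codons - 2L, replace = TRUE), collapse = ""),
                "TGA")
  bases <- c("A", "C", "G", "T")
  introns <- vapply(intron_lens, function(l) {
    if (l < 6L) ps_input_error("introns must be at least 6 b")
    paste0("GT", paste(sample(bases, l - 4L, replace = TRUE), collapse = ""), "AG")
  }, character(1))
  # interleave exons and introns in transcription order
  cuts <- cumsum(exon_lens)
  exon_seqs <- substring(cds, c(1L, cuts[-length(cuts)] + 1L), cuts)
  pieces <- character(0)
  local_exons <- data.frame(start = integer(0), end = integer(0))
  at <- 0L
  for (i in seq_along(exon_seqs)) {
    pieces <- c(pieces, exon_seqs[i])
    local_exons <- rbind(local_exons,
                         data.frame(start = at, end = at + exon_lens[i]))
    at <- at + exon_lens[i]
    if (i <= length(introns)) {
      pieces <- c(pieces, introns[i])
      at <- at + intron_lens[i]
    }
  }
  gene_seq <- paste(pieces, collapse = "")
  glen <- nchar(gene_seq)
  if (start + glen > nchar(genome[[contig]]))
    ps_input_error("gene does not fit at %s:%d", contig, start)
  genomic_seq <- if (strand == "+") gene_seq else revcomp_chr(gene_seq)
  g <- unclass(genome)
  g[[contig]] <- paste0(substr(g[[contig]], 1L, start), genomic_seq,
                        substr(g[[contig]], start + glen + 1L,
                               nchar(g[[contig]])))
  class(g) <- "ref_genome"
  exons <- if (strand == "+") {
    data.frame(start = start + local_exons$start, end = start + local_exons$end)
  } else {
    data.frame(start = start + glen - local_exons$end,
               end = start + glen - local_exons$start)
  }
  list(genome = g, model = gene_model(gene_id, contig, strand, exons))
}

# positions (0-based) of a coding-strand base inside a model, given the
# local CDS coordinate; returns genomic position
genomic_of_cds_pos <- function(model, cds_pos) {
  ex <- model$exons
  lens <- ex$end - ex$start
  if (model$strand == "-") { ex <- ex[rev(seq_len(nrow(ex))), ]; lens <- rev(lens) }
  cum <- cumsum(lens)
  ei <- which(cds_pos < cum)[1]
  off <- cds_pos - if (ei > 1L) cum[ei - 1L] else 0L
  if (model$strand == "+") ex$start[ei] + off else ex$end[ei] - 1L - off
}

#' Construct the standard simulated mapping study
#'
#' Builds the full study design the package's analyses are exercised on: a
#' random genome carrying two synthetic genes, three mutant lineages (`A`,
#' `fus`, `B`) with EMS-style background mutations, and three causative
#' lesions — an intergenic SNP for lineage `A`, a splice-donor G-to-A SNP in
#' the first base of intron 2 of the `tih`-like gene for `fus`, and a
#' stop-loss A-to-G SNP in the stop codon of the (minus-strand) GATA-like
#' gene for `B`. Four pools are designed after the published crossing
#' scheme: `wt` (wild-type spores from the A x fus cross), `A_fus` (double
#' mutant), `fus` (single mutant) and `B` (single mutant with fus
#' counter-selected).
#'
#' Uses the current RNG state; call `set.seed()` first for reproducibility.
#'
#' @param genome_length total genome size in bases (default 2 Mb).
#' @param n_contigs number of contigs.
#' @param gc GC fraction.
#' @param n_background background (non-causative) mutations per lineage
#'   (default 40, i.e. 120 segregating loci in total).
#' @param n_isolates isolates per pool (default 40).
#' @param indel_fraction fraction of background mutations that are 1-3 b
#'   indels.
#' @return list of class `ps_scenario`: `genome`, `models`, `specs`,
#'   `design`, `truth`, `causative` (truth rows of the planted lesions).
#' @export
study_scenario <- function(genome_length = 2e6, n_contigs = 1L, gc = 0.5,
                           n_background = 40L, n_isolates = 40L,
                           indel_fraction = 0.1) {
  lens <- rep(floor(genome_length / n_contigs), n_contigs)
  genome <- generate_genome(n_contigs, lens)
  cc <- names(genome)[1]
  gpos1 <- floor(lens[1] * 0.30)
  gpos2 <- floor(lens[1] * 0.62)
  g1 <- synthesize_gene(genome, cc, gpos1, "tih_like", strand = "+",
                        exon_lens = c(301, 143, 219), intron_lens = c(63, 58))
  g2 <- synthesize_gene(g1$genome, cc, gpos2, "gata_like", strand = "-",
                        exon_lens = c(400, 254), intron_lens = c(71))
  genome <- g2$genome
  models <- list(tih_like = g1$model, gata_like = g2$model)

  # causative lesions
  loc1 <- localize_model(models$tih_like, genome)
  donor_local <- loc1$introns$start[2]                    # first base of intron 2
  donor_gpos <- gene_span(models$tih_like)[1] + donor_local  # plus strand
  stopifnot(sub0(genome[[cc]], donor_gpos, donor_gpos + 1L) == "G")
  cds2_len <- sum(models$gata_like$exons$end - models$gata_like$exons$start)
  stop3_gpos <- genomic_of_cds_pos(models$gata_like, cds2_len - 1L)  # last base of TGA
  stop_ref <- sub0(genome[[cc]], stop3_gpos, stop3_gpos + 1L)
  stop_alt <- if (models$gata_like$strand == "+") "G" else "C"  # coding A->G
  a_pos <- floor(lens[1] * 0.10)
  a_ref <- sub0(genome[[cc]], a_pos, a_pos + 1L)
  causative <- list(
    mutation_spec("snp", cc, a_pos, ref = a_ref, alt = transition_of[[a_ref]],
                  lineage = "A", causative = TRUE),
    mutation_spec("snp", cc, donor_gpos, ref = "G", alt = "A",
                  lineage = "fus", causative = TRUE),
    mutation_spec("snp", cc, stop3_gpos, ref = stop_ref, alt = stop_alt,
                  lineage = "B", causative = TRUE))

  # background mutations: avoid the genes and the causative sites
  exclude <- rbind(
    data.frame(contig = cc, start = gene_span(models$tih_like)[1] - 10L,
               end = gene_span(models$tih_like)[2] + 10L),
    data.frame(contig = cc, start = gene_span(models$gata_like)[1] - 10L,
               end = gene_span(models$gata_like)[2] + 10L),
    data.frame(contig = cc, start = a_pos - 10L, end = a_pos + 10L))
  lineages <- c("A", "fus", "B")
  bg <- random_mutation_specs(genome, n_background * length(lineages),
                              lineage = "bg", indel_fraction = indel_fraction,
                              min_spacing = 12L)
  bg <- Filter(function(s) {
    !any(exclude$contig == s$contig & s$pos >= exclude$start &
           s$pos < exclude$end)
  }, bg)
  lin_assign <- rep(lineages, length.out = length(bg))
  for (i in seq_along(bg)) bg[[i]]$lineage <- lin_assign[i]

  specs <- c(causative, bg)
  presence <- rbind(
    wt    = c(A = "absent", fus = "absent", B = "none"),
    A_fus = c(A = "fixed",  fus = "fixed",  B = "none"),
    fus   = c(A = "none",   fus = "fixed",  B = "none"),
    B     = c(A = "none",   fus = "absent", B = "fixed"))
  design <- pool_design(rownames(presence), lineages, presence,
                        n_isolates = n_isolates)
  structure(list(genome = genome, models = models, specs = specs,
                 design = design, truth = truth_table(specs),
                 causative = truth_table(causative)),
            class = "ps_scenario")
}

#' Construct the structural-lesion scenario
#'
#' Two mutant lineages on a clean genome: `del` carries an unbalanced
#' kilobase-scale deletion, and `bal` carries a balanced complex
#' replacement — the same-size deletion whose interval is occupied by
#' duplicated (one inverted) copies of flanking sequence, the lesion type
#' that insert-size analysis cannot see. Three pools: `wt`, `del`, `bal`.
#'
#' @param genome_length genome size (default 300 kb).
#' @param del_len deleted length (default 1100, after the published 1.1-kb
#'   case).
#' @param replaced_len total length of duplicated flank copies in the
#'   balanced lesion (default 1080).
#' @param n_isolates isolates per pool.
#' @return list of class `ps_scenario` (no gene models).
#' @export
structural_scenario <- function(genome_length = 3e5, del_len = 1100L,
                                replaced_len = 1080L, n_isolates = 40L) {
  genome <- generate_genome(1L, genome_length)
  cc <- names(genome)[1]
  p_del <- floor(genome_length * 0.25)
  p_bal <- floor(genome_length * 0.65)
  l1 <- floor(replaced_len * 0.5)
  l2 <- floor(replaced_len * 0.26)
  l3 <- replaced_len - l1 - l2
  plan <- data.frame(
    start = c(p_bal - l1, p_bal + del_len, p_bal - 20L - l3),
    end = c(p_bal, p_bal + del_len + l2, p_bal - 20L),
    orientation = c("fwd", "rev", "fwd"))
  specs <- list(
    mutation_spec("large_deletion", cc, p_del, len = del_len,
                  lineage = "del", causative = TRUE),
    mutation_spec("complex_replacement", cc, p_bal, len = del_len,
                  plan = plan, lineage = "bal", causative = TRUE))
  presence <- rbind(wt  = c(del = "absent", bal = "absent"),
                    del = c(del = "fixed",  bal = "none"),
                    bal = c(del = "none",   bal = "fixed"))
  design <- pool_design(rownames(presence), c("del", "bal"), presence,
                        n_isolates = n_isolates)
  structure(list(genome = genome, models = list(), specs = specs,
                 design = design, truth = truth_table(specs),
                 causative = truth_table(specs)),
            class = "ps_scenario")
}

#' Simulate the sequencing of one pool
#'
#' Draws the pool composition, builds the isolate haplotype genomes, and
#' simulates reads from the mixture.
#'
#' @param scenario a study scenario ([study_scenario()] etc.), or a list
#'   with `genome`, `specs`, `design`.
#' @param sample sample id.
#' @param coverage fold coverage.
#' @param read_len,insert_mean,insert_sd,error_rate,n_rate,paired see
#'   [simulate_reads()].
#' @return list with `reads` (a `ps_readsim`) and `pool` (isolate counts).
#' @export
simulate_sample_reads <- function(scenario, sample, coverage, read_len = 76L,
                                  insert_mean = 2000, insert_sd = 200,
                                  error_rate = 0, n_rate = 0, paired = TRUE) {
  pool <- simulate_pool(scenario$specs, scenario$design, sample)
  haps <- build_pool_haplotypes(scenario$genome, scenario$specs,
                                attr(pool, "genotypes"))
  reads <- simulate_reads(haps, coverage, read_len = read_len,
                          insert_mean = insert_mean, insert_sd = insert_sd,
                          error_rate = error_rate, n_rate = n_rate,
                          paired = paired)
  list(reads = reads, pool = pool)
}

#' Run the full in-memory analysis of a simulated study
#'
#' For every pool: simulate reads, clean, map with the internal mapper and
#' build the pileup; then run the small-variant screen across pools. This
#' is the programmatic (file-free) counterpart of [run_pipeline()] and the
#' workhorse of the package's validation suites.
#'
#' @param scenario a `ps_scenario`.
#' @param coverage fold coverage per pool (default 50).
#' @param read_len,insert_mean,insert_sd,error_rate,n_rate read-simulation
#'   parameters.
#' @param cfg a [screen_config()].
#' @param seed_len,max_mismatches internal mapper parameters.
#' @param keep set of extra per-sample objects to retain: any of
#'   `"pileups"`, `"alignments"` (slim, for insert-size analysis),
#'   `"tracks"`, `"pools"`.
#' @return list of class `ps_study_run`: `screen` (a `ps_screen`),
#'   `summary` (per-sample [sequencing_summary()] rows), `mean_cov`, plus
#'   any requested `keep` elements.
#' @export
screen_simulated_study <- function(scenario, coverage = 50, read_len = 76L,
                                   insert_mean = 2000, insert_sd = 200,
                                   error_rate = 0.005, n_rate = 0.001,
                                   cfg = screen_config(penetrance_min = 0.9,
                                                       absence_max_alt = 2L),
                                   seed_len = 20L, max_mismatches = 3L,
                                   keep = character(0)) {
  samples <- scenario$design$samples
  pileups <- list()
  alns <- list()
  tracks <- list()
  pools <- list()
  summary <- NULL
  for (s in samples) {
    sim <- simulate_sample_reads(scenario, s, coverage, read_len,
                                 insert_mean, insert_sd, error_rate, n_rate)
    cl <- clean_reads(sim$reads$mate1, sim$reads$mate2)
    aln <- map_reads(cl, scenario$genome, seed_len = seed_len,
                     max_mismatches = max_mismatches, sample_id = s)
    cnt <- attr(aln, "counts")
    summary <- rbind(summary, sequencing_summary(
      cnt[["n_input"]], read_len, cnt[["n_mapped"]],
      genome_length(scenario$genome), sample_id = s))
    pileups[[s]] <- build_pileup(aln, scenario$genome)
    if ("alignments" %in% keep)
      alns[[s]] <- aln[, c("read_id", "sample_id", "contig", "pos", "length",
                           "strand", "mate_strand", "mate_pos", "insert")]
    if ("tracks" %in% keep) tracks[[s]] <- coverage_track(pileups[[s]])
    if ("pools" %in% keep) pools[[s]] <- sim$pool
    rm(sim, cl, aln)
  }
  mean_cov <- vapply(pileups, mean_coverage, numeric(1))
  calls <- call_small_variants(pileups, scenario$genome, cfg)
  calls <- apply_coverage_filter(calls, mean_cov, cfg)
  screen <- screen_patterns(calls, scenario$design, cfg)
  screen <- flag_homopolymers(screen, scenario$genome, cfg)
  out <- list(screen = screen, summary = summary, mean_cov = mean_cov)
  if ("pileups" %in% keep) out$pileups <- pileups
  if ("alignments" %in% keep) out$alignments <- alns
  if ("tracks" %in% keep) out$tracks <- tracks
  if ("pools" %in% keep) out$pools <- pools
  class(out) <- "ps_study_run"
  out
}
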