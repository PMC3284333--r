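# A deterministic two-intron fixture gene with hand-computable splicing
# outcomes, on either strand.
fixture_gene <- function(strand = "+", seed = 101) {
  set.seed(seed)
  g <- generate_genome(1, 12000)
  synthesize_gene(g, "contig_1", 4000, "fix", strand = strand,
                  exon_lens = c(99, 60, 42), intron_lens = c(30, 34))
}

test_that("synthesized genes validate and translate consistently", {
  for (strand in c("+", "-")) {
    fx <- fixture_gene(strand)
    expect_true(validate_gene_model(fx$model, fx$genome))
    # translation oracle: spliced CDS through Biostrings equals the
    # exon-concatenation peptide
    cds <- poolscreen:::spliced_cds(fx$model, fx$genome)
    bs <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    pep <- poolscreen:::peptide_to_stop(cds)
    expect_equal(paste0(pep$peptide, "*"), bs)
    expect_equal(nchar(pep$peptide), (99 + 60 + 42) / 3 - 1)
  }
})

test_that("GFF3 round-trip preserves gene models on both strands", {
  fx1 <- fixture_gene("+")
  fx2 <- synthesize_gene(fx1$genome, "contig_1", 8000, "fix2", strand = "-",
                         exon_lens = c(150, 75), intron_lens = c(40))
  f <- tempfile(fileext = ".gff3")
  write_gene_models_gff(list(fx1$model, fx2$model), f)
  back <- load_gene_models(f, genome = fx2$genome)
  expect_setequal(names(back), c("fix", "fix2"))
  expect_equal(back$fix$exons, fx1$model$exons)
  expect_equal(back$fix2$strand, "-")
  expect_equal(back$fix2$exons, fx2$model$exons)
})

test_that("variant categories follow coordinates, alleles and strand", {
  for (strand in c("+", "-")) {
    fx <- fixture_gene(strand)
    g <- fx$genome; m <- fx$model
    loc <- poolscreen:::localize_model(m, g)
    to_genomic <- function(lp) {
      sp <- poolscreen:::gene_span(m)
      if (strand == "+") sp[1] + lp else sp[2] - 1L - lp
    }
    snp_at <- function(gpos, alt_local) {
      ref <- substr(g[[1]], gpos + 1, gpos + 1)
      alt <- if (strand == "+") alt_local else
        chartr("ACGT", "TGCA", alt_local)
      list(contig = "contig_1", pos = gpos, type = "snp", ref = ref, alt = alt)
    }
    # first base of intron 2 (a G of the GT donor) -> splice_donor
    d <- classify_variant(snp_at(to_genomic(loc$introns$start[2]), "A"), list(m), g)
    expect_equal(d$category, "splice_donor")
    expect_match(d$detail, "intron 2")
    # last base of intron 1 (the G of AG) -> splice_acceptor
    a <- classify_variant(snp_at(to_genomic(loc$introns$end[1] - 1L), "C"), list(m), g)
    expect_equal(a$category, "splice_acceptor")
    expect_match(a$detail, "intron 1")
    # mid-intron -> intronic
    i <- classify_variant(snp_at(to_genomic(loc$introns$start[1] + 10L), "A"),
                          list(m), g)
    expect_equal(i$category, "intronic")
    # far away -> intergenic
    far <- snp_at(100L, "A")
    far$alt <- setdiff(c("A", "C", "G", "T"), far$ref)[1]
    expect_equal(classify_variant(far, list(m), g)$category, "intergenic")
    # stop codon TGA: third base A->G gives TGG (Trp) -> stop_loss
    cds_len <- sum(m$exons$end - m$exons$start)
    sl <- classify_variant(snp_at(poolscreen:::genomic_of_cds_pos(m, cds_len - 1L),
                                  "G"), list(m), g)
    expect_equal(sl$category, "stop_loss")
  }
})

test_that("exonic SNPs classify by codon comparison and indels by frame", {
  fx <- fixture_gene("+")
  g <- fx$genome; m <- fx$model
  sp <- poolscreen:::gene_span(m)
  # ATG start: A->G at codon 1 base 1 is missense (M -> V)
  v <- list(contig = "contig_1", pos = sp[1], type = "snp", ref = "A", alt = "G")
  expect_equal(classify_variant(v, list(m), g)$category, "missense")
  # craft a nonsense change: find a TAC/TAT (Tyr) codon and hit base 3 -> TAA/TAG?
  cds <- poolscreen:::spliced_cds(m, g)
  codons <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  tgg <- which(codons == "TGG")  # Trp: TGG -> TGA by G->A at base 3
  if (length(tgg) > 0) {
    cp <- (tgg[1] - 1) * 3 + 2   # 0-based CDS coordinate of base 3
    gpos <- poolscreen:::genomic_of_cds_pos(m, cp)
    v2 <- list(contig = "contig_1", pos = gpos, type = "snp",
               ref = substr(g[[1]], gpos + 1, gpos + 1), alt = "A")
    expect_equal(classify_variant(v2, list(m), g)$category, "nonsense")
  }
  # 2-base deletion in exon 1 -> frameshift; 3-base -> in-frame
  v3 <- list(contig = "contig_1", pos = sp[1] + 10L, type = "del",
             ref = substr(g[[1]], sp[1] + 11, sp[1] + 12), alt = "", len = 2L)
  expect_equal(classify_variant(v3, list(m), g)$category, "frameshift_indel")
  v4 <- list(contig = "contig_1", pos = sp[1] + 10L, type = "del",
             ref = substr(g[[1]], sp[1] + 11, sp[1] + 13), alt = "", len = 3L)
  expect_equal(classify_variant(v4, list(m), g)$category, "inframe_indel")
  # a large deletion across the gene -> cds_deletion
  v5 <- list(contig = "contig_1", pos = sp[1] - 200L, type = "large_deletion",
             ref = "", alt = "", len = 1100L)
  expect_equal(classify_variant(v5, list(m), g)$category, "cds_deletion")
})

test_that("stop-loss extensions count residues to the next in-frame stop", {
  # hand-countable fixture: ATG TAC [TAG->CAG] GGG TAA
  # translation continues Q (the mutated stop codon), G, then TAA stops
  g <- list(c1 = paste0("ATGTACCAG", "GGGTAA", "ACGTACGT"))
  class(g) <- "ref_genome"
  m <- gene_model("mini", "c1", "+", data.frame(start = 0, end = 9))
  ext <- stop_loss_extension(m, g)
  expect_equal(ext$extension_aa, 2L)
  expect_equal(ext$added_peptide, "QG")

  g2 <- list(c1 = "ATGCAGTAAACGT")
  class(g2) <- "ref_genome"
  m2 <- gene_model("mini2", "c1", "+", data.frame(start = 0, end = 6))
  expect_equal(stop_loss_extension(m2, g2)$extension_aa, 1L)

  # no downstream stop -> runs off the contig
  g3 <- list(c1 = "ATGCAGGGGGGGGGG")
  class(g3) <- "ref_genome"
  ext3 <- stop_loss_extension(gene_model("m3", "c1", "+",
                                         data.frame(start = 0, end = 6)), g3)
  expect_true(ext3$runs_off_contig)
  expect_true(is.na(ext3$extension_aa))

  # still-stop terminal codon refuses
  g4 <- list(c1 = "ATGTAAACGTAA")
  class(g4) <- "ref_genome"
  expect_error(stop_loss_extension(gene_model("m4", "c1", "+",
                                              data.frame(start = 0, end = 6)), g4),
               class = "ps_input_error")
})

test_that("stop-loss extension equals the brute-force stop scan on random fixtures", {
  set.seed(111)
  for (i in 1:100) {
    strand <- if (i %% 2 == 0) "+" else "-"
    g <- generate_genome(1, 3000 + 100 * (i %% 7))
    fx <- synthesize_gene(g, "contig_1", 500, "r", strand = strand,
                          exon_lens = c(90, 45), intron_lens = c(21))
    m <- fx$model
    # make the stop-loss allele: TGA -> TGG at coding base 3 of the stop
    cds_len <- sum(m$exons$end - m$exons$start)
    gpos <- poolscreen:::genomic_of_cds_pos(m, cds_len - 1L)
    alt <- if (strand == "+") "G" else "C"
    ref <- substr(fx$genome[[1]], gpos + 1, gpos + 1)
    mut <- plant_mutations(fx$genome, mutation_spec("snp", "contig_1", gpos,
                                                    ref = ref, alt = alt))$genome
    got <- stop_loss_extension(m, mut)
    sp <- poolscreen:::gene_span(m)
    want <- oracle_stop_scan(mut, "contig_1", strand, sp[2], sp[1])
    if (is.na(want)) {
      expect_true(got$runs_off_contig)
    } else {
      expect_equal(got$extension_aa, want)
    }
    # exclusive convention differs by exactly one residue
    expect_equal(stop_loss_extension(m, mut, convention = "exclusive")$extension_aa,
                 got$extension_aa - 1L)
  }
})

test_that("splice defects yield the retention and cryptic-donor transcripts", {
  fx <- fixture_gene("+")
  g <- fx$genome; m <- fx$model
  loc <- poolscreen:::localize_model(m, g)
  tr <- splice_defect_transcripts(m, g, disrupted_intron = 2)
  wt_len <- 99 + 60 + 42
  expect_equal(tr$transcript_len[tr$transcript == "wild_type"], wt_len)
  expect_equal(tr$transcript_len[tr$transcript == "retention"], wt_len + 34)
  # intron 2 length 34 is not a multiple of 3: the frame shifts right after
  # exons 1+2 (53 codons), so the peptide diverges there
  ret <- tr[tr$transcript == "retention", ]
  expect_gte(ret$divergence_aa, (99 + 60) / 3 + 1)
  expect_false(identical(ret$peptide, tr$peptide[tr$transcript == "wild_type"]))

  # a cryptic donor 12 b into exon 2 shortens the transcript by 12+intron
  sp <- poolscreen:::gene_span(m)
  cd_local <- loc$exons$end[2] - 12L
  cd_genomic <- sp[1] + cd_local
  tr2 <- splice_defect_transcripts(m, g, 2, cryptic_donor = cd_genomic)
  expect_equal(tr2$transcript_len[tr2$transcript == "cryptic"], wt_len - 12)
  expect_error(splice_defect_transcripts(m, g, 2, cryptic_donor = 50L),
               class = "ps_input_error")
  expect_error(splice_defect_transcripts(m, g, 5), class = "ps_input_error")
})

test_that("retaining a 3n-length intron without stops inserts in frame", {
  # construct explicitly: exon1 ATG AAA, intron GTACCGGCAAG (no, needs 3n)
  # intron of 9: GT ACC AG -> craft GTACCCAAG (9 b, no in-frame stop when
  # retained between codons)
  exon1 <- "ATGAAA"
  intron <- "GTACCCAAG"
  exon2 <- "GATTGA"
  g <- list(c1 = paste0("AAAA", exon1, intron, exon2, "AAAA"))
  class(g) <- "ref_genome"
  m <- gene_model("tri", "c1", "+",
                  data.frame(start = c(4, 4 + 6 + 9), end = c(10, 25)))
  tr <- splice_defect_transcripts(m, g, 1)
  ret <- tr[tr$transcript == "retention", ]
  wt <- tr[tr$transcript == "wild_type", ]
  expect_equal(ret$transcript_len - wt$transcript_len, 9L)
  expect_false(ret$premature_stop)
  expect_equal(ret$peptide_len, wt$peptide_len + 3L)
})

test_that("every variant receives exactly one category", {
  fx <- fixture_gene("+")
  g <- fx$genome; m <- fx$model
  sp <- poolscreen:::gene_span(m)
  cats <- character(0)
  for (p in seq(sp[1] - 5L, sp[2] + 5L, by = 7L)) {
    ref <- substr(g[[1]], p + 1, p + 1)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    cons <- classify_variant(list(contig = "contig_1", pos = p, type = "snp",
                                  ref = ref, alt = alt), list(m), g)
    expect_length(cons$category, 1L)
    cats <- c(cats, cons$category)
  }
  expect_true(all(cats %in% c("intergenic", "intronic", "splice_donor",
                              "splice_acceptor", "synonymous", "missense",
                              "nonsense", "stop_loss")))
})
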