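# Construct a pileup object directly from explicit alignments so screen
# behaviour can be pinned without simulation noise.
pileup_from_reads <- function(genome, placements, sample_id) {
  aln <- do.call(rbind, lapply(placements, function(p)
    data.frame(read_id = p$id, sample_id = sample_id, contig = p$contig,
               pos = p$pos, strand = "+", length = nchar(p$seq), nm = 0L,
               seq = p$seq, cigar = if (is.null(p$cigar)) NA_character_ else p$cigar,
               stringsAsFactors = FALSE)))
  build_pileup(aln, genome)
}

reads_over <- function(genome, contig, from, to, n, mutate = NULL) {
  lapply(seq_len(n), function(i) {
    s <- substr(genome[[contig]], from + 1, to)
    if (!is.null(mutate)) s <- mutate(s)
    list(id = sprintf("r%d_%d", from, i), contig = contig, pos = from, seq = s)
  })
}

test_that("site calls merge per-sample evidence and respect the indel size cap", {
  g <- generate_genome(1, 2000, seed = 51)
  cc <- "contig_1"
  refb <- substr(g[[cc]], 501, 501)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  mut_fun <- function(s) { substr(s, 101, 101) <- alt; s }
  p1 <- pileup_from_reads(g, reads_over(g, cc, 400, 501, 15), "s1")
  p1b <- pileup_from_reads(g, reads_over(g, cc, 400, 501, 15,
                                         mutate = mut_fun), "s1")
  p2 <- pileup_from_reads(g, reads_over(g, cc, 400, 501, 20), "s2")
  calls <- call_small_variants(list(s1 = p1b, s2 = p2), g)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, 500)
  expect_equal(calls$alt, alt)
  expect_equal(calls$alt_s1, 15L)
  expect_equal(calls$alt_s2, 0L)
  expect_equal(calls$depth_s2, 20L)

  # no alt evidence anywhere -> empty call set
  empty <- call_small_variants(list(s1 = p1, s2 = p2), g)
  expect_equal(nrow(empty), 0L)

  # a 5-base deletion (via gapped SAM-style cigar) is excluded, 2-base kept
  del5 <- list(list(id = "d5", contig = cc, pos = 300,
                    seq = paste0(substr(g[[cc]], 301, 320),
                                 substr(g[[cc]], 326, 355)),
                    cigar = "20M5D30M"))
  del2 <- lapply(seq_len(5), function(i)
    list(id = paste0("d2_", i), contig = cc, pos = 300,
         seq = paste0(substr(g[[cc]], 301, 320), substr(g[[cc]], 323, 352)),
         cigar = "20M2D30M"))
  p3 <- pileup_from_reads(g, c(del5, del2), "s1")
  calls3 <- call_small_variants(list(s1 = p3, s2 = p2), g)
  expect_equal(nrow(calls3), 1L)
  expect_equal(calls3$type, "del")
  expect_equal(nchar(calls3$ref), 2L)
})

test_that("identical indels left-align to a shared key", {
  g <- list(c1 = "ACGTAAAAATTTTCGGGCATG")
  class(g) <- "ref_genome"
  # deleting any single A of the run normalizes to the run start
  n1 <- poolscreen:::normalize_indel(g$c1, "del", 6L, "A")
  n2 <- poolscreen:::normalize_indel(g$c1, "del", 8L, "A")
  expect_equal(n1$pos, n2$pos)
  expect_equal(n1$pos, 4L)
  # insertions rotate into the run anchor
  i1 <- poolscreen:::normalize_indel(g$c1, "ins", 8L, "A")
  i2 <- poolscreen:::normalize_indel(g$c1, "ins", 5L, "A")
  expect_equal(i1$pos, i2$pos)
})

test_that("the 40% coverage rule marks evidence sufficiency per sample", {
  cfg <- screen_config()
  calls <- data.frame(contig = "c", pos = 1L, type = "snp", ref = "A",
                      alt = "G", depth_s1 = 25L, depth_s2 = 10L,
                      alt_s1 = 25L, alt_s2 = 0L)
  attr(calls, "samples") <- c("s1", "s2")
  out <- apply_coverage_filter(calls, c(s1 = 54, s2 = 50), cfg)
  expect_true(out$suff_s1)    # 25 >= 0.4 * 54 = 21.6
  expect_false(out$suff_s2)   # 10 < 20
  out0 <- apply_coverage_filter(calls, c(s1 = 54, s2 = 50),
                                screen_config(coverage_fraction = 0))
  expect_true(out0$suff_s2)
  expect_error(apply_coverage_filter(calls, c(s1 = 54), cfg),
               class = "ps_input_error")
})

make_calls <- function(depth, alt, suff = NULL) {
  samples <- colnames(depth)
  colnames(alt) <- samples
  if (!is.null(suff)) colnames(suff) <- samples
  calls <- data.frame(contig = "c", pos = seq_len(nrow(depth)) - 1L,
                      type = "snp", ref = "A", alt = "G")
  for (s in samples) {
    calls[[paste0("depth_", s)]] <- depth[, s]
    calls[[paste0("alt_", s)]] <- alt[, s]
    calls[[paste0("suff_", s)]] <- if (is.null(suff)) TRUE else suff[, s]
  }
  attr(calls, "samples") <- samples
  calls
}

four_design <- function() {
  pres <- rbind(
    wt    = c(A = "absent", fus = "absent", B = "none"),
    A_fus = c(A = "fixed",  fus = "fixed",  B = "none"),
    fus   = c(A = "none",   fus = "fixed",  B = "none"),
    B     = c(A = "none",   fus = "absent", B = "fixed"))
  pool_design(rownames(pres), c("A", "fus", "B"), pres)
}

test_that("pattern classification implements the penetrance/absence rules", {
  design <- four_design()
  samples <- design$samples
  D <- matrix(50L, 6, 4, dimnames = list(NULL, samples))
  A <- rbind(
    c(0L, 44L, 107L, 0L),   # penetrant in the fus pattern -> candidate
    c(50L, 50L, 50L, 50L),  # penetrant everywhere -> reference error
    c(0L, 25L, 0L, 0L),     # half-frequency -> partial penetrance
    c(0L, 50L, 0L, 0L),     # matches lineage A pattern -> candidate
    c(0L, 44L, 107L, 3L),   # leakage in B -> not a candidate
    c(50L, 50L, 0L, 0L))    # penetrant in wt+A_fus: no such lineage
  D[1, ] <- c(50L, 44L, 107L, 50L)
  D[5, ] <- c(50L, 44L, 107L, 50L)
  calls <- make_calls(D, A)
  sc <- screen_patterns(calls, design, screen_config())
  expect_equal(sc$classification,
               c("pattern_candidate", "reference_error", "partial_penetrance",
                 "pattern_candidate", "partial_penetrance", "inconsistent"))
  expect_equal(sc$matched_lineage[1], "fus")
  expect_equal(sc$matched_lineage[4], "A")
  expect_equal(sc$pattern[1], "A_fus+fus")
  # classifications partition the sites
  expect_false(any(table(seq_len(nrow(sc)), sc$classification) > 1))
})

test_that("uncovered non-pattern samples and insufficient pattern samples demote sites", {
  design <- four_design()
  D <- matrix(50L, 2, 4, dimnames = list(NULL, design$samples))
  A <- rbind(c(0L, 50L, 0L, 0L), c(0L, 50L, 0L, 0L))
  D[1, "wt"] <- 0L           # absence cannot be asserted
  suff <- matrix(TRUE, 2, 4, dimnames = list(NULL, design$samples))
  suff[2, "A_fus"] <- FALSE  # pattern sample below the coverage rule
  calls <- make_calls(D, A, suff)
  sc <- screen_patterns(calls, design, screen_config())
  expect_equal(sc$classification, c("inconsistent", "low_coverage"))

  # strict mode extends the coverage rule to every sample at the site
  D2 <- matrix(50L, 1, 4, dimnames = list(NULL, design$samples))
  A2 <- matrix(c(0L, 50L, 0L, 0L), 1, 4)
  s2 <- matrix(c(TRUE, TRUE, FALSE, TRUE), 1, 4,
               dimnames = list(NULL, design$samples))  # fus sample fails
  lax <- screen_patterns(make_calls(D2, A2, s2), design, screen_config())
  strict <- screen_patterns(make_calls(D2, A2, s2), design,
                            screen_config(strict_all_samples = TRUE))
  expect_equal(lax$classification, "pattern_candidate")
  expect_equal(strict$classification, "low_coverage")
})

test_that("raising the coverage fraction never creates new candidates", {
  scen <- small_scenario(61, genome_length = 1e5)
  run <- screen_simulated_study(scen, coverage = 25, error_rate = 0.003,
                                n_rate = 0)
  calls <- run$screen
  expect_gt(nrow(calls), 0)
  design <- attr(calls, "design")
  n_prev <- Inf
  for (cf in c(0, 0.4, 0.8, 1.2)) {
    cfg <- screen_config(coverage_fraction = min(cf, 1),
                         penetrance_min = 0.9, absence_max_alt = 2)
    cl2 <- apply_coverage_filter(calls, run$mean_cov, cfg)
    sc <- screen_patterns(cl2, design, cfg)
    n <- sum(sc$classification == "pattern_candidate")
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("homopolymer flags mark 1-base indels inside runs and spare SNPs", {
  g <- list(c1 = "ACGTAAAAACGTCTTCGATG")
  class(g) <- "ref_genome"
  cfg <- screen_config()
  screen <- data.frame(
    contig = "c1",
    pos = c(5L, 5L, 13L),
    type = c("del", "snp", "ins"),
    ref = c("A", "A", ""),
    alt = c("", "G", "T"),
    stringsAsFactors = FALSE)
  out <- flag_homopolymers(screen, g, cfg)
  expect_equal(out$homopolymer_flag, c(TRUE, FALSE, FALSE))
})

test_that("reference corrections rewrite the assembly and log coordinate shifts", {
  g <- generate_genome(1, 10000, seed = 71)
  cc <- "contig_1"
  refb <- substr(g[[cc]], 101, 101)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  errs <- data.frame(contig = cc, pos = c(100L, 5000L),
                     type = c("snp", "del"),
                     ref = c(refb, substr(g[[cc]], 5001, 5001)),
                     alt = c(alt, ""), stringsAsFactors = FALSE)
  fix <- apply_reference_corrections(g, errs)
  expect_equal(nchar(fix$genome[[cc]]), 9999)
  expect_equal(substr(fix$genome[[cc]], 101, 101), alt)
  expect_equal(fix$log$shift_after, c(0L, -1L))
  # overlapping corrections refuse
  errs2 <- data.frame(contig = cc, pos = c(100L, 100L), type = c("snp", "snp"),
                      ref = refb, alt = c(alt, alt), stringsAsFactors = FALSE)
  expect_error(apply_reference_corrections(g, errs2),
               class = "ps_consistency_error")
})

test_that("correcting the reference makes shared variants vanish end to end", {
  set.seed(81)
  truth_g <- generate_genome(1, 80000)
  # corrupt the mapping reference at 12 sites
  pos <- seq(5000, 71500, length.out = 12)
  specs <- lapply(pos, function(p) {
    b <- substr(truth_g[[1]], p + 1, p + 1)
    mutation_spec("snp", "contig_1", as.integer(p), ref = b,
                  alt = poolscreen:::transition_of[[b]])
  })
  bad_ref <- plant_mutations(truth_g, specs)$genome
  pres <- rbind(s1 = c(l = "fixed"), s2 = c(l = "absent"))
  design <- pool_design(c("s1", "s2"), "l", pres)
  cfg <- screen_config(penetrance_min = 0.9, absence_max_alt = 2)
  screen_against <- function(ref) {
    pileups <- list()
    for (s in c("s1", "s2")) {
      rs <- simulate_reads(truth_g, coverage = 25, error_rate = 0.002)
      cl <- clean_reads(rs$mate1, rs$mate2)
      aln <- map_reads(cl, ref, sample_id = s)
      pileups[[s]] <- build_pileup(aln, ref)
    }
    mc <- vapply(pileups, mean_coverage, numeric(1))
    calls <- call_small_variants(pileups, ref, cfg)
    calls <- apply_coverage_filter(calls, mc, cfg)
    screen_patterns(calls, design, cfg)
  }
  sc1 <- screen_against(bad_ref)
  ref_err <- sc1[sc1$classification == "reference_error", ]
  expect_equal(sort(ref_err$pos), sort(as.integer(pos)))
  fixed <- apply_reference_corrections(bad_ref, ref_err)
  sc2 <- screen_against(fixed$genome)
  expect_equal(sum(sc2$classification == "reference_error"), 0L)
})
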