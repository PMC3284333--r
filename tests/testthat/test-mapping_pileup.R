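test_that("read cleaning drops N reads, singles orphans, and conserves totals", {
  m1 <- list(id = c("r1", "r2", "r3"), seq = c("ACGT", "ACGT", "ANGT"))
  m2 <- list(id = c("r1", "r2", "r3"), seq = c("ACNT", "TTTT", "GGGG"))
  class(m1) <- class(m2) <- "ps_reads"
  res <- clean_reads(m1, m2)
  expect_equal(unname(res$counts["retained_pairs"]), 1L)
  expect_equal(res$mate1$id, "r2")
  expect_setequal(res$singles$id, c("r1", "r3"))
  expect_equal(res$singles$seq[res$singles$id == "r1"], "ACGT")
  cnt <- res$counts
  expect_equal(unname(2 * cnt["retained_pairs"] + cnt["singles"] + cnt["dropped"]),
               unname(cnt["input_reads"]))

  # 1000 clean pairs survive untouched
  g <- generate_genome(1, 50000, seed = 8)
  rs <- simulate_reads(g, coverage = 4, seed = 1)  # ~1300 pairs, no N
  res2 <- clean_reads(rs$mate1, rs$mate2)
  expect_equal(unname(res2$counts["retained_pairs"]), length(rs$mate1$id))
  expect_equal(unname(res2$counts["singles"]), 0L)

  expect_error(clean_reads(m1, list(id = "r1", seq = "AAAA")),
               class = "ps_format_error")
})

test_that("N-injection drop rate matches the closed form 1-(1-r)^L", {
  g <- generate_genome(1, 100000, seed = 14)
  rs <- simulate_reads(g, coverage = 30, read_len = 76, n_rate = 0.01, seed = 2)
  res <- clean_reads(rs$mate1, rs$mate2)
  drop_frac <- res$counts[["dropped"]] / res$counts[["input_reads"]]
  expect_lt(abs(drop_frac - (1 - 0.99^76)), 0.02)
})

test_that("error-free reads map uniquely to their true coordinates", {
  set.seed(3)
  g <- generate_genome(1, 200000, seed = 33)
  rs <- simulate_reads(g, coverage = 8, error_rate = 0, n_rate = 0)
  expect_gt(length(rs$mate1$id), 5000)
  aln <- map_reads(rs, g, sample_id = "s1")
  cnt <- attr(aln, "counts")
  expect_equal(unname(cnt["n_mapped"]), unname(cnt["n_input"]))
  tr <- rs$truth
  m1 <- aln[aln$role == "mate1", ]
  expect_equal(m1$pos, tr$start[match(m1$read_id, tr$id)])
  m2 <- aln[aln$role == "mate2", ]
  i2 <- match(m2$read_id, tr$id)
  expect_equal(m2$pos, tr$start[i2] + tr$frag[i2] - 76L)
  expect_true(all(m2$strand == "-"))
  # observed insert equals the simulated fragment length
  expect_equal(m1$insert, tr$frag[match(m1$read_id, tr$id)])
})

test_that("reads from exactly duplicated sequence are rejected as ambiguous", {
  g <- generate_genome(1, 50000, seed = 41)
  # duplicate a 2-kb block elsewhere
  block <- substr(g[[1]], 10001, 12000)
  seq <- g[[1]]
  substr(seq, 30001, 32000) <- block
  g2 <- g; g2[[1]] <- seq
  read <- substr(seq, 10501, 10576)
  rd <- structure(list(id = "dup", seq = read), class = "ps_reads")
  aln <- map_reads(rd, g2)
  expect_equal(nrow(aln), 0L)
  expect_equal(unname(attr(aln, "counts")["n_ambiguous"]), 1L)
  # a read from unique sequence still maps
  rd2 <- structure(list(id = "uniq", seq = substr(seq, 40001, 40076)),
                   class = "ps_reads")
  expect_equal(map_reads(rd2, g2)$pos, 40000L)
})

test_that("reported placements never exceed the mismatch budget", {
  set.seed(6)
  g <- generate_genome(1, 100000, seed = 55)
  rs <- simulate_reads(g, coverage = 5, error_rate = 0.02)  # error-rich
  aln <- map_reads(rs, g, max_mismatches = 3)
  expect_true(all(aln$nm <= 3))
  # direct recount agrees with the reported nm on a sample of alignments
  idx <- sample(nrow(aln), 50)
  for (i in idx) {
    expect_equal(oracle_mismatches(aln$seq[i], g, aln$contig[i], aln$pos[i]),
                 aln$nm[i])
  }
  expect_error(map_reads(rs, structure(character(0), class = "ref_genome")),
               class = "ps_input_error")
})

test_that("pileup columns equal a brute-force recount and depths add up", {
  set.seed(10)
  g <- generate_genome(1, 40000, seed = 10)   # <= 50 kb oracle instance
  rs <- simulate_reads(g, coverage = 6, error_rate = 0.01, n_rate = 0.002)
  cl <- clean_reads(rs$mate1, rs$mate2)
  aln <- map_reads(cl, g, sample_id = "s")
  p <- build_pileup(aln, g)
  oracle <- oracle_pileup_counts(aln, g)
  expect_identical(unname(p$counts[["contig_1"]]), unname(oracle[["contig_1"]]))
  expect_identical(p$depth[["contig_1"]], colSums(p$counts[["contig_1"]]))
  # depth at each position equals the number of overlapping alignments
  pos_check <- c(1000L, 20000L, 39000L)
  for (q in pos_check) {
    n_over <- sum(aln$pos <= q & aln$pos + aln$length > q)
    expect_equal(unname(p$depth[["contig_1"]][q + 1L]), n_over)
  }
  expect_error(build_pileup(data.frame(contig = "nope", pos = 0L, seq = "A",
                                       cigar = NA, sample_id = "s"), g),
               class = "ps_consistency_error")
})

test_that("SAM import/export round-trips and converts coordinates correctly", {
  g <- generate_genome(1, 20000, seed = 17)
  rs <- simulate_reads(g, coverage = 2, seed = 4)
  aln <- map_reads(rs, g, sample_id = "s")
  f <- tempfile(fileext = ".sam")
  write_sam(aln, g, f)
  back <- import_sam(f, sample_id = "s")
  expect_equal(nrow(back), nrow(aln))
  i <- match(paste(aln$read_id, aln$role == "mate2"),
             paste(back$read_id, back$strand == "-"))
  expect_false(anyNA(i))
  expect_equal(back$pos[i], aln$pos)
  expect_equal(back$seq[i], aln$seq)

  # gapped CIGAR feeds indel evidence into the pileup
  sam <- c("@HD\tVN:1.6", sprintf("@SQ\tSN:contig_1\tLN:%d", nchar(g[[1]])),
           paste("gapped", 0, "contig_1", 101, 60, "30M2D46M", "*", 0, 0,
                 paste0(substr(g[[1]], 101, 130), substr(g[[1]], 133, 178)),
                 "*", sep = "\t"))
  f2 <- tempfile(fileext = ".sam")
  writeLines(sam, f2)
  ga <- import_sam(f2, "s")
  expect_equal(ga$length, 78L)  # reference span includes the deletion
  p <- build_pileup(ga, g)
  expect_equal(p$del$pos, 130)
  expect_equal(p$del$len, 2L)

  writeLines(c(sam[1:2], "bad\tline"), f2)
  expect_error(import_sam(f2, "s"), class = "ps_format_error")
})

test_that("sequencing summaries reproduce report-table arithmetic", {
  s <- sequencing_summary(c(1000000L, 0L), 76, c(800000L, 0L), 1e6,
                          sample_id = c("a", "b"))
  expect_equal(s$total_mb, c(76, 0))
  expect_equal(s$mapped_pct, c(80.0, 0.0))
  expect_equal(s$coverage[1], 76)
  expect_error(sequencing_summary(10, 76, 5, 0), class = "ps_input_error")
})
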