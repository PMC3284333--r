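test_that("generated genomes are reproducible, length-exact and GC-calibrated", {
  g1 <- generate_genome(1, 100000, 0.5, seed = 1)
  g2 <- generate_genome(1, 100000, 0.5, seed = 1)
  expect_identical(g1, g2)

  g <- generate_genome(2, c(50000, 30000), gc = 0.55, seed = 7)
  expect_equal(genome_length(g), 80000)
  expect_named(g, c("contig_1", "contig_2"))
  expect_false(any(grepl("[^ACGT]", g)))

  big <- generate_genome(1, 1e6, 0.5, seed = 3)
  gc <- sum(strsplit(big[[1]], "")[[1]] %in% c("G", "C")) / 1e6
  expect_gt(gc, 0.48)
  expect_lt(gc, 0.52)

  expect_error(generate_genome(1, -5, 0.5), class = "ps_input_error")
  expect_error(generate_genome(1, 100, gc = 0), class = "ps_input_error")
})

test_that("planting mutations edits exactly what each lesion kind describes", {
  g <- generate_genome(1, 20000, seed = 2)
  cc <- "contig_1"
  refb <- substr(g[[cc]], 1000, 1000)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]

  m <- plant_mutations(g, mutation_spec("snp", cc, 999, ref = refb, alt = alt))
  diff <- which(strsplit(m$genome[[cc]], "")[[1]] != strsplit(g[[cc]], "")[[1]])
  expect_identical(diff, 1000L)

  m2 <- plant_mutations(g, mutation_spec("large_deletion", cc, 5000, len = 1100))
  expect_equal(nchar(m2$genome[[cc]]), 20000 - 1100)

  plan <- data.frame(start = c(4460, 6100), end = c(5000, 6640),
                     orientation = c("fwd", "rev"))
  m3 <- plant_mutations(g, mutation_spec("complex_replacement", cc, 5000,
                                         len = 1100, plan = plan))
  expect_equal(nchar(m3$genome[[cc]]), 20000 - 1100 + 1080)
  # duplicated segments align perfectly to their planned sources
  inserted <- substr(m3$genome[[cc]], 5001, 5000 + 1080)
  want <- paste0(substr(g[[cc]], 4461, 5000),
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(substr(g[[cc]], 6101, 6640)))))
  expect_identical(inserted, want)
  # truth records stay in reference coordinates
  expect_equal(m3$truth$pos, 5000)

  expect_error(
    plant_mutations(g, mutation_spec("snp", cc, 999,
                                     ref = setdiff(c("A","C","G","T"), refb)[2],
                                     alt = refb)),
    class = "ps_consistency_error")
  expect_error(
    plant_mutations(g, list(
      mutation_spec("small_deletion", cc, 100, len = 3),
      mutation_spec("snp", cc, 101, ref = substr(g[[cc]], 102, 102),
                    alt = setdiff(c("A","C","G","T"),
                                  substr(g[[cc]], 102, 102))[1]))),
    class = "ps_input_error")
})

test_that("small indel specs respect the under-4-base rule", {
  expect_error(mutation_spec("small_deletion", "c", 10, len = 4),
               class = "ps_input_error")
  expect_error(mutation_spec("small_insertion", "c", 10, alt = "ACGT"),
               class = "ps_input_error")
  expect_error(mutation_spec("large_deletion", "c", 10, len = 100),
               class = "ps_input_error")
  s <- mutation_spec("small_insertion", "c", 10, alt = "AC")
  expect_equal(s$len, 0L)
})

test_that("pool simulation fixes causative loci and segregates backgrounds 1:1", {
  g <- generate_genome(1, 50000, seed = 4)
  cc <- "contig_1"
  base_at <- function(p) substr(g[[cc]], p + 1, p + 1)
  alt_of <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  specs <- list(
    mutation_spec("snp", cc, 100, ref = base_at(100), alt = alt_of(base_at(100)),
                  lineage = "fus", causative = TRUE),
    mutation_spec("snp", cc, 2000, ref = base_at(2000),
                  alt = alt_of(base_at(2000)), lineage = "fus"))
  pres <- rbind(wt = c(fus = "absent"), fus = c(fus = "fixed"))
  design <- pool_design(c("wt", "fus"), "fus", pres, n_isolates = 40)

  set.seed(9)
  counts <- simulate_pool(specs, design, "fus")
  expect_equal(counts[1], 40L)          # selection forces fixation
  geno <- attr(counts, "genotypes")
  expect_equal(colSums(geno), as.integer(counts))

  counts_wt <- simulate_pool(specs, design, "wt")
  expect_equal(counts_wt[1], 0L)        # counter-selected causative
  # background still segregates in the wild-type pool
  draws <- replicate(400, simulate_pool(specs, design, "wt")[2])
  expect_equal(mean(draws) / 40, 0.5, tolerance = 3 * sqrt(0.25 / 40) / sqrt(400) / 0.5)
  # Binomial(40, 0.5) stays within +/-10 of its mean essentially always
  expect_gte(mean(draws >= 10 & draws <= 30), 0.995)
})

test_that("a lineage with no fixed sample is rejected as an impossible design", {
  pres <- rbind(a = c(l1 = "segregating"), b = c(l1 = "absent"))
  expect_error(pool_design(c("a", "b"), "l1", pres), class = "ps_config_error")
})

test_that("read simulation matches its coverage contract and is seed-deterministic", {
  g <- generate_genome(1, 100000, seed = 12)
  rs <- simulate_reads(g, coverage = 50, read_len = 76, seed = 5)
  n_expected <- 50 * 1e5 / (2 * 76)
  expect_lt(abs(length(rs$mate1$id) - n_expected) / n_expected, 0.02)
  expect_equal(unique(nchar(rs$mate1$seq)), 76)

  rs2 <- simulate_reads(g, coverage = 50, read_len = 76, seed = 5)
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(rs$mate1, f1); write_fastq(rs2$mate1, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # error-free reads reproduce their source exactly
  tr <- rs$truth
  for (i in c(1, 500, 1000)) {
    expect_identical(rs$mate1$seq[i],
                     substr(g[[tr$contig[i]]], tr$start[i] + 1, tr$start[i] + 76))
  }
  expect_error(simulate_reads(g, coverage = 0), class = "ps_input_error")
  expect_error(simulate_reads(g, coverage = 5, read_len = 300,
                              insert_mean = 200), class = "ps_input_error")
})

test_that("fixed pool variants appear in every error-free covering read", {
  g <- generate_genome(1, 30000, seed = 21)
  cc <- "contig_1"
  refb <- substr(g[[cc]], 15001, 15001)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  spec <- mutation_spec("snp", cc, 15000, ref = refb, alt = alt,
                        lineage = "x", causative = TRUE)
  mut <- plant_mutations(g, spec)$genome
  rs <- simulate_reads(rep(list(mut), 4), coverage = 30, seed = 3)
  tr <- rs$truth
  covering <- which(tr$start <= 15000 - 0 & tr$start + 76 > 15001)
  expect_gt(length(covering), 0)
  seen <- substr(rs$mate1$seq[covering], 15001 - tr$start[covering],
                 15001 - tr$start[covering])
  expect_true(all(seen == alt))
})

test_that("segregating loci average an allele frequency of one half across pools", {
  g <- generate_genome(1, 20000, seed = 31)
  cc <- "contig_1"
  refb <- substr(g[[cc]], 10001, 10001)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  specs <- list(mutation_spec("snp", cc, 10000, ref = refb, alt = alt,
                              lineage = "l"))
  pres <- rbind(s = c(l = "fixed"))
  design <- pool_design("s", "l", pres, n_isolates = 40)
  set.seed(77)
  fracs <- replicate(15, {
    pool <- simulate_pool(specs, design, "s")
    haps <- build_pool_haplotypes(g, specs, attr(pool, "genotypes"))
    rs <- simulate_reads(haps, coverage = 25)
    tr <- rs$truth
    cov <- which(tr$start <= 10000 & tr$start + 76 > 10001)
    seen <- substr(rs$mate1$seq[cov], 10001 - tr$start[cov],
                   10001 - tr$start[cov])
    mean(seen == alt)
  })
  # mean read-level alt fraction ~ 0.5 with SE ~ sqrt(Var(p_hat))/sqrt(n)
  expect_lt(abs(mean(fracs) - 0.5), 3 * sqrt(0.25 / 40) / sqrt(15) + 0.02)
})
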